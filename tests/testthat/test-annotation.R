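test_that("collapse_reads counts per stage and conserves totals", {
  reads <- data.frame(sequence = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                                   "ACGTACGTACGTACGTAC", "TTTTACGTACGTACGTACGTACGT"),
                      stage = c("10DAF", "10DAF", "15DAF", "10DAF"))
  cc <- collapse_reads(reads, stages = c("10DAF", "15DAF"))
  expect_equal(nrow(cc), 2)
  r1 <- cc[cc$sequence == "ACGTACGTACGTACGTAC", ]
  expect_equal(c(r1$`10DAF`, r1$`15DAF`), c(2L, 1L))
  expect_equal(sum(cc$`10DAF`), 3L)                   # conservation
  expect_equal(sum(cc$`15DAF`), 1L)
  expect_equal(nrow(collapse_reads(reads[0, ])), 0)   # empty in, empty out
  expect_error(collapse_reads(data.frame(sequence = "ACGT", stage = "10DAF")),
               "18-30")
})

test_that("map_to_genome equals a brute-force scan over every offset", {
  set.seed(123)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  reads <- c(substr(g, 101, 121),
             mirfill:::revcomp(substr(g, 1001, 1024)),   # minus-strand read
             substr(g, 4975, 4996),
             paste(rep("A", 20), collapse = ""))
  hits <- map_to_genome(reads, c(chr1 = g))
  # independent oracle: compare every offset by string equality
  brute <- do.call(rbind, lapply(unique(reads), function(q) {
    L <- nchar(q); qr <- mirfill:::revcomp(q)
    rows <- list()
    for (i in seq_len(nchar(g) - L + 1)) {
      sub <- substr(g, i, i + L - 1)
      if (sub == q) rows[[length(rows) + 1]] <-
          data.frame(sequence = q, chrom = "chr1", start = i - 1L,
                     end = i + L - 1L, strand = "+")
      if (sub == qr) rows[[length(rows) + 1]] <-
          data.frame(sequence = q, chrom = "chr1", start = i - 1L,
                     end = i + L - 1L, strand = "-")
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  ord <- function(d) d[order(d$sequence, d$start, d$strand), ]
  expect_equal(unname(as.matrix(ord(hits))), unname(as.matrix(ord(brute))))
  # an absent read yields no loci; the planted minus-strand read is found
  expect_false(paste(rep("A", 20), collapse = "") %in% hits$sequence)
  minus <- hits[hits$sequence == reads[2], ]
  expect_equal(minus$strand, "-")
  expect_equal(c(minus$start, minus$end), c(1000L, 1024L))
})

make_test_tracks <- function() {
  annotation_tracks(data.frame(
    type   = c("rRNA", "mirna_precursor", "mirna_mature", "repeat", "exon",
               "intron", "tRNA"),
    chrom  = "chr1",
    start  = c(100L, 150L, 160L, 300L, 500L, 700L, 120L),
    end    = c(200L, 260L, 181L, 400L, 600L, 800L, 195L),
    strand = c("+", "+", "+", "+", "+", "+", "+"),
    id     = c("rrna1", "mir1", "mir1-5p", "rep1", "gene1.e1", "gene1.i1",
               "trna1"),
    source = c("rfam", NA, NA, NA, NA, NA, "genbank"),
    stringsAsFactors = FALSE))
}

test_that("the priority rule picks the highest-ranked annotation", {
  tracks <- make_test_tracks()
  loci1 <- data.frame(sequence = "x", chrom = "chr1", start = 170L, end = 190L,
                      strand = "+")   # overlaps rRNA, tRNA and the precursor
  # GenBank tRNA outranks Rfam rRNA inside the rRNA-etc block
  expect_equal(mirfill:::classify_one(loci1, tracks)$category, "tRNA")
  df <- as.data.frame(tracks)
  tracks_norrna <- annotation_tracks(df[!df$type %in% c("rRNA", "tRNA"), ])
  expect_equal(mirfill:::classify_one(loci1, tracks_norrna)$category,
               "known_miRNA")
  # exon antisense: read on minus strand over a plus-strand exon
  loci2 <- data.frame(sequence = "y", chrom = "chr1", start = 520L, end = 540L,
                      strand = "-")
  expect_equal(mirfill:::classify_one(loci2, tracks)$category, "exon_antisense")
  loci3 <- data.frame(sequence = "y", chrom = "chr1", start = 520L, end = 540L,
                      strand = "+")
  expect_equal(mirfill:::classify_one(loci3, tracks)$category, "exon_sense")
  # unmapped -> no_annotation
  expect_equal(mirfill:::classify_one(NULL, tracks)$category, "no_annotation")
  # untracked region -> no_annotation
  loci4 <- data.frame(sequence = "z", chrom = "chr1", start = 900L, end = 920L,
                      strand = "+")
  expect_equal(mirfill:::classify_one(loci4, tracks)$category, "no_annotation")
})

test_that("classification is invariant to locus order and monotone in tracks", {
  tracks <- make_test_tracks()
  loci <- data.frame(sequence = "x", chrom = "chr1",
                     start = c(170L, 520L, 720L), end = c(190L, 540L, 740L),
                     strand = "+")
  base <- mirfill:::classify_one(loci, tracks)$category
  set.seed(1)
  for (i in 1:5) {
    perm <- loci[sample(nrow(loci)), ]
    expect_equal(mirfill:::classify_one(perm, tracks)$category, base)
  }
  # adding a lower-priority feature under an already-categorized read
  # never changes the category
  extra <- rbind(as.data.frame(tracks),
                 data.frame(type = "repeat", chrom = "chr1", start = 160L,
                            end = 195L, strand = "+", id = "rep9",
                            source = NA, parent = NA))
  expect_equal(mirfill:::classify_one(loci, annotation_tracks(extra))$category,
               base)
})

test_that("the +/-2 nt mature window matches and its exterior does not", {
  tracks <- make_test_tracks()   # mature at [160, 181)
  mk <- function(s, e) list(chrom = "chr1", start = s, end = e, strand = "+")
  expect_equal(match_known_mature(mk(160L, 181L), tracks), "mir1-5p")
  expect_equal(match_known_mature(mk(162L, 183L), tracks), "mir1-5p")  # +2/+2
  expect_equal(match_known_mature(mk(158L, 179L), tracks), "mir1-5p")  # -2/-2
  expect_true(is.na(match_known_mature(mk(163L, 184L), tracks)))       # +3
  expect_true(is.na(match_known_mature(mk(160L, 185L), tracks)))       # end +4
})

test_that("size distributions normalize and distinguish unique from total", {
  cc <- collapse_reads(data.frame(
    sequence = c(strrep("ACGTA", 4) , strrep("TGCA", 6), strrep("GATC", 6)),
    stage = "10DAF",
    count = c(5L, 1L, 1L)))            # 20 nt x5, 24 nt x1, 24 nt x1
  u <- size_distribution(cc, "unique")
  t <- size_distribution(cc, "total")
  expect_equal(u$`10DAF`[u$length == 20], 1 / 3)
  expect_equal(u$`10DAF`[u$length == 24], 2 / 3)
  expect_equal(t$`10DAF`[t$length == 20], 5 / 7)
  expect_equal(t$`10DAF`[t$length == 24], 2 / 7)
  expect_equal(sum(u$`10DAF`), 1, tolerance = 1e-12)
  expect_equal(sum(t$`10DAF`), 1, tolerance = 1e-12)
  # a single 24-nt read puts all mass on 24
  single <- size_distribution(collapse_reads(
    data.frame(sequence = strrep("TGCA", 6), stage = "10DAF")), "total")
  expect_equal(single$`10DAF`[single$length == 24], 1)
})

test_that("TPM normalization matches the published arithmetic", {
  raw <- matrix(c(1326, 0), nrow = 2,
                dimnames = list(c("a", "b"), "10DAF"))
  tpm <- tpm_normalize(raw, c("10DAF" = 14248902))
  expect_equal(round(tpm["a", 1], 2), 93.06)     # printed Table-2 scale value
  expect_equal(tpm["b", 1], 0)
  expect_error(tpm_normalize(raw, c("10DAF" = 0)), "positive")
  # covering the whole library sums to one million
  w <- shared_world()
  m <- mirfill:::count_matrix(w$libs)
  tt <- tpm_normalize(m, colSums(m))
  expect_equal(unname(colSums(tt)), rep(1e6, 5))
})

test_that("star ratios flag dominance, infinities and crossing profiles", {
  tpm <- rbind(mat1 = c(10, 10), star1 = c(500, 10),
               mat2 = c(0, 5),  star2 = c(3, 0),
               mat3 = c(10, 2), star3 = c(5, 6))
  colnames(tpm) <- c("10DAF", "35DAF")
  out <- star_ratio(tpm, data.frame(mature_id = c("mat1", "mat2", "mat3"),
                                    star_id = c("star1", "star2", "star3")))
  r1 <- out[out$mature_id == "mat1", ]
  expect_equal(r1$ratio, c(50, 1))
  expect_equal(r1$star_dominant, c(TRUE, FALSE))
  r2 <- out[out$mature_id == "mat2", ]
  expect_true(is.infinite(r2$ratio[1]) && r2$infinite[1])
  expect_false(is.na(r2$ratio[2]))
  # star-dominance can hold at one stage and not another
  r3 <- out[out$mature_id == "mat3", ]
  expect_equal(r3$star_dominant, c(FALSE, TRUE))
  expect_error(star_ratio(tpm, data.frame(mature_id = "nope", star_id = "mat1")),
               "missing")
})

test_that("the partition table reproduces the per-stage library totals", {
  w <- shared_world()
  part <- partition_table(w$cls)
  expect_equal(sort(unique(w$cls$category)) %in% part$category,
               rep(TRUE, length(unique(w$cls$category))))
  for (s in names(tiny_depths)) {
    tot <- part[part$category == "Total", paste0(s, "_total")]
    expect_equal(tot, unname(tiny_depths[s]))
    cats <- part[part$category != "Total", paste0(s, "_total")]
    expect_equal(sum(cats), tot)                        # Table-1 identity
    uni <- part[part$category != "Total", paste0(s, "_unique")]
    expect_equal(sum(uni), part[part$category == "Total", paste0(s, "_unique")])
  }
  # every unique read has exactly one category
  expect_true(all(w$cls$category %in% mirfill:::CATEGORIES))
})
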