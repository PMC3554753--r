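test_that("candidate windows are clipped, merged and cover planted loci", {
  g <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))   # 2 kb
  hits <- data.frame(sequence = c("a", "b", "c"), chrom = "chr1",
                     start = c(5L, 900L, 1000L), end = c(26L, 921L, 1021L),
                     strand = "+")
  win <- extract_candidates(hits, g)
  # read at the genome start: window clipped at 0
  expect_equal(win$start[1], 0L)
  expect_true(all(win$start >= 0 & win$end <= 2000))
  # the two reads 79 nt apart merge into one window (interval-merge oracle:
  # union of [900,1021] expanded by 150 on each side)
  expect_equal(nrow(win), 2L)
  expect_equal(c(win$start[2], win$end[2]), c(750L, 1171L))
  # far-apart reads stay separate
  hits2 <- hits; hits2$start[3] <- 1500L; hits2$end[3] <- 1521L
  expect_equal(nrow(extract_candidates(hits2, g)), 3L)
  # planted novel hairpins are all covered by some window
  w <- shared_world()
  unann <- w$cls$sequence[w$cls$category == "no_annotation"]
  uh <- w$hits[w$hits$sequence %in% unann, ]
  wins <- extract_candidates(uh, w$sim$genome)
  pm <- w$sim$truth$planted_mirnas
  for (i in which(!pm$known)) {
    expect_true(any(wins$start <= pm$prec_start[i] &
                      wins$end >= pm$prec_end[i]))
  }
})

# a synthetic candidate whose metrics we control exactly
fake_candidate <- function(mature_len = 21, mfe = -30, paired = 18,
                           bulge = 2, asymmetry = 1, spacing = 60) {
  structure(list(mature = strrep("A", mature_len), mfe = mfe,
                 metrics = list(paired = paired, bulge = bulge,
                                asymmetry = asymmetry, spacing = spacing)),
            class = "hairpin_candidate")
}

test_that("duplex criteria sit exactly on the published MIREAP boundaries", {
  chk <- function(...) check_duplex_criteria(fake_candidate(...))[["pass"]]
  expect_true(chk())                                    # comfortable pass
  expect_true(chk(paired = 16));  expect_false(chk(paired = 15))
  expect_true(chk(bulge = 4));    expect_false(chk(bulge = 5))
  expect_true(chk(asymmetry = 4)); expect_false(chk(asymmetry = 5))
  expect_true(chk(mfe = -18));    expect_false(chk(mfe = -17.9))
  expect_true(chk(spacing = 300)); expect_false(chk(spacing = 301))
  expect_true(chk(mature_len = 18) && chk(mature_len = 25))
  expect_false(chk(mature_len = 17) || chk(mature_len = 26))
  flags <- check_duplex_criteria(fake_candidate(paired = 15, bulge = 5))
  expect_false(flags[["paired"]]); expect_false(flags[["bulge"]])
  expect_true(flags[["mfe"]])
})

test_that("weakening any threshold never converts pass into fail", {
  set.seed(31)
  for (i in 1:50) {
    cand <- fake_candidate(mature_len = sample(15:28, 1),
                           mfe = runif(1, -40, -5),
                           paired = sample(10:21, 1),
                           bulge = sample(0:7, 1),
                           asymmetry = sample(0:7, 1),
                           spacing = sample(c(10:50, 280:320), 1))
    strict <- hairpin_thresholds()
    loose <- hairpin_thresholds(min_mature_len = 15, max_mature_len = 28,
                                max_mfe = -5, min_paired = 10, max_bulge = 7,
                                max_asymmetry = 7, max_space = 320)
    if (check_duplex_criteria(cand, strict)[["pass"]]) {
      expect_true(check_duplex_criteria(cand, loose)[["pass"]])
    }
  }
})

test_that("evidence classification follows the star / majority rules", {
  # one hairpin planted in a small genome; counts are crafted per case
  cfg <- simulation_config(genome_length = 12000L, n_known_mirnas = 0L,
                           n_novel_hairpins = 1L, seed = 5)
  sim <- simulate_genome(cfg)
  pm <- sim$truth$planted_mirnas
  stages <- names(cfg$library_depths)
  mk_cls <- function(mature_counts, star_counts) {
    df <- data.frame(sequence = c(pm$mature, pm$star),
                     stringsAsFactors = FALSE)
    for (k in seq_along(stages)) df[[stages[k]]] <- c(mature_counts[k],
                                                      star_counts[k])
    df$category <- "no_annotation"; df$mature_id <- NA_character_
    class(df) <- c("collapsed_reads", "data.frame")
    df
  }
  run <- function(mature_counts, star_counts) {
    cls <- mk_cls(mature_counts, star_counts)
    hits <- map_to_genome(cls$sequence, sim$genome)
    hits <- hits[hits$sequence %in% cls$sequence[rowSums(
      as.matrix(cls[, stages])) > 0], ]
    cls <- cls[rowSums(as.matrix(cls[, stages])) > 0, ]
    disc <- discover_novel_mirnas(cls, hits, sim$genome)
    if (nrow(disc$novel)) disc$novel$evidence[1] else NA_character_
  }
  # star in exactly one library, mature in one -> star evidence only
  expect_equal(run(c(9, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), "*")
  # no star, mature in three of five -> expression evidence
  expect_equal(run(c(3, 3, 3, 0, 0), c(0, 0, 0, 0, 0)), "T")
  # both -> "*, T"
  expect_equal(run(c(3, 3, 3, 0, 0), c(1, 0, 0, 0, 0)), "*, T")
  # no star, mature in only two libraries -> rejected
  expect_true(is.na(run(c(4, 4, 0, 0, 0), c(0, 0, 0, 0, 0))))
})

test_that("noise-free discovery recovers every planted novel hairpin", {
  w <- shared_world()
  disc <- shared_discovery()
  pm <- w$sim$truth$planted_mirnas
  novel <- pm[!pm$known, ]
  expect_true(all(novel$mature %in% disc$novel$sequence))   # 100 % recovery
  # per-criterion failure reasons are reported for rejected windows
  fails <- disc$report$outcome[grepl("^fail:", disc$report$outcome)]
  expect_gt(length(fails), 0)
  expect_true(all(grepl("^fail:(evidence|[a-z_+]+)$", fails)))
  # no emitted mature locus overlaps a known precursor
  mat_hits <- w$hits[w$hits$sequence %in% disc$novel$sequence, ]
  for (i in seq_len(nrow(mat_hits))) {
    expect_equal(nrow(mirfill:::overlapping_features(
      w$sim$tracks, mat_hits$chrom[i], mat_hits$start[i], mat_hits$end[i],
      "mirna_precursor")), 0L)
  }
  # reported TPM columns agree with the planted expression
  m <- mirfill:::count_matrix(w$libs)
  for (i in seq_len(nrow(disc$novel))) {
    seq <- disc$novel$sequence[i]
    expect_equal(as.numeric(disc$novel[i, names(tiny_depths)]),
                 unname(m[seq, ] / w$totals * 1e6))
  }
})
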