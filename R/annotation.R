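#' Collapse raw small-RNA reads into unique sequences with per-stage counts
#'
#' @param reads a data.frame with columns `sequence` and `stage`, one row
#'   per sequenced read, or with an additional `count` column for
#'   pre-aggregated input.
#' @param stages stage labels defining column order; defaults to the stages
#'   present, in first-appearance order of the canonical five-stage design.
#' @return a data.frame of class `"collapsed_reads"`: column `sequence`
#'   (uppercase DNA, U normalized to T) plus one integer count column per
#'   stage.  Per-stage count sums equal the input read numbers.
#' @export
collapse_reads <- function(reads, stages = NULL) {
  stopifnot(is.data.frame(reads), all(c("sequence", "stage") %in% names(reads)))
  if (is.null(stages)) {
    stages <- if (all(reads$stage %in% STAGES)) {
      STAGES[STAGES %in% unique(reads$stage)]
    } else unique(reads$stage)
  }
  if (nrow(reads) == 0) {
    out <- data.frame(sequence = character(0))
    for (s in stages) out[[s]] <- integer(0)
    return(structure(out, class = c("collapsed_reads", "data.frame")))
  }
  seqs <- norm_seq(reads$sequence)
  n <- nchar(seqs)
  if (any(n < 18 | n > 30)) {
    stop("reads outside the 18-30 nt window; filter before collapsing")
  }
  cnt <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  tab <- tapply(cnt, list(seqs, factor(reads$stage, levels = stages)),
                sum, default = 0L)
  out <- data.frame(sequence = rownames(tab), stringsAsFactors = FALSE)
  for (s in stages) out[[s]] <- as.integer(tab[, s])
  rownames(out) <- NULL
  structure(out, class = c("collapsed_reads", "data.frame"))
}

# stage (count) columns of a collapsed_reads data.frame, as a matrix
count_matrix <- function(collapsed) {
  stages <- setdiff(names(collapsed), c("sequence", "category", "mature_id"))
  m <- as.matrix(collapsed[, stages, drop = FALSE])
  rownames(m) <- collapsed$sequence
  m
}

#' Map sequences to a genome by exact match on both strands
#'
#' All perfect-match loci (0 mismatches) of each query on the forward and
#' reverse strand of each chromosome, in 0-based half-open coordinates.
#'
#' @param sequences character vector of query sequences.
#' @param genome named character vector of chromosome sequences or a
#'   `Biostrings::DNAStringSet`.
#' @return data.frame `sequence`, `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`); unmapped queries are simply absent.
#' @export
map_to_genome <- function(sequences, genome) {
  genome <- as_named_chars(genome, "chr")
  sequences <- unique(norm_seq(sequences))
  out <- list()
  by_width <- split(sequences, nchar(sequences))
  for (chr in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chr]])
    rsubj <- Biostrings::reverseComplement(subj)
    glen <- length(subj)
    for (w in names(by_width)) {
      qs <- by_width[[w]]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(qs))
      for (strand in c("+", "-")) {
        mi <- Biostrings::matchPDict(pd, if (strand == "+") subj else rsubj)
        nhit <- S4Vectors::elementNROWS(mi)
        if (sum(nhit) == 0) next
        st <- unlist(IRanges::start(mi), use.names = FALSE)
        en <- unlist(IRanges::end(mi), use.names = FALSE)
        qidx <- rep(seq_along(qs), nhit)
        if (strand == "-") {             # map back to forward coordinates
          tmp <- st
          st <- glen - en + 1L
          en <- glen - tmp + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          sequence = qs[qidx], chrom = chr,
          start = st - 1L, end = en, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence, res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# annotation tracks

TRACK_TYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA",
                 "mirna_precursor", "mirna_mature", "mirna_star",
                 "repeat", "exon", "intron", "gene")

# classification priority, highest first; the rRNA-etc block is internally
# resolved GenBank-before-Rfam, then rRNA > tRNA > snRNA > snoRNA
RNAETC <- c("rRNA", "tRNA", "snRNA", "snoRNA")
CATEGORIES <- c(RNAETC, "known_miRNA", "repeat",
                "exon_sense", "exon_antisense",
                "intron_sense", "intron_antisense", "no_annotation")

#' Construct a prioritized annotation track set
#'
#' @param features data.frame with columns `type` (one of rRNA, tRNA,
#'   snRNA, snoRNA, mirna_precursor, mirna_mature, mirna_star, repeat,
#'   exon, intron, gene), `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `id`; optional `source` (`genbank`/`rfam`, consulted in that
#'   order inside the rRNA-etc block) and `parent` (precursor id for
#'   mature/star arms, gene id for exons/introns).
#' @return the validated data.frame with class `"annotation_tracks"`.
#' @export
annotation_tracks <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("type", "chrom", "start", "end", "strand", "id") %in%
                  names(features)))
  bad <- setdiff(unique(features$type), TRACK_TYPES)
  if (length(bad)) stop("unknown track types: ", paste(bad, collapse = ", "))
  if (!"source" %in% names(features)) features$source <- NA_character_
  if (!"parent" %in% names(features)) features$parent <- NA_character_
  if (any(features$end <= features$start)) stop("empty or inverted intervals")
  structure(features, class = c("annotation_tracks", "data.frame"))
}

# features of given types overlapping the locus (same chrom, >= 1 bp)
overlapping_features <- function(tracks, chrom, start, end, types = NULL) {
  sel <- tracks$chrom == chrom & tracks$start < end & tracks$end > start
  if (!is.null(types)) sel <- sel & tracks$type %in% types
  tracks[sel, , drop = FALSE]
}

#' Match a read locus against annotated mature miRNAs with a +/-2 nt window
#'
#' A read is accepted as a known mature (or star) species when its start
#' lies within 2 nt of the annotated arm start and its end within 2 nt of
#' the annotated arm end, on the same strand.
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param tracks an [annotation_tracks()] object containing
#'   `mirna_mature` / `mirna_star` features.
#' @param arms which arm annotations to search.
#' @param window terminus tolerance in nt (default 2).
#' @return the matched arm `id`, or `NA_character_`.
#' @export
match_known_mature <- function(locus, tracks,
                               arms = c("mirna_mature", "mirna_star"),
                               window = 2L) {
  cand <- tracks[tracks$type %in% arms &
                   tracks$chrom == locus$chrom &
                   tracks$strand == locus$strand &
                   abs(tracks$start - locus$start) <= window &
                   abs(tracks$end - locus$end) <= window, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  cand$id[order(abs(cand$start - locus$start) + abs(cand$end - locus$end))][1]
}

# category of one read given all its loci -- the priority rule
classify_one <- function(loci, tracks) {
  if (is.null(loci) || nrow(loci) == 0) {
    return(list(category = "no_annotation", mature_id = NA_character_))
  }
  hits <- do.call(rbind, lapply(seq_len(nrow(loci)), function(k) {
    ov <- overlapping_features(tracks, loci$chrom[k], loci$start[k], loci$end[k])
    if (nrow(ov)) cbind(ov, read_strand = loci$strand[k],
                        read_start = loci$start[k], read_end = loci$end[k])
    else NULL
  }))
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(category = "no_annotation", mature_id = NA_character_))
  }
  etc <- hits[hits$type %in% RNAETC, , drop = FALSE]
  if (nrow(etc)) {
    src_rank <- match(tolower(etc$source), c("genbank", "rfam"))
    src_rank[is.na(src_rank)] <- 3L
    type_rank <- match(etc$type, RNAETC)
    best <- order(src_rank, type_rank)[1]
    return(list(category = etc$type[best], mature_id = NA_character_))
  }
  mir <- hits[hits$type %in% c("mirna_precursor", "mirna_mature", "mirna_star"),
              , drop = FALSE]
  if (nrow(mir)) {
    mature_id <- NA_character_
    for (k in seq_len(nrow(loci))) {
      mature_id <- match_known_mature(loci[k, ], tracks)
      if (!is.na(mature_id)) break
    }
    return(list(category = "known_miRNA", mature_id = mature_id))
  }
  if (any(hits$type == "repeat")) {
    return(list(category = "repeat", mature_id = NA_character_))
  }
  for (ft in c("exon", "intron")) {
    sub <- hits[hits$type == ft, , drop = FALSE]
    if (nrow(sub)) {
      sense <- any(sub$strand == sub$read_strand)
      return(list(category = paste0(ft, if (sense) "_sense" else "_antisense"),
                  mature_id = NA_character_))
    }
  }
  list(category = "no_annotation", mature_id = NA_character_)
}

#' Classify collapsed reads by the annotation priority rule
#'
#' Each unique read receives exactly one category, the highest-priority
#' annotation overlapped by any of its genomic loci:
#' rRNA-etc (GenBank before Rfam; rRNA > tRNA > snRNA > snoRNA) >
#' known miRNA > repeat > exon > intron; exon/intron reads are split into
#' sense/antisense by read strand versus gene strand, and unmapped or
#' untracked reads fall through to `no_annotation`.  Multi-locus reads are
#' classified once by their best locus; counts are not split.
#'
#' @param collapsed a [collapse_reads()] result.
#' @param hits genome loci from [map_to_genome()] for these sequences.
#' @param tracks an [annotation_tracks()] object.
#' @return `collapsed` with added columns `category` and `mature_id`.
#' @export
classify_reads <- function(collapsed, hits, tracks) {
  stopifnot(inherits(tracks, "annotation_tracks"))
  loci_by_seq <- if (nrow(hits)) split(hits, hits$sequence) else list()
  res <- lapply(collapsed$sequence, function(s) {
    classify_one(loci_by_seq[[s]], tracks)
  })
  collapsed$category <- vapply(res, `[[`, character(1), "category")
  collapsed$mature_id <- vapply(res, `[[`, character(1), "mature_id")
  collapsed
}

#' Partition table of read classes per stage (unique and total counts)
#'
#' The Table-1-style summary: for every category and stage, the number of
#' distinct sequences observed (`unique`) and the summed read count
#' (`total`), plus a `Total` row.  Per-stage category sums reproduce the
#' library totals exactly.
#'
#' @param classified output of [classify_reads()].
#' @return data.frame `category` x interleaved `<stage>_unique`,
#'   `<stage>_total` columns.
#' @export
partition_table <- function(classified) {
  stopifnot("category" %in% names(classified))
  m <- count_matrix(classified)
  stages <- colnames(m)
  cats <- c(RNAETC, "known_miRNA", "repeat", "exon_sense", "exon_antisense",
            "intron_sense", "intron_antisense", "no_annotation")
  out <- data.frame(category = c("Total", cats), stringsAsFactors = FALSE)
  for (s in stages) {
    u <- integer(length(cats)); tt <- numeric(length(cats))
    for (i in seq_along(cats)) {
      sel <- classified$category == cats[i]
      u[i] <- sum(m[sel, s] > 0)
      tt[i] <- sum(m[sel, s])
    }
    out[[paste0(s, "_unique")]] <- c(sum(m[, s] > 0), u)
    out[[paste0(s, "_total")]] <- c(sum(m[, s]), tt)
  }
  out
}

#' Read-length distributions per stage
#'
#' @param collapsed a [collapse_reads()] result.
#' @param level `"unique"` counts each distinct sequence once; `"total"`
#'   weights by read count.
#' @return data.frame `length` x one fraction column per stage; each
#'   stage column sums to 1 (stages with no reads are all-zero).
#' @export
size_distribution <- function(collapsed, level = c("unique", "total")) {
  level <- match.arg(level)
  m <- count_matrix(collapsed)
  len <- nchar(collapsed$sequence)
  lengths <- sort(unique(len))
  out <- data.frame(length = lengths)
  for (s in colnames(m)) {
    w <- if (level == "unique") as.numeric(m[, s] > 0) else m[, s]
    tot <- sum(w)
    out[[s]] <- if (tot > 0) {
      vapply(lengths, function(L) sum(w[len == L]) / tot, numeric(1))
    } else rep(0, length(lengths))
  }
  out
}

#' Normalize a count matrix to transcripts per million (TPM)
#'
#' `TPM(i, s) = raw(i, s) / total_clean(s) * 1e6`.  The denominator is the
#' library's total clean-read count, not its mappable subset.
#'
#' @param raw numeric matrix (rows = sequences or ids, columns = stages).
#' @param totals named vector of per-stage total clean reads (> 0); names
#'   must cover the columns of `raw`.
#' @return matrix of TPM values with the dimensions of `raw`.
#' @export
tpm_normalize <- function(raw, totals) {
  raw <- as.matrix(raw)
  if (is.null(names(totals))) {
    stopifnot(length(totals) == ncol(raw))
    names(totals) <- colnames(raw)
  }
  miss <- setdiff(colnames(raw), names(totals))
  if (length(miss)) stop("no library total for stage(s): ", paste(miss, collapse = ", "))
  totals <- totals[colnames(raw)]
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(raw, 2, totals, "/") * 1e6
}

#' miRNA:miRNA* abundance ratios per stage
#'
#' @param tpm TPM matrix with mature and star ids among its rownames.
#' @param pairs data.frame with columns `mature_id`, `star_id`.
#' @return long data.frame per pair and stage: TPMs, `ratio` =
#'   star/mature (`Inf` with `infinite = TRUE` when only the star is
#'   expressed, `NA` when neither is), and `star_dominant` = ratio > 1.
#' @export
star_ratio <- function(tpm, pairs) {
  stopifnot(all(c("mature_id", "star_id") %in% names(pairs)))
  miss <- setdiff(c(pairs$mature_id, pairs$star_id), rownames(tpm))
  if (length(miss)) stop("ids missing from TPM matrix: ", paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    mt <- tpm[pairs$mature_id[i], ]
    st <- tpm[pairs$star_id[i], ]
    ratio <- ifelse(mt > 0, st / mt, ifelse(st > 0, Inf, NA_real_))
    out[[i]] <- data.frame(
      mature_id = pairs$mature_id[i], star_id = pairs$star_id[i],
      stage = colnames(tpm), mature_tpm = as.numeric(mt),
      star_tpm = as.numeric(st), ratio = as.numeric(ratio),
      infinite = is.infinite(ratio),
      star_dominant = !is.na(ratio) & ratio > 1,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
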