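#' MIREAP-style duplex thresholds for novel miRNA discovery
#'
#' Defaults: mature length 18-25 nt, precursor MFE at most -18 kcal/mol,
#' at least 16 base pairs between the mature and star arms, bulge at most
#' 4 nt, duplex asymmetry at most 4 nt, mature-star spacing at most
#' 300 nt, 20 nt precursor flank.
#'
#' @param min_mature_len,max_mature_len mature length bounds (nt).
#' @param max_mfe precursor free-energy cutoff (kcal/mol).
#' @param min_paired minimum mature:star base pairs.
#' @param max_bulge maximal bulge (longest unpaired run on one arm, nt).
#' @param max_asymmetry maximal duplex asymmetry (nt).
#' @param max_space maximal spacing between mature and star (nt).
#' @param flank precursor flank length (nt).
#' @return named list of thresholds.
#' @export
hairpin_thresholds <- function(min_mature_len = 18L, max_mature_len = 25L,
                               max_mfe = -18, min_paired = 16L,
                               max_bulge = 4L, max_asymmetry = 4L,
                               max_space = 300L, flank = 20L) {
  list(min_mature_len = min_mature_len, max_mature_len = max_mature_len,
       max_mfe = max_mfe, min_paired = min_paired, max_bulge = max_bulge,
       max_asymmetry = max_asymmetry, max_space = max_space, flank = flank)
}

#' Extract candidate precursor windows around unannotated read loci
#'
#' Read loci on the same chromosome and strand closer than `merge_gap` are
#' merged, then expanded by `expand` nt on each side and clipped at the
#' chromosome ends.
#'
#' @param hits data.frame of loci (`sequence`, `chrom`, `start`, `end`,
#'   `strand`) for unannotated reads, from [map_to_genome()].
#' @param genome named character vector / `DNAStringSet`.
#' @param expand half-window size in nt (default 150, so a window can hold
#'   a mature-star spacing of up to 300 nt).
#' @param merge_gap merge distance in nt (default 300).
#' @return data.frame `chrom`, `start`, `end`, `strand`, `window`
#'   (sequence on the read strand, 5'->3').
#' @export
extract_candidates <- function(hits, genome, expand = 150L, merge_gap = 300L) {
  genome <- as_named_chars(genome, "chr")
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), window = character()))
  }
  out <- list()
  for (key in unique(paste(hits$chrom, hits$strand))) {
    sub <- hits[paste(hits$chrom, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    chrom <- sub$chrom[1]; strand <- sub$strand[1]
    glen <- nchar(genome[[chrom]])
    s <- sub$start[1]; e <- sub$end[1]
    flush <- function(s, e) {
      ws <- max(0L, s - expand); we <- min(glen, e + expand)
      seq <- substr(genome[[chrom]], ws + 1L, we)
      if (strand == "-") seq <- revcomp(seq)
      data.frame(chrom = chrom, start = ws, end = we, strand = strand,
                 window = seq, stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(sub))[-1]) {
      if (sub$start[k] - e < merge_gap) {
        e <- max(e, sub$end[k])
      } else {
        out[[length(out) + 1L]] <- flush(s, e)
        s <- sub$start[k]; e <- sub$end[k]
      }
    }
    out[[length(out) + 1L]] <- flush(s, e)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# duplex metrics of a mature arm inside a folded window.
# mature_off: 0-based half-open offsets of the mature within the window.
# Returns paired-base count, longest one-arm bulge, asymmetry, spacing and
# the star arm implied by the fold (the span pairing with the mature).
duplex_metrics <- function(fold, mature_off) {
  n <- nchar(fold$sequence)
  idx <- (mature_off[1] + 1L):mature_off[2]           # 1-based mature positions
  partner <- fold$pairs[idx]
  outside <- partner > 0 & !(partner %in% idx)
  if (!any(outside)) {
    return(list(paired = 0L, bulge = NA_integer_, asymmetry = NA_integer_,
                spacing = NA_integer_, star_off = NULL, star_seq = NA_character_))
  }
  # the star arm is the largest gap-free block of partner positions; a
  # stray long-range pair must not blow the star span up
  part <- sort(partner[outside])
  blocks <- cumsum(c(1L, diff(part) > length(idx) + 10L))
  biggest <- which.max(tabulate(blocks))
  star_lo <- min(part[blocks == biggest]); star_hi <- max(part[blocks == biggest])
  star_idx <- star_lo:star_hi
  paired <- sum(partner %in% star_idx)
  unpaired_m <- !(fold$pairs[idx] %in% star_idx)
  unpaired_s <- !(fold$pairs[star_idx] %in% idx)
  runmax <- function(flags) {
    if (!any(flags)) return(0L)
    r <- rle(flags); max(r$lengths[r$values])
  }
  bulge <- max(runmax(unpaired_m), runmax(unpaired_s))
  asym <- abs(sum(unpaired_m) - sum(unpaired_s))
  spacing <- if (star_lo > mature_off[2]) star_lo - 1L - mature_off[2]
             else mature_off[1] - star_hi
  list(paired = as.integer(paired), bulge = as.integer(bulge),
       asymmetry = as.integer(asym), spacing = as.integer(spacing),
       star_off = c(star_lo - 1L, star_hi),
       star_seq = substr(fold$sequence, star_lo, star_hi))
}

#' Build a hairpin candidate from a folded window and a mature read
#'
#' @param window one row of [extract_candidates()] output.
#' @param mature_seq the mature read sequence (most abundant read in the
#'   window by convention).
#' @param mature_off 0-based half-open offsets of the mature within the
#'   window sequence.
#' @param fold optional precomputed [fold_and_score()] result for the
#'   window.
#' @param thresholds a [hairpin_thresholds()] list (for the flank length).
#' @return list of class `"hairpin_candidate"`: locus, window fold, mature
#'   and star arms with offsets, `mfe`, and `duplex_metrics`
#'   (paired/bulge/asymmetry/spacing).
#' @export
hairpin_candidate <- function(window, mature_seq, mature_off, fold = NULL,
                              thresholds = hairpin_thresholds()) {
  if (is.null(fold)) fold <- fold_and_score(window$window)
  if (is.null(fold)) return(NULL)
  met <- duplex_metrics(fold, mature_off)
  arm <- if (!is.null(met$star_off) && met$star_off[1] > mature_off[2]) "5p"
         else "3p"
  prec_lo <- max(0L, min(mature_off[1], if (!is.null(met$star_off)) met$star_off[1] else mature_off[1]) - thresholds$flank)
  prec_hi <- min(nchar(window$window),
                 max(mature_off[2], if (!is.null(met$star_off)) met$star_off[2] else mature_off[2]) + thresholds$flank)
  structure(list(
    chrom = window$chrom, start = window$start, end = window$end,
    strand = window$strand, fold = fold,
    precursor = substr(window$window, prec_lo + 1L, prec_hi),
    mature = mature_seq, mature_off = mature_off, arm = arm,
    star = met$star_seq, star_off = met$star_off,
    mfe = fold$mfe, metrics = met), class = "hairpin_candidate")
}

#' Check the MIREAP-style duplex criteria for a hairpin candidate
#'
#' Pass requires: mature length within bounds, precursor MFE at or below
#' the cutoff, mature:star paired bases at or above the minimum (boundary
#' inclusive), bulge and asymmetry at or below their maxima, and
#' mature-star spacing within the limit.
#'
#' @param candidate a [hairpin_candidate()].
#' @param thresholds a [hairpin_thresholds()] list.
#' @return named logical vector of the six per-criterion flags plus `pass`.
#' @export
check_duplex_criteria <- function(candidate, thresholds = hairpin_thresholds()) {
  met <- candidate$metrics
  L <- nchar(candidate$mature)
  flags <- c(
    mature_length = L >= thresholds$min_mature_len && L <= thresholds$max_mature_len,
    mfe       = candidate$mfe <= thresholds$max_mfe,
    paired    = !is.na(met$paired) && met$paired >= thresholds$min_paired,
    bulge     = !is.na(met$bulge) && met$bulge <= thresholds$max_bulge,
    asymmetry = !is.na(met$asymmetry) && met$asymmetry <= thresholds$max_asymmetry,
    spacing   = !is.na(met$spacing) && met$spacing <= thresholds$max_space
  )
  c(flags, pass = all(flags))
}

#' Classify the evidence supporting a hairpin candidate
#'
#' A candidate is accepted as a novel miRNA when a star read is detected
#' in at least one library (`"star"` evidence), or the mature is detected
#' in more than half of the libraries (`"expression"`, i.e. >= 3 of 5), or
#' both (`"both"`).  Star detection matches any read whose genomic locus
#' agrees with the star arm within +/-2 nt at each terminus on the same
#' strand.
#'
#' @param candidate a passing [hairpin_candidate()].
#' @param collapsed a [collapse_reads()] table holding the library counts.
#' @param hits genome loci for the collapsed sequences.
#' @param window terminus tolerance for star matching (nt).
#' @return list with `evidence` (`"star"`, `"expression"`, `"both"` or
#'   `NA` = rejected), `star_libraries`, `mature_libraries`, and the
#'   Table-2-style `evidence_tag` (`"*"`, `"T"`, `"*, T"`).
#' @export
classify_evidence <- function(candidate, collapsed, hits, window = 2L) {
  m <- count_matrix(collapsed)
  nlib <- ncol(m)
  need <- ceiling((nlib + 1) / 2)

  mature_counts <- if (candidate$mature %in% rownames(m))
    m[candidate$mature, ] else setNames(rep(0, nlib), colnames(m))
  mature_libs <- sum(mature_counts > 0)

  star_libs <- 0L
  if (!is.null(candidate$star_off)) {
    # star offsets within the window -> genomic coordinates on + strand
    wlen <- candidate$end - candidate$start
    so <- candidate$star_off
    if (candidate$strand == "+") {
      g <- c(candidate$start + so[1], candidate$start + so[2])
    } else {
      g <- c(candidate$start + wlen - so[2], candidate$start + wlen - so[1])
    }
    near <- hits[hits$chrom == candidate$chrom &
                   hits$strand == candidate$strand &
                   abs(hits$start - g[1]) <= window &
                   abs(hits$end - g[2]) <= window, , drop = FALSE]
    if (nrow(near)) {
      seqs <- intersect(unique(near$sequence), rownames(m))
      if (length(seqs)) {
        star_libs <- sum(colSums(m[seqs, , drop = FALSE]) > 0)
      }
    }
  }
  evidence <- if (star_libs >= 1 && mature_libs >= need) "both"
    else if (star_libs >= 1) "star"
    else if (mature_libs >= need) "expression"
    else NA_character_
  tag <- switch(evidence %||% "none",
                both = "*, T", star = "*", expression = "T", "none" = NA_character_)
  list(evidence = evidence, star_libraries = star_libs,
       mature_libraries = mature_libs, evidence_tag = tag)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Discover novel miRNAs from unannotated reads
#'
#' The full hairpin-discovery workflow: candidate windows are extracted
#' around unannotated read loci, and within each window candidate mature
#' reads are examined in descending abundance (ties broken
#' lexicographically).  Each candidate read is folded in a subwindow of
#' its locus plus/minus 150 nt, the duplex criteria are checked and
#' surviving candidates are classified by star/expression evidence; reads
#' overlapping an already-examined mature locus are not re-examined.  To
#' bound folding cost, reads below `min_candidate_count` total reads are
#' only considered as the single top read of their window.  Candidates
#' whose mature locus overlaps a known-miRNA precursor are never emitted.
#'
#' @param classified a [classify_reads()] result.
#' @param hits genome loci for the classified sequences.
#' @param genome named character vector / `DNAStringSet`.
#' @param tracks an [annotation_tracks()] object (known precursors are
#'   excluded through it); may be `NULL`.
#' @param totals per-stage total clean-read counts for TPM.
#' @param thresholds a [hairpin_thresholds()] list.
#' @param min_candidate_count total-count floor for secondary candidate
#'   reads within a window (default 2).
#' @return list with `novel` (Table-2-layout data.frame: id, sequence,
#'   length, one TPM column per stage, evidence tag), `candidates` (the
#'   accepted `hairpin_candidate` objects) and `report` (per-window
#'   outcome with per-criterion failure flags).
#' @export
discover_novel_mirnas <- function(classified, hits, genome, tracks = NULL,
                                  totals = NULL,
                                  thresholds = hairpin_thresholds(),
                                  min_candidate_count = 2) {
  stopifnot("category" %in% names(classified))
  genome_chr <- as_named_chars(genome, "chr")
  m <- count_matrix(classified)
  unann <- classified$sequence[classified$category == "no_annotation"]
  uhits <- hits[hits$sequence %in% unann, , drop = FALSE]
  windows <- extract_candidates(uhits, genome_chr)
  expand <- 150L
  novel <- list(); cands <- list(); report <- list()
  note <- function(win, mature, outcome) {
    report[[length(report) + 1L]] <<- data.frame(
      chrom = win$chrom, start = win$start, end = win$end,
      strand = win$strand, mature = mature, outcome = outcome,
      stringsAsFactors = FALSE)
  }
  for (w in seq_len(nrow(windows))) {
    grp <- windows[w, ]
    inside <- uhits[uhits$chrom == grp$chrom & uhits$strand == grp$strand &
                      uhits$start >= grp$start & uhits$end <= grp$end, , drop = FALSE]
    if (nrow(inside) == 0) next
    tot <- rowSums(m[inside$sequence, , drop = FALSE])
    inside <- inside[order(-tot, inside$sequence), , drop = FALSE]
    first <- TRUE
    while (nrow(inside) > 0) {
      best <- inside[1, ]
      if (!first && sum(m[best$sequence, ]) < min_candidate_count) break
      first <- FALSE
      # drop reads overlapping this mature locus from further consideration
      inside <- inside[!(inside$start < best$end & inside$end > best$start), ,
                       drop = FALSE]
      if (!is.null(tracks)) {
        prec <- overlapping_features(tracks, best$chrom, best$start, best$end,
                                     "mirna_precursor")
        if (nrow(prec)) next
      }
      # fold a mature-centered subwindow (locus +/- 150 nt, clipped), so
      # the fold cost stays bounded however large the merged cluster is
      glen <- nchar(genome_chr[[grp$chrom]])
      ws <- max(0L, best$start - expand); we <- min(glen, best$end + expand)
      wseq <- substr(genome_chr[[grp$chrom]], ws + 1L, we)
      if (grp$strand == "-") wseq <- revcomp(wseq)
      win <- data.frame(chrom = grp$chrom, start = ws, end = we,
                        strand = grp$strand, window = wseq,
                        stringsAsFactors = FALSE)
      off <- if (win$strand == "+") c(best$start - win$start, best$end - win$start)
             else c(win$end - best$end, win$end - best$start)
      fold <- fold_and_score(win$window)
      if (is.null(fold)) {
        note(win, best$sequence, "window_too_short")
        next
      }
      cand <- hairpin_candidate(win, best$sequence, off, fold, thresholds)
      flags <- check_duplex_criteria(cand, thresholds)
      if (!flags[["pass"]]) {
        note(win, best$sequence,
             paste0("fail:", paste(names(flags)[!flags & names(flags) != "pass"],
                                   collapse = "+")))
        next
      }
      ev <- classify_evidence(cand, classified, hits)
      if (is.na(ev$evidence)) {
        note(win, best$sequence, "fail:evidence")
        next
      }
      cand$evidence <- ev
      cands[[length(cands) + 1L]] <- cand
      counts <- m[best$sequence, ]
      tpm <- if (!is.null(totals)) as.numeric(counts) / as.numeric(totals[colnames(m)]) * 1e6
             else as.numeric(counts)
      rec <- data.frame(id = NA_character_, sequence = best$sequence,
                        length = nchar(best$sequence), stringsAsFactors = FALSE)
      for (k in seq_along(colnames(m))) rec[[colnames(m)[k]]] <- tpm[k]
      rec$evidence <- ev$evidence_tag
      novel[[length(novel) + 1L]] <- rec
      note(win, best$sequence, paste0("novel:", ev$evidence))
      # an accepted hairpin claims its whole precursor span
      if (!is.null(cand$star_off)) {
        so <- cand$star_off; wlen <- win$end - win$start
        gs <- if (win$strand == "+") win$start + so[1] else win$start + wlen - so[2]
        ge <- if (win$strand == "+") win$start + so[2] else win$start + wlen - so[1]
        inside <- inside[!(inside$start < ge & inside$end > gs), , drop = FALSE]
      }
    }
  }
  novel_df <- if (length(novel)) do.call(rbind, novel) else
    data.frame(id = character(), sequence = character(), length = integer(),
               evidence = character())
  if (nrow(novel_df)) {
    # a hairpin is seen once per strand orientation; keep the first
    keep <- !duplicated(novel_df$sequence)
    novel_df <- novel_df[keep, , drop = FALSE]
    cands <- cands[keep]
    arm <- vapply(cands, function(x) x$arm, character(1))
    novel_df$id <- sprintf("miRn%d-%s", seq_len(nrow(novel_df)), arm)
    rownames(novel_df) <- NULL
  }
  list(novel = novel_df, candidates = cands,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(outcome = character()))
}
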