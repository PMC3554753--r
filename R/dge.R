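#' Canonical NlaIII/MmeI tags of a transcript
#'
#' One canonical 21-nt tag per CATG site: the recognition site plus the 17
#' nt immediately downstream (sites with fewer than 17 nt downstream are
#' skipped).  The 3'-most extractable tag is flagged `primary`, mirroring
#' the bead-capture step that retains the 3'-terminal fragment.
#'
#' @param transcript a nucleotide string (>= 25 nt for any tag to exist).
#' @return data.frame `tag`, `position` (0-based offset of the CATG) and
#'   `primary`; zero rows (with a warning) when the transcript has no
#'   usable CATG site.
#' @export
canonical_tags <- function(transcript) {
  transcript <- norm_seq(transcript)
  pos <- gregexpr("CATG", transcript, fixed = TRUE)[[1]]
  pos <- pos[pos > 0]
  pos <- pos[pos + 20 <= nchar(transcript)]   # need CATG + 17 nt downstream
  if (!length(pos)) {
    warning("transcript has no CATG site with 17 nt downstream; no tags")
    return(data.frame(tag = character(), position = integer(),
                      primary = logical()))
  }
  data.frame(tag = substring(transcript, pos, pos + 20),
             position = as.integer(pos - 1L),
             primary = seq_along(pos) == length(pos),
             stringsAsFactors = FALSE)
}

#' Filter observed DGE tags
#'
#' Retains tags that are exactly 21 nt, start with CATG, and were
#' sequenced at least twice in the library (singletons are removed
#' per-library: a tag kept in one stage may be dropped in another).
#'
#' @param tags data.frame with columns `tag`, `stage`, `count`.
#' @param min_count per-library minimum count (default 2).
#' @return the retained rows.
#' @export
filter_tags <- function(tags, min_count = 2L) {
  stopifnot(all(c("tag", "stage", "count") %in% names(tags)))
  keep <- nchar(tags$tag) == 21L &
    substr(tags$tag, 1, 4) == "CATG" &
    tags$count >= min_count
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify gene expression from filtered DGE tags
#'
#' Each tag is assigned to the gene(s) whose canonical tag set contains
#' it; a gene's expression is the summation of all its assigned tag
#' counts.  Tags matching several genes are counted for each match and
#' flagged ambiguous (set `ambiguous = "exclude"` to drop them instead).
#' TPM uses the per-stage total of clean (filtered) tags.
#'
#' @param tags filtered tags from [filter_tags()].
#' @param transcripts named character vector / `DNAStringSet` of
#'   transcript sequences (names = gene ids).
#' @param stages stage order for the output columns.
#' @param ambiguous `"count"` (default) or `"exclude"`.
#' @return list with `genes` (data.frame: gene, per-stage counts and
#'   per-stage TPM columns `<stage>_tpm`), `ambiguous_tags` (character),
#'   and `totals` (per-stage clean-tag totals used for TPM).
#' @export
quantify_genes <- function(tags, transcripts, stages = NULL,
                           ambiguous = c("count", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  transcripts <- as_named_chars(transcripts, "gene")
  if (is.null(stages)) {
    stages <- if (all(tags$stage %in% STAGES)) STAGES[STAGES %in% tags$stage]
              else unique(tags$stage)
  }
  index <- list()  # tag -> gene ids
  for (g in names(transcripts)) {
    ct <- suppressWarnings(canonical_tags(transcripts[[g]]))
    for (tg in unique(ct$tag)) index[[tg]] <- c(index[[tg]], g)
  }
  amb <- names(index)[vapply(index, length, integer(1)) > 1]
  genes <- names(transcripts)
  counts <- matrix(0, nrow = length(genes), ncol = length(stages),
                   dimnames = list(genes, stages))
  assigned <- 0; multiplicity <- 0
  for (i in seq_len(nrow(tags))) {
    tg <- tags$tag[i]
    gs <- index[[tg]]
    if (is.null(gs)) next
    if (ambiguous == "exclude" && length(gs) > 1) next
    st <- tags$stage[i]
    if (!st %in% stages) next
    counts[gs, st] <- counts[gs, st] + tags$count[i]
    assigned <- assigned + tags$count[i]
    multiplicity <- multiplicity + tags$count[i] * (length(gs) - 1L)
  }
  totals <- vapply(stages, function(s) sum(tags$count[tags$stage == s]),
                   numeric(1))
  tpm <- if (all(totals > 0)) tpm_normalize(counts, totals) else counts * NA_real_
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in stages) out[[s]] <- counts[, s]
  for (s in stages) out[[paste0(s, "_tpm")]] <- tpm[, s]
  out$has_ambiguous <- vapply(genes, function(g) {
    any(vapply(index, function(x) g %in% x && length(x) > 1, logical(1)))
  }, logical(1))
  list(genes = out, ambiguous_tags = amb, totals = totals,
       assigned = assigned, ambiguous_multiplicity = multiplicity)
}
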