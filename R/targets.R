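#' Score an ungapped miRNA:target duplex
#'
#' Aligns a miRNA (5'->3') against a candidate target site (5'->3' on the
#' mRNA) antiparallel and without gaps: miRNA position `k` (counted from the
#' miRNA 5' end) faces site position `L - k + 1`.  Each position is
#' classified Watson-Crick (`WC`), G:U wobble (`GU`) or mismatch (`MM`);
#' the weighted mismatch score counts a mismatch as 1 and a G:U pair as
#' 0.5.  Hybridization energies of the duplex and of the miRNA against its
#' perfect reverse complement are computed under the shared stacking model
#' ([energy-model]).
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param site target-site sequence of identical length, 5'->3'.
#' @return a list of class `"duplex_alignment"`: `mirna`, `site`, `states`
#'   (per miRNA position 1..L), `total_score`, `mfe`, `mfe_perfect`.
#' @examples
#' aln <- score_duplex("UGACAGAAGAGAGUGAGCAC",
#'                     mirfill:::revcomp("UGACAGAAGAGAGUGAGCAC"))
#' aln$total_score  # 0: perfect complement
#' @export
score_duplex <- function(mirna, site) {
  mirna <- norm_seq(mirna); site <- norm_seq(site)
  L <- nchar(mirna)
  if (nchar(site) != L) stop("miRNA and site must have equal length (ungapped core)")
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])      # site read 3'->5' opposite the miRNA
  states <- pair_state(m, s)
  weights <- ifelse(states == "MM", 1, ifelse(states == "GU", 0.5, 0))
  mfe <- stack_energy(pair_strength(m, s))
  sp <- rev(strsplit(revcomp(mirna), "")[[1]])
  mfe_perfect <- stack_energy(pair_strength(m, sp))
  structure(list(mirna = mirna, site = site, states = states,
                 weights = weights, total_score = sum(weights),
                 mfe = mfe, mfe_perfect = mfe_perfect),
            class = "duplex_alignment")
}

#' Hybridization energy of an ungapped miRNA:site duplex
#'
#' @inheritParams score_duplex
#' @return energy in kcal/mol (<= 0) under the package stacking model.
#' @export
duplex_mfe <- function(mirna, site) score_duplex(mirna, site)$mfe

#' Apply the six plant miRNA target-prediction rules
#'
#' The rules, evaluated on an ungapped duplex with positions counted from
#' the miRNA 5' end:
#' 1. weighted mismatch total <= `max_score` (mismatch = 1, G:U = 0.5);
#' 2. no run of more than two adjacent mismatches anywhere;
#' 3. no two adjacent mismatches with both positions within 2-12;
#' 4. no mismatch at positions 10 or 11;
#' 5. weighted mismatch total over positions 1-12 <= `max_seed_score`;
#' 6. duplex energy at least `mfe_fraction` of the perfect-complement
#'    energy (both energies negative: `|mfe| >= mfe_fraction * |mfe_perfect|`).
#'
#' G:U wobbles contribute half weight to the weighted sums (rules 1 and 5)
#' but do not count as mismatches for the positional rules (2, 3, 4).
#'
#' @param alignment a `"duplex_alignment"` from [score_duplex()].
#' @param max_score rule-1 cap (default 4).
#' @param max_seed_score rule-5 cap over positions 1-12 (default 2.5).
#' @param mfe_fraction rule-6 energy fraction (default 0.75).
#' @return named logical vector of the six flags plus `pass` (all six).
#' @export
apply_target_rules <- function(alignment, max_score = 4,
                               max_seed_score = 2.5, mfe_fraction = 0.75) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  st <- alignment$states
  w <- alignment$weights
  L <- length(st)
  mm <- st == "MM"

  runmax <- 0L
  if (any(mm)) {
    r <- rle(mm)
    runmax <- max(r$lengths[r$values])
  }
  seed <- seq_len(min(12L, L))
  adj_in_seed <- FALSE
  hi <- min(12L, L)
  if (hi >= 3L) {
    idx <- 2:(hi - 1L)                    # pairs (i, i+1) with both in [2,12]
    adj_in_seed <- any(mm[idx] & mm[idx + 1L])
  }
  flags <- c(
    total_score  = alignment$total_score <= max_score,
    adjacent     = runmax <= 2L,
    seed_adjacent = !adj_in_seed,
    pos_10_11    = !any(mm[intersect(10:11, seq_len(L))]),
    seed_score   = sum(w[seed]) <= max_seed_score,
    mfe_ratio    = abs(alignment$mfe) >= mfe_fraction * abs(alignment$mfe_perfect)
  )
  c(flags, pass = all(flags))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Evaluates every window of miRNA length on the sense strand of each
#' transcript under the six rules of [apply_target_rules()] and reports
#' the windows passing all of them, ordered by (miRNA id, transcript id,
#' position).
#'
#' @param mirnas named character vector of miRNA sequences (5'->3'), or a
#'   `Biostrings::DNAStringSet`/`RNAStringSet`.
#' @param transcripts named character vector of transcript sequences or a
#'   `DNAStringSet`.
#' @param ... thresholds forwarded to [apply_target_rules()].
#' @return data.frame with columns `mirna`, `transcript`, `start`, `end`
#'   (0-based half-open site coordinates), `score`, `mfe`, `mfe_ratio` and
#'   the six rule flags (all `TRUE` for reported hits).
#' @export
scan_transcriptome <- function(mirnas, transcripts, ...) {
  mirnas <- as_named_chars(mirnas, "mir")
  transcripts <- as_named_chars(transcripts, "tx")
  out <- list()
  for (mid in names(mirnas)) {
    mseq <- norm_seq(mirnas[[mid]])
    L <- nchar(mseq)
    for (tid in names(transcripts)) {
      tseq <- norm_seq(transcripts[[tid]])
      n <- nchar(tseq)
      if (n < L) next
      for (pos in seq_len(n - L + 1L)) {
        site <- substr(tseq, pos, pos + L - 1L)
        aln <- score_duplex(mseq, site)
        fl <- apply_target_rules(aln, ...)
        if (fl[["pass"]]) {
          flags <- fl[setdiff(names(fl), "pass")]
          names(flags) <- paste0("rule_", names(flags))
          out[[length(out) + 1L]] <- data.frame(
            mirna = mid, transcript = tid,
            start = pos - 1L, end = pos + L - 1L,
            score = aln$total_score, mfe = aln$mfe,
            mfe_ratio = if (aln$mfe_perfect < 0) aln$mfe / aln$mfe_perfect else NA_real_,
            t(flags),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), score = numeric(),
                      mfe = numeric(), mfe_ratio = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$mirna, res$transcript, res$start), , drop = FALSE]
}

#' Render a duplex alignment as text
#'
#' Watson-Crick pairs are drawn with `|`, G:U wobbles with `:`.
#'
#' @param alignment a `"duplex_alignment"`.
#' @return character vector of three display lines (site 3'->5' on top).
#' @export
render_duplex <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  bars <- ifelse(alignment$states == "WC", "|",
                 ifelse(alignment$states == "GU", ":", " "))
  site_rev <- paste(rev(strsplit(alignment$site, "")[[1]]), collapse = "")
  c(paste0("target 3' ", site_rev, " 5'"),
    paste0("          ", paste(bars, collapse = "")),
    paste0("miRNA  5' ", alignment$mirna, " 3'"))
}

# coerce sequences (character / XStringSet) to a named character vector
as_named_chars <- function(x, prefix) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  x <- vapply(x, as.character, character(1))
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0(prefix, seq_along(x))
  }
  x
}
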