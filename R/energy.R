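#' @title Nucleotide and duplex energy primitives
#' @name energy-model
#' @description
#' All thermodynamic comparisons in the package use one simplified
#' nearest-neighbour stacking model so that thresholds (the -18 kcal/mol
#' precursor cutoff, the 75 % duplex-energy ratio) are applied consistently
#' end to end and every energy is reproducible by hand:
#'
#' * pair strengths: G:C = 3.0, A:U = 2.0, G:U = 1.0 (kcal/mol),
#' * two adjacent pairs stack with energy `-(s1 + s2)/2`,
#' * isolated pairs, loops and unpaired bases contribute 0,
#' * minimum hairpin loop of 3 nt, no pseudoknots.
#'
#' An external thermodynamic folder can be plugged in by replacing
#' [fold_and_score()] behind the same contract (dot-bracket + MFE).
NULL

# normalize to uppercase DNA alphabet (U -> T); validates characters
norm_seq <- function(x) {
  x <- chartr("u", "T", chartr("U", "T", toupper(x)))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGTU characters in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  x
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", norm_seq(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# strength of a base pair between normalized DNA letters (RNA semantics:
# T stands for U).  0 = cannot pair.
pair_strength <- function(a, b) {
  s <- numeric(length(a))
  s[(a == "G" & b == "C") | (a == "C" & b == "G")] <- 3
  s[(a == "A" & b == "T") | (a == "T" & b == "A")] <- 2
  s[(a == "G" & b == "T") | (a == "T" & b == "G")] <- 1
  s
}

# pairing state between two letters: "WC", "GU" or "MM"
pair_state <- function(a, b) {
  st <- rep("MM", length(a))
  st[(a == "G" & b == "C") | (a == "C" & b == "G") |
     (a == "A" & b == "T") | (a == "T" & b == "A")] <- "WC"
  st[(a == "G" & b == "T") | (a == "T" & b == "G")] <- "GU"
  st
}

# stacking energy of an ungapped duplex given per-position pair strengths
# (0 = unpaired); adjacent paired positions stack with -(s1+s2)/2
stack_energy <- function(strengths) {
  if (length(strengths) < 2) return(0)
  k <- seq_len(length(strengths) - 1)
  on <- strengths[k] > 0 & strengths[k + 1] > 0
  -sum((strengths[k][on] + strengths[k + 1][on]) / 2)
}

#' Fold a candidate precursor window and report its minimum free energy
#'
#' Predicts a pseudoknot-free secondary structure for a single RNA strand
#' under the package's simplified nearest-neighbour stacking model (see
#' [energy-model]) by dynamic programming, and returns the structure in
#' dot-bracket notation together with its energy.
#'
#' @param window a nucleotide string (DNA or RNA alphabet); windows shorter
#'   than `min_len` cannot hold a miRNA duplex and yield the skip-signal
#'   `NULL`.
#' @param min_len minimum foldable window length in nt (default 40).
#' @return `NULL` (skip) for short windows, otherwise a list of class
#'   `"hairpin_fold"` with elements `sequence`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol, <= 0) and `pairs` (integer vector of 1-based partner
#'   positions, 0 = unpaired).
#' @examples
#' stem <- "GCGCGCGCGCAUAUAUAUAU"
#' hp <- fold_and_score(paste0(stem, "CAACAACAA",
#'                             mirfill:::revcomp(stem), "AAAAAAAAAAAA"))
#' hp$mfe
#' @export
fold_and_score <- function(window, min_len = 40L) {
  stopifnot(is.character(window), length(window) == 1L)
  window <- norm_seq(window)
  if (nchar(window) < min_len) return(NULL)
  res <- .fold_engine(window)
  structure(list(sequence = window,
                 structure = res$structure,
                 mfe = res$mfe,
                 pairs = res$pairs),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("MFE = %.2f kcal/mol", x$mfe), "\n", sep = "")
  invisible(x)
}
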