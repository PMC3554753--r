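#' @title File formats
#' @name mirfill-io
#' @description
#' FASTA is read and written with Biostrings, GFF3 with rtracklayer
#' (1-based inclusive on disk, 0-based half-open in memory).  Collapsed
#' small-RNA libraries use the conventional collapsed-FASTA dialect where
#' the header carries the read count: `>id_xCOUNT`.  Tables are plain TSV
#' with TPM exported at 2 decimal places.
NULL

#' Write sequences as FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_named_chars(seqs, "seq"))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write one stage of a collapsed library as collapsed FASTA
#'
#' Headers are `>sN_xCOUNT`; sequences with zero count in the stage are
#' omitted.
#'
#' @param collapsed a [collapse_reads()] table.
#' @param stage which count column to export.
#' @param path output file.
#' @export
write_collapsed_fasta <- function(collapsed, stage, path) {
  keep <- collapsed[[stage]] > 0
  seqs <- collapsed$sequence[keep]
  cnt <- collapsed[[stage]][keep]
  names(seqs) <- sprintf("s%d_x%d", seq_along(seqs), cnt)
  write_fasta(seqs, path)
}

#' Read stage-labelled collapsed FASTA libraries
#'
#' @param paths named character vector stage -> collapsed FASTA path;
#'   headers must end in `_xCOUNT`.
#' @return a [collapse_reads()] table.
#' @export
read_collapsed_fasta <- function(paths) {
  chunks <- list()
  for (stage in names(paths)) {
    seqs <- read_fasta(paths[[stage]])
    cnt <- suppressWarnings(as.integer(sub("^.*_x", "", names(seqs))))
    if (any(is.na(cnt))) stop("collapsed FASTA headers must end in _xCOUNT: ",
                              paths[[stage]])
    chunks[[length(chunks) + 1L]] <- data.frame(
      sequence = unname(seqs), stage = stage, count = cnt,
      stringsAsFactors = FALSE)
  }
  collapse_reads(do.call(rbind, chunks), stages = names(paths))
}

#' Write annotation tracks as GFF3
#' @param tracks an [annotation_tracks()] object.
#' @param path output `.gff3` file.
#' @export
write_gff3 <- function(tracks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tracks$chrom,
    ranges = IRanges::IRanges(start = tracks$start + 1L, end = tracks$end),
    strand = ifelse(tracks$strand %in% c("+", "-"), tracks$strand, "*"))
  S4Vectors::mcols(gr)$type <- tracks$type
  S4Vectors::mcols(gr)$source <- ifelse(is.na(tracks$source), "mirfill",
                                        tracks$source)
  S4Vectors::mcols(gr)$ID <- tracks$id
  S4Vectors::mcols(gr)$Parent <- tracks$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into an annotation track set
#' @param path a GFF3 file written by [write_gff3()] or compatible.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- S4Vectors::mcols(gr)$Parent
  if (!is.null(parent) && methods::is(parent, "List")) {
    parent <- vapply(as.list(parent),
                     function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
  }
  src <- as.character(S4Vectors::mcols(gr)$source)
  src[src == "mirfill"] <- NA_character_
  annotation_tracks(data.frame(
    type = as.character(S4Vectors::mcols(gr)$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(S4Vectors::mcols(gr)$ID),
    source = src,
    parent = if (is.null(parent)) NA_character_ else as.character(parent),
    stringsAsFactors = FALSE))
}

#' Write / read a simple TSV table
#' @param x data.frame.
#' @param path file path.
#' @param digits decimal places for numeric columns (default 2, the TPM
#'   export convention); `NA` leaves values untouched.
#' @export
write_tsv <- function(x, path, digits = 2) {
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1)) & !vapply(x, is.integer, logical(1))
    x[num] <- lapply(x[num], round, digits = digits)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load the packaged table of the 45 transcribed novel miRNAs
#'
#' The fixture transcribes the published novel-miRNA table: id, sequence,
#' printed length, TPM in the five libraries, and the evidence tag
#' (`*` = star read detected, `T` = mature in at least three of five
#' libraries, `*, T` = both).  Loading validates the row count and the
#' invariant that each printed length equals the sequence length.
#'
#' @param path override the packaged file (mainly for tests).
#' @return data.frame with 45 rows and class `"table2_fixture"`.
#' @export
load_table2_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_novel_mirnas.tsv",
                        package = "mirfill", mustWork = TRUE)
  }
  x <- read_tsv(path)
  need <- c("id", "sequence", "length", STAGES, "evidence")
  if (!all(need %in% names(x))) stop("fixture is missing columns")
  if (nrow(x) != 45L) stop("fixture must have exactly 45 records, found ", nrow(x))
  if (!all(nchar(x$sequence) == x$length)) {
    stop("fixture corrupt: printed length != sequence length for ",
         paste(x$id[nchar(x$sequence) != x$length], collapse = ", "))
  }
  if (!all(x$evidence %in% c("*", "T", "*, T"))) {
    stop("fixture corrupt: unexpected evidence tags")
  }
  structure(x, class = c("table2_fixture", "data.frame"))
}

#' Load the packaged per-stage read-class partition table
#'
#' A transcription of the published Table-1-style summary: for each of
#' the five libraries, unique and total read counts of every annotation
#' category plus the library totals.
#'
#' @param path override the packaged file.
#' @return data.frame: `category` x `<stage>_unique` / `<stage>_total`.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_read_classes.tsv",
                        package = "mirfill", mustWork = TRUE)
  }
  x <- read_tsv(path)
  if (!"category" %in% names(x) || nrow(x) != 12L) {
    stop("partition fixture must have a category column and 12 rows")
  }
  x
}
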