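# FASTA-backed scaffold sets.
#
# A scaffold_set is a data.frame with columns
#   scaffold_id (character, unique), length (integer bp), sequence (character
#   or NA for length-only sets),
# carrying class "scaffold_set". Length-only sets support every coordinate
# computation (AGP building, assembly statistics); sequences are required only
# to emit FASTA.

IUPAC_DNA <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"

#' Create a scaffold set
#'
#' @param scaffold_id character vector of unique scaffold names.
#' @param length integer vector of scaffold lengths in bp (> 0). May be
#'   omitted when `sequence` is given.
#' @param sequence optional character vector of nucleotide sequences; `NA`
#'   entries give a length-only record.
#' @return A `scaffold_set` data.frame.
#' @export
scaffold_set <- function(scaffold_id, length = NULL, sequence = NULL) {
  scaffold_id <- as.character(scaffold_id)
  if (anyDuplicated(scaffold_id))
    stop_format("duplicated scaffold id: %s",
                scaffold_id[duplicated(scaffold_id)][1L])
  if (is.null(sequence)) sequence <- rep(NA_character_, length(scaffold_id))
  if (is.null(length)) {
    if (anyNA(sequence)) stop_format("`length` required when sequences are absent")
    length <- nchar(sequence)
  }
  length <- as.integer(length)
  if (length(length) != length(scaffold_id) ||
      length(sequence) != length(scaffold_id))
    stop_format("scaffold_id, length and sequence must have equal length")
  if (any(!is.finite(length)) || any(length <= 0L))
    stop_format("scaffold lengths must be positive")
  has_seq <- !is.na(sequence)
  if (any(nchar(sequence[has_seq]) != length[has_seq]))
    stop_format("sequence length disagrees with declared length for: %s",
                scaffold_id[has_seq][nchar(sequence[has_seq]) != length[has_seq]][1L])
  out <- data.frame(scaffold_id = scaffold_id, length = length,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("scaffold_set", "data.frame")
  out
}

#' Read scaffolds from FASTA
#'
#' Non-IUPAC characters are retained with a warning, so a set read from an
#' unusual FASTA still round-trips byte-identically (after line-wrapping
#' normalisation).
#'
#' @param path FASTA file.
#' @return A [scaffold_set()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_format("no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  txt <- as.character(seqs)
  if (any(nchar(txt) == 0L))
    stop_format("empty FASTA record: %s", ids[nchar(txt) == 0L][1L])
  bad <- grepl(sprintf("[^%s]", IUPAC_DNA), txt)
  if (any(bad))
    warning(sprintf("non-IUPAC characters in %d record(s) (e.g. %s); retained",
                    sum(bad), ids[bad][1L]), call. = FALSE)
  scaffold_set(ids, sequence = txt)
}

#' Write scaffolds or an assembly to FASTA
#'
#' @param x a `scaffold_set` with sequences, or an [build_pseudochromosomes()]
#'   `assembly_bundle` (chromosome records are written, then unplaced
#'   scaffolds as separate records).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "assembly_bundle")) {
    seqs <- x$sequences
    if (is.null(seqs)) stop_format("assembly bundle carries no sequences")
  } else {
    if (anyNA(x$sequence))
      stop_format("cannot write length-only scaffolds to FASTA")
    seqs <- setNames(x$sequence, x$scaffold_id)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' Full IUPAC alphabet, case-preserving; characters outside the alphabet are
#' left in place (reversed only).
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}
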