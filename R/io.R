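#' Read a FASTA file
#'
#' Parsing is delegated to [Biostrings::readDNAStringSet()], which accepts
#' multi-line records, Windows line endings, lowercase and IUPAC ambiguity
#' codes. Sequences come back upper-cased (the parser folds case, which is
#' also the first step of [build_kmer_set()] and [clean_records()], so
#' downstream behaviour is unaffected); ambiguity handling happens
#' downstream.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `name` and `sequence`; zero rows for
#'   an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e)
                  stop("malformed FASTA in '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  data.frame(name = if (length(x)) names(x) else character(0),
             sequence = as.character(x), row.names = NULL)
}

#' Write sequences as FASTA
#'
#' @param records A data frame with `name`/`sequence` columns, a named (or
#'   unnamed) character vector, or a `representation` (sequences are then
#'   named with sequential integers starting at 1, the cleaned-format
#'   convention).
#' @param path Destination path.
#' @param line_width Characters per sequence line; `0` (default) writes
#'   each sequence on a single line, which makes whole-file byte
#'   accounting reproducible.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 0) {
  if (inherits(records, "representation")) {
    seqs <- records$sequences
    nms <- as.character(seq_along(seqs))
  } else if (is.data.frame(records)) {
    seqs <- as.character(records$sequence)
    nms <- as.character(records$name)
  } else {
    seqs <- as.character(records)
    nms <- names(seqs)
    if (is.null(nms)) nms <- as.character(seq_along(seqs))
  }
  if (length(seqs) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  width <- if (line_width > 0) as.integer(line_width)
           else max(nchar(seqs), 1L)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Clean FASTA records for k-mer work
#'
#' The cleaning protocol used before byte-level comparisons of textual
#' de Bruijn graph representations: fold to upper case, split every
#' sequence at each unknown (non-ACGT) nucleotide, discard segments
#' shorter than `min_length` (default 18 bp), and rename the survivors to
#' sequential integers starting at 1.
#'
#' @param records Data frame with `name`/`sequence` columns, or a
#'   character vector of sequences.
#' @param min_length Minimum surviving segment length in bases (>= 1).
#' @return A data frame with columns `name` (`"1"`, `"2"`, ...) and
#'   `sequence` (upper-case ACGT only).
#' @examples
#' clean_records(data.frame(name = "x",
#'                          sequence = "ACGTACGTNNTTTTTTTTTTTTTTTTTT"))
#' @export
clean_records <- function(records, min_length = 18) {
  if (min_length < 1) stop("min_length must be >= 1")
  seqs <- toupper(as_sequences(records))
  segs <- unlist(strsplit(seqs, "[^ACGT]+"), use.names = FALSE)
  if (is.null(segs)) segs <- character(0)
  segs <- segs[nchar(segs) >= min_length]
  data.frame(name = as.character(seq_along(segs)), sequence = segs,
             row.names = NULL)
}
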