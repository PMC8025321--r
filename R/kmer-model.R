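#' Reverse complement of nucleotide strings
#'
#' Reverses each string and complements every base (A<->T, C<->G). Applying
#' the function twice returns the input.
#'
#' @param s Character vector of strings over the alphabet A, C, G, T.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ACG")   # "CGT"
#' reverse_complement("ACGT")  # its own reverse complement
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  cpp_revcomp(s)
}

#' Canonical form of nucleotide strings
#'
#' The canonical form of a k-mer is the lexicographic minimum (A < C < G < T)
#' of the k-mer and its reverse complement; it is the node identity used by
#' the bi-directed strand model.
#'
#' @param s Character vector of strings over A, C, G, T.
#' @return Character vector; `canonical_form` is idempotent and invariant
#'   under `reverse_complement()`.
#' @examples
#' canonical_form("CGT") # "ACG"
#' @export
canonical_form <- function(s) {
  stopifnot(is.character(s))
  cpp_canonical(s)
}

#' All consecutive k-mers of a segment
#'
#' @param s A single string over A, C, G, T.
#' @param k k-mer length (>= 1).
#' @return Character vector of the `nchar(s) - k + 1` k-mers in order of
#'   occurrence; empty when `s` is shorter than `k`.
#' @examples
#' kmers_of_segment("ACGTT", 3)
#' @export
kmers_of_segment <- function(s, k) {
  stopifnot(is.character(s), length(s) == 1L)
  if (k < 1) stop("k must be >= 1")
  if (!grepl("^[ACGT]*$", s)) stop("segment contains non-ACGT characters")
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq(k, n))
}

#' Construct a k-mer set (node-centric de Bruijn graph)
#'
#' Extracts the distinct k-mers of one or more sequences. Sequences are
#' folded to upper case and split into maximal ACGT-only segments at every
#' other character (N, IUPAC ambiguity codes, gaps), so no k-mer spans an
#' ambiguous position. In the bi-directed model the members are canonical
#' k-mers.
#'
#' @param x Sequences: a character vector, a data frame with a `sequence`
#'   column (as returned by [read_fasta()]), or a
#'   [Biostrings::DNAStringSet-class].
#' @param k k-mer length, in `[1, 32]`.
#' @param model Strand model, `"bi"` (canonical k-mers, default) or `"uni"`.
#' @return An object of class `kmer_set`: a list with elements `k`, `model`
#'   and `kmers` (distinct members, sorted lexicographically).
#' @examples
#' build_kmer_set("ACGTT", k = 3, model = "uni")  # ACG, CGT, GTT
#' build_kmer_set("ACGT", k = 3, model = "bi")    # collapses to ACG
#' @export
build_kmer_set <- function(x, k, model = c("bi", "uni")) {
  model <- match.arg(model)
  seqs <- as_sequences(x)
  kmer_set(k = k, model = model,
           kmers = cpp_build_kmer_set(seqs, as.integer(k), model == "bi"))
}

#' Assemble a k-mer set from explicit members
#'
#' Low-level constructor used by [build_kmer_set()]; validates that all
#' members have length `k` and, in the bi-directed model, canonicalizes and
#' deduplicates them.
#'
#' @param k k-mer length in `[1, 32]`.
#' @param model `"uni"` or `"bi"`.
#' @param kmers Character vector of members.
#' @return A `kmer_set` object.
#' @export
kmer_set <- function(k, model = c("bi", "uni"), kmers = character(0)) {
  model <- match.arg(model)
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 32)
    stop("k must be a single integer in [1, 32]")
  k <- as.integer(k)
  if (length(kmers) && any(nchar(kmers) != k))
    stop("all k-mers must have length k = ", k)
  if (length(kmers)) {
    if (model == "bi") kmers <- cpp_canonical(kmers)
    kmers <- sort(unique(kmers), method = "radix") # C-locale: A<C<G<T
  }
  structure(list(k = k, model = model, kmers = kmers), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d distinct %s k-mer(s), k = %d, model = %s\n",
              length(x$kmers), if (x$model == "bi") "canonical" else "",
              x$k, x$model))
  if (length(x$kmers))
    cat("  ", paste(head(x$kmers, 6), collapse = " "),
        if (length(x$kmers) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$kmers)

# normalize the accepted sequence containers to a plain character vector
as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x))
      stop("data frame input must have a 'sequence' column")
    return(as.character(x$sequence))
  }
  if (is.character(x)) return(x)
  stop("unsupported sequence container: ", class(x)[1])
}
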