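#' Extension policy for the greedy simplitig algorithm
#'
#' The greedy algorithm is deterministic given the order in which seeding
#' k-mers are drawn and the order in which extension nucleotides are tried.
#' Extension trials follow the lexicographic nucleotide order by default;
#' the only source of variability between equally valid simplitig sets is
#' the seed order.
#'
#' @param seed_order `"sorted-code"` (ascending packed code, the
#'   cross-platform deterministic default), `"insertion"` (order of the
#'   member vector as given), or `"random"` (requires `seed`).
#' @param seed Integer seed for `seed_order = "random"`.
#' @param nucleotide_order A permutation of `"ACGT"` used for extension
#'   trials.
#' @return An `extension_policy` object.
#' @export
extension_policy <- function(seed_order = c("sorted-code", "insertion", "random"),
                             seed = NULL, nucleotide_order = "ACGT") {
  seed_order <- match.arg(seed_order)
  if (seed_order == "random") {
    if (is.null(seed)) stop("seed_order = \"random\" requires a seed")
    seed <- as.integer(seed)
  } else {
    seed <- 0L
  }
  if (!is.character(nucleotide_order) || length(nucleotide_order) != 1L ||
      nchar(nucleotide_order) != 4L ||
      !setequal(strsplit(nucleotide_order, "")[[1]], c("A", "C", "G", "T")))
    stop("nucleotide_order must be a permutation of \"ACGT\"")
  structure(list(seed_order = seed_order, seed = seed,
                 nucleotide_order = nucleotide_order),
            class = "extension_policy")
}

new_representation <- function(kind, k, model, sequences) {
  structure(list(kind = kind, k = as.integer(k), model = model,
                 sequences = as.character(sequences)),
            class = "representation")
}

#' @export
print.representation <- function(x, ...) {
  cat(sprintf("%s representation: NS = %d, CL = %d, k = %d, model = %s\n",
              x$kind, length(x$sequences), sum(nchar(x$sequences)),
              x$k, x$model))
  invisible(x)
}

#' Compute maximal simplitigs greedily
#'
#' Simplitigs are spellings of the paths of a vertex-disjoint path cover of
#' the node-centric de Bruijn graph; maximal simplitigs can be neither
#' extended at an end nor merged pairwise through a (k-1)-overlap. The
#' greedy heuristic repeatedly seeds a new simplitig with the next unused
#' k-mer and extends it forwards and then backwards as long as some
#' single-base extension forms a k-mer still present in the working set,
#' removing each k-mer from the set the moment it is used. The result
#' carries every k-mer of the input exactly once (see [verify()]).
#'
#' In the bi-directed model the growing simplitig is held in its emitted
#' orientation and membership is tested on canonical forms, so an extension
#' may consume a k-mer matched through its reverse complement.
#'
#' @param K A [kmer_set()].
#' @param policy An [extension_policy()].
#' @return A `representation` of kind `"simplitigs"`. An empty `K` yields an
#'   empty representation.
#' @examples
#' K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
#' compute_simplitigs(K)$sequences  # "ACGA" "CGT"
#' @export
compute_simplitigs <- function(K, policy = extension_policy()) {
  stopifnot(inherits(K, "kmer_set"), inherits(policy, "extension_policy"))
  seqs <- cpp_compute_simplitigs(K$kmers, K$k, K$model == "bi",
                                 policy$seed_order, policy$seed,
                                 policy$nucleotide_order)
  new_representation("simplitigs", K$k, K$model, seqs)
}

#' Compute maximal unitigs
#'
#' A unitig is a path whose internal nodes have in-degree 1 and whose
#' non-terminal nodes have out-degree 1; maximal unitigs are the classical
#' compacted representation that stops at branching nodes. Neighbors are
#' found by probing all four single-base extensions for membership (with
#' orientation tracking in the bi-directed model). Isolated cycles, where
#' every node has in- and out-degree 1, have no canonical start and are
#' broken at the node with the smallest packed code.
#'
#' @param K A [kmer_set()].
#' @return A `representation` of kind `"unitigs"` carrying every k-mer of
#'   `K` exactly once.
#' @examples
#' K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
#' compute_unitigs(K)$sequences  # no compaction: ACG branches
#' @export
compute_unitigs <- function(K) {
  stopifnot(inherits(K, "kmer_set"))
  seqs <- cpp_compute_unitigs(K$kmers, K$k, K$model == "bi")
  new_representation("unitigs", K$k, K$model, seqs)
}

#' Check maximality of a simplitig representation
#'
#' A representation that carries the k-mers of `K` exactly once is maximal
#' when no sequence end could absorb an unused k-mer (vacuous here, since
#' all k-mers are used) and no two distinct sequences can be merged through
#' a (k-1)-overlap between the last k-mer of one and the first k-mer of the
#' other. A single sequence closing a cycle onto itself is not a violation:
#' no merge partner exists. In the bi-directed model both orientations of
#' every sequence are considered when looking for merge partners.
#'
#' @param rep A `representation`.
#' @param K The reference [kmer_set()]; `rep` must pass [verify()] against
#'   it, otherwise the check is rejected.
#' @return A list with `maximal` (logical) and `violations` (data frame
#'   with columns `from_seq`, `to_seq`, `overlap` naming each mergeable
#'   ordered pair).
#' @export
is_maximal <- function(rep, K) {
  stopifnot(inherits(rep, "representation"), inherits(K, "kmer_set"))
  v <- verify(rep, K)
  if (!v$passed)
    stop("representation does not carry the k-mers of K exactly once; ",
         "run verify() for details")
  k <- K$k
  seqs <- rep$sequences
  n <- length(seqs)
  empty <- data.frame(from_seq = integer(0), to_seq = integer(0),
                      overlap = character(0))
  if (n <= 1L)
    return(list(maximal = TRUE, violations = empty))

  # ends of each sequence in each admissible orientation
  orient <- function(s) if (K$model == "bi") c(s, reverse_complement(s)) else s
  heads <- list() # (k-1)-prefixes keyed by sequence index
  tails <- list()
  for (i in seq_len(n)) {
    os <- orient(seqs[i])
    heads[[i]] <- unique(substring(os, 1L, k - 1L))
    tails[[i]] <- unique(substring(os, nchar(os) - k + 2L, nchar(os)))
  }
  m <- merge(
    data.frame(from_seq = rep(seq_len(n), lengths(tails)),
               overlap = unlist(tails)),
    data.frame(to_seq = rep(seq_len(n), lengths(heads)),
               overlap = unlist(heads)),
    by = "overlap")
  viol <- m[m$from_seq != m$to_seq, c("from_seq", "to_seq", "overlap")]
  viol <- viol[order(viol$from_seq, viol$to_seq), , drop = FALSE]
  rownames(viol) <- NULL
  list(maximal = nrow(viol) == 0L, violations = viol)
}
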