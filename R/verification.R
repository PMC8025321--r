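#' Verify the exactly-once property of a representation
#'
#' A textual representation of a de Bruijn graph is correct if and only if
#' every k-mer of the reference set occurs exactly once across its
#' sequences and no other k-mer occurs. The check is an independent
#' occurrence-counting pass over the emitted strings: k-mers are sliced out
#' with plain substring arithmetic and, in the bi-directed model,
#' canonicalized through [Biostrings::reverseComplement()], so none of the
#' construction machinery is reused.
#'
#' @param rep A `representation` (or any character vector of sequences).
#' @param K The reference [kmer_set()]; must share `k` and strand model
#'   with `rep` when `rep` is a representation.
#' @return A `verification_report`: list with `passed` (logical),
#'   `missing` and `extra` (character vectors of k-mers), and `duplicated`
#'   (named integer vector of observed multiplicities > 1).
#' @examples
#' K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
#' verify(compute_simplitigs(K), K)$passed
#' @export
verify <- function(rep, K) {
  stopifnot(inherits(K, "kmer_set"))
  if (inherits(rep, "representation")) {
    if (rep$k != K$k) stop("k mismatch: representation has k = ", rep$k,
                           ", reference has k = ", K$k)
    if (rep$model != K$model)
      stop("strand model mismatch: ", rep$model, " vs ", K$model)
    seqs <- rep$sequences
  } else {
    seqs <- as_sequences(rep)
  }
  k <- K$k

  occ <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq(k, n))
  }), use.names = FALSE)
  if (is.null(occ)) occ <- character(0)
  if (K$model == "bi" && length(occ)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(occ)))
    occ <- ifelse(occ <= rc, occ, rc)
  }
  tab <- table(occ)
  seen <- names(tab)
  missing <- setdiff(K$kmers, seen)
  extra <- setdiff(seen, K$kmers)
  dup <- tab[tab > 1L]
  duplicated <- setNames(as.integer(dup), names(dup))

  structure(list(
    passed = length(missing) == 0L && length(extra) == 0L &&
      length(duplicated) == 0L,
    missing = missing, extra = extra, duplicated = duplicated
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  if (x$passed) {
    cat("verification PASSED: every k-mer present exactly once\n")
  } else {
    cat(sprintf("verification FAILED: %d missing, %d extra, %d duplicated\n",
                length(x$missing), length(x$extra), length(x$duplicated)))
    show <- function(lab, v) {
      if (length(v))
        cat("  ", lab, ": ", paste(head(v, 5), collapse = " "),
            if (length(v) > 5) "..." else "", "\n", sep = "")
    }
    show("missing", x$missing)
    show("extra", x$extra)
    if (length(x$duplicated))
      cat("  duplicated: ",
          paste(sprintf("%s(x%d)", head(names(x$duplicated), 5),
                        head(x$duplicated, 5)), collapse = " "),
          if (length(x$duplicated) > 5) "..." else "", "\n", sep = "")
  }
  invisible(x)
}
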