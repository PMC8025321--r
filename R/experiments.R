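#' NS/CL scaling across k-mer lengths
#'
#' Computes maximal simplitigs and maximal unitigs of one genome for every
#' k in a range and tabulates NS, CL and the number of distinct k-mers
#' (the CL lower bound). On random genomes the unitig NS peaks near
#' k = log4(G): below that k nearly all 4^k k-mers occur and the graph
#' branches at almost every node, so unitigs fragment towards single
#' k-mers, while simplitigs keep compacting through the branching nodes.
#'
#' @param genome A single sequence (string) or anything accepted by
#'   [build_kmer_set()].
#' @param k_range Integer vector of k values, each in `[1, 32]`.
#' @param model Strand model, `"uni"` or `"bi"`.
#' @param policy [extension_policy()] for the simplitig computation.
#' @return Data frame with one row per k: `k`, `n_kmers`, `ns_simplitigs`,
#'   `cl_simplitigs`, `ns_unitigs`, `cl_unitigs`.
#' @export
k_scaling_experiment <- function(genome, k_range, model = c("uni", "bi"),
                                 policy = extension_policy()) {
  model <- match.arg(model)
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (any(k_range < 1 | k_range > 32)) stop("k_range must lie within [1, 32]")
  rows <- lapply(as.integer(k_range), function(k) {
    K <- build_kmer_set(genome, k = k, model = model)
    s <- stats_of(compute_simplitigs(K, policy), K)
    u <- stats_of(compute_unitigs(K), K)
    data.frame(k = k, n_kmers = s$n_kmers,
               ns_simplitigs = s$NS, cl_simplitigs = s$CL,
               ns_unitigs = u$NS, cl_unitigs = u$CL)
  })
  do.call(rbind, rows)
}

#' NS/CL scaling across pan-genome size
#'
#' Simulates a pan-genome collection, then for an increasing number of
#' merged genomes computes both representations of the union k-mer set and
#' the NS/CL reduction ratios of simplitigs over unitigs. The benefit of
#' simplitigs grows with the number of genomes included, because added
#' within-species variation adds branching nodes.
#'
#' @param cfg A [pangenome_config()].
#' @param k k-mer length.
#' @param checkpoints Non-decreasing genome counts at which to evaluate,
#'   each within `[1, cfg$n_genomes]`; defaults to every count.
#' @param model Strand model.
#' @param policy [extension_policy()] for the simplitig computation.
#' @return Data frame with one row per checkpoint: `n_genomes`, `n_kmers`,
#'   `ns_simplitigs`, `cl_simplitigs`, `ns_unitigs`, `cl_unitigs`,
#'   `ns_reduction`, `cl_reduction`.
#' @export
pangenome_scaling_experiment <- function(cfg, k,
                                         checkpoints = seq_len(cfg$n_genomes),
                                         model = c("bi", "uni"),
                                         policy = extension_policy()) {
  stopifnot(inherits(cfg, "pangenome_config"))
  model <- match.arg(model)
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) == 0L || any(is.na(checkpoints)))
    stop("checkpoints must be a non-empty integer vector")
  if (is.unsorted(checkpoints))
    stop("checkpoints must be non-decreasing")
  if (any(checkpoints < 1L | checkpoints > cfg$n_genomes))
    stop("checkpoints must lie within [1, n_genomes]")
  genomes <- simulate_pangenome(cfg)
  rows <- lapply(checkpoints, function(m) {
    K <- build_kmer_set(genomes[seq_len(m)], k = k, model = model)
    s <- stats_of(compute_simplitigs(K, policy), K)
    u <- stats_of(compute_unitigs(K), K)
    rr <- reduction_ratios(u, s)
    data.frame(n_genomes = m, n_kmers = s$n_kmers,
               ns_simplitigs = s$NS, cl_simplitigs = s$CL,
               ns_unitigs = u$NS, cl_unitigs = u$CL,
               ns_reduction = unname(rr["ns_ratio"]),
               cl_reduction = unname(rr["cl_ratio"]))
  })
  do.call(rbind, rows)
}

#' Bits-per-k-mer storage comparison
#'
#' For each input and k, compares three textual representations of the
#' de Bruijn graph — the cleaned input sequences themselves, maximal
#' unitigs, and maximal simplitigs — by their storage cost in bits per
#' distinct k-mer, before and after compression. Each representation is
#' written as a cleaned one-line FASTA with sequential integer headers.
#' Two uncompressed figures are reported: the sequence payload alone
#' (comparable to the exact 8-bit lower bound) and the whole FASTA file,
#' headers and newlines included. The 8-bit uncompressed and 2-bit
#' compressed reference values apply to textual representations; the
#' 2-bit line is a reference only.
#'
#' @param inputs Named list; each element is a set of sequences accepted
#'   by [build_kmer_set()] (character vector or record data frame).
#' @param k_values Integer vector of k-mer lengths.
#' @param model Strand model.
#' @param compressor Passed to [compressed_bits_per_kmer()]; `NULL`
#'   disables compression columns.
#' @param min_length Cleaning threshold for the input-sequence rows,
#'   see [clean_records()].
#' @param policy [extension_policy()] for the simplitig computation.
#' @return Data frame with one row per input x k x representation:
#'   `input`, `k`, `representation`, `n_kmers`, `NS`, `CL`,
#'   `payload_bits_per_kmer`, `file_bits_per_kmer`,
#'   `compressed_bits_per_kmer` (`NA` when disabled).
#' @export
storage_experiment <- function(inputs, k_values, model = c("bi", "uni"),
                               compressor = "xz", min_length = 18,
                               policy = extension_policy()) {
  model <- match.arg(model)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be a named list")
  rows <- list()
  for (nm in names(inputs)) {
    cleaned <- clean_records(inputs[[nm]], min_length = min_length)
    for (k in as.integer(k_values)) {
      K <- build_kmer_set(cleaned, k = k, model = model)
      reps <- list(
        assembly = cleaned$sequence,
        unitigs = compute_unitigs(K)$sequences,
        simplitigs = compute_simplitigs(K, policy)$sequences
      )
      for (rep_name in names(reps)) {
        seqs <- reps[[rep_name]]
        fa <- tempfile(fileext = ".fa")
        write_fasta(setNames(seqs, seq_along(seqs)), fa, line_width = 0)
        file_bytes <- file.info(fa)$size
        payload <- sum(nchar(seqs))
        nk <- length(K$kmers)
        rows[[length(rows) + 1L]] <- data.frame(
          input = nm, k = k, representation = rep_name,
          n_kmers = nk, NS = length(seqs), CL = payload,
          payload_bits_per_kmer = if (nk) bits_per_kmer(payload, nk)
                                  else NA_real_,
          file_bits_per_kmer = if (nk) bits_per_kmer(file_bytes, nk)
                               else NA_real_,
          compressed_bits_per_kmer =
            if (!is.null(compressor) && nk)
              compressed_bits_per_kmer(fa, nk, compressor)
            else NA_real_)
        unlink(fa)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
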