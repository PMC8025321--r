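#' NS/CL statistics of a representation
#'
#' For any representation carrying each k-mer exactly once, the number of
#' sequences (NS) and their cumulative length (CL) obey the identity
#' `CL = n_kmers + (k - 1) * NS`: each sequence spells its k-mers plus one
#' (k-1)-overhang. NS is bounded by 1 and `n_kmers`, CL by `n_kmers` and
#' `k * n_kmers`; the upper bounds are attained at maximal fragmentation,
#' where every k-mer forms its own sequence, and the lower bounds by a
#' single sequence containing all k-mers.
#'
#' @param rep A `representation`.
#' @param K The [kmer_set()] it represents; must share `k` and strand
#'   model.
#' @return A `representation_stats` object: list with `kind`, `k`, `model`,
#'   `NS`, `CL`, `n_kmers`, `eq1_residual` (`CL - (n_kmers + (k-1)*NS)`,
#'   zero for exactly-once representations), `ns_bounds_ok`,
#'   `cl_bounds_ok`, and `bits_per_kmer_uncompressed` (`8 * CL / n_kmers`,
#'   the sequence-payload storage cost).
#' @examples
#' K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
#' stats_of(compute_simplitigs(K), K)
#' @export
stats_of <- function(rep, K) {
  stopifnot(inherits(rep, "representation"), inherits(K, "kmer_set"))
  if (rep$k != K$k) stop("k mismatch: ", rep$k, " vs ", K$k)
  if (rep$model != K$model)
    stop("strand model mismatch: ", rep$model, " vs ", K$model)
  NS <- length(rep$sequences)
  CL <- sum(nchar(rep$sequences))
  n_kmers <- length(K$kmers)
  structure(list(
    kind = rep$kind, k = K$k, model = K$model,
    NS = NS, CL = CL, n_kmers = n_kmers,
    eq1_residual = CL - (n_kmers + (K$k - 1L) * NS),
    ns_bounds_ok = if (n_kmers == 0L) NS == 0L else
      (NS >= 1L && NS <= n_kmers),
    cl_bounds_ok = if (n_kmers == 0L) CL == 0L else
      (CL >= n_kmers && CL <= K$k * n_kmers),
    bits_per_kmer_uncompressed = if (n_kmers > 0L) 8 * CL / n_kmers else NA_real_
  ), class = "representation_stats")
}

#' @export
print.representation_stats <- function(x, ...) {
  cat(sprintf(
    "%s stats (k = %d, %s): NS = %d, CL = %d, #kmers = %d\n",
    x$kind, x$k, x$model, x$NS, x$CL, x$n_kmers))
  cat(sprintf("  CL = #kmers + (k-1)*NS residual: %d; bounds ok: NS %s, CL %s\n",
              x$eq1_residual, x$ns_bounds_ok, x$cl_bounds_ok))
  if (!is.na(x$bits_per_kmer_uncompressed))
    cat(sprintf("  payload bits per distinct k-mer: %.3f\n",
                x$bits_per_kmer_uncompressed))
  invisible(x)
}

#' @export
as.data.frame.representation_stats <- function(x, ...) {
  data.frame(kind = x$kind, k = x$k, model = x$model, NS = x$NS, CL = x$CL,
             n_kmers = x$n_kmers, eq1_residual = x$eq1_residual,
             ns_bounds_ok = x$ns_bounds_ok, cl_bounds_ok = x$cl_bounds_ok,
             bits_per_kmer_uncompressed = x$bits_per_kmer_uncompressed)
}

#' NS and CL reduction ratios of simplitigs over unitigs
#'
#' @param unitig_stats,simplitig_stats [stats_of()] results computed
#'   against the same k-mer set.
#' @return Named numeric vector `c(ns_ratio, cl_ratio)` with
#'   `NS(unitigs)/NS(simplitigs)` and `CL(unitigs)/CL(simplitigs)`; both
#'   are at least 1 for maximal simplitigs in the uni-directed model.
#' @export
reduction_ratios <- function(unitig_stats, simplitig_stats) {
  stopifnot(inherits(unitig_stats, "representation_stats"),
            inherits(simplitig_stats, "representation_stats"))
  if (unitig_stats$n_kmers != simplitig_stats$n_kmers ||
      unitig_stats$k != simplitig_stats$k)
    stop("stats must be computed against the same k-mer set")
  if (simplitig_stats$NS == 0L || simplitig_stats$CL == 0L)
    stop("reduction ratios are undefined for an empty representation")
  c(ns_ratio = unitig_stats$NS / simplitig_stats$NS,
    cl_ratio = unitig_stats$CL / simplitig_stats$CL)
}

#' Bits per distinct k-mer
#'
#' Storage cost of a representation: `8 * payload_bytes / n_kmers`. For the
#' raw sequence characters of an exactly-once representation this equals
#' `8 * CL / n_kmers`, which is at least 8 bits and approaches 8 as the
#' per-sequence (k-1)-overhang becomes negligible.
#'
#' @param payload_bytes Byte count of the stored payload.
#' @param n_kmers Number of distinct k-mers (>= 1).
#' @return Bits per distinct k-mer.
#' @export
bits_per_kmer <- function(payload_bytes, n_kmers) {
  if (length(n_kmers) != 1L || is.na(n_kmers) || n_kmers < 1)
    stop("n_kmers must be >= 1")
  8 * as.numeric(payload_bytes) / as.numeric(n_kmers)
}

#' Bits per distinct k-mer after standard compression
#'
#' Compresses a byte payload (typically a one-line FASTA file) with a
#' standard stream compressor at its best compression level and reports
#' `8 * compressed_bytes / n_kmers`. The reference line of 2 bits per
#' k-mer for compressed textual representations is a comparison point, not
#' a bound: highly redundant synthetic sequences can compress below it.
#'
#' @param x Payload: a raw vector, a single string, or a path to an
#'   existing file.
#' @param n_kmers Number of distinct k-mers (>= 1).
#' @param compressor `"xz"` (default, level 9), `"gzip"` or `"bzip2"`.
#' @return Bits per distinct k-mer after compression, or `NA` with a
#'   warning when the compressor is unavailable in this build of R.
#' @export
compressed_bits_per_kmer <- function(x, n_kmers, compressor = "xz") {
  if (length(n_kmers) != 1L || is.na(n_kmers) || n_kmers < 1)
    stop("n_kmers must be >= 1")
  bytes <- payload_bytes_of(x)
  nb <- tryCatch(compressed_size(bytes, compressor),
                 error = function(e) {
                   warning("compressor '", compressor,
                           "' unavailable, compressed rate disabled: ",
                           conditionMessage(e))
                   NA_real_
                 })
  8 * nb / as.numeric(n_kmers)
}

payload_bytes_of <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(readBin(x, "raw", n = file.info(x)$size))
  if (is.character(x))
    return(charToRaw(paste(x, collapse = "\n")))
  stop("payload must be a raw vector, a string, or a file path")
}

# size in bytes of `bytes` after compression at the best level
compressed_size <- function(bytes, compressor = c("xz", "gzip", "bzip2")) {
  compressor <- match.arg(compressor)
  tmp <- tempfile(fileext = paste0(".", compressor))
  on.exit(unlink(tmp))
  con <- switch(compressor,
                xz = xzfile(tmp, "wb", compression = 9),
                gzip = gzfile(tmp, "wb", compression = 9),
                bzip2 = bzfile(tmp, "wb", compression = 9))
  writeBin(bytes, con)
  close(con)
  as.numeric(file.info(tmp)$size)
}
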