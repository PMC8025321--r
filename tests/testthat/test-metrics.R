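test_that("stats_of computes NS, CL, residual and bound flags", {
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
  st <- stats_of(compute_simplitigs(K), K)
  expect_equal(st$NS, 2)
  expect_equal(st$CL, 7)
  expect_equal(st$eq1_residual, 0)
  expect_true(st$ns_bounds_ok && st$cl_bounds_ok)
  expect_equal(st$bits_per_kmer_uncompressed, 8 * 7 / 3)

  chainK <- build_kmer_set("ACGTT", 3, "uni")
  st2 <- stats_of(compute_simplitigs(chainK), chainK)
  expect_equal(st2$NS, 1)
  expect_equal(st2$CL, 5)
  expect_equal(st2$eq1_residual, 0)

  # maximal fragmentation: m non-overlapping k-mers kept as singletons
  frag_kmers <- c("AAA", "CCC", "GGG", "TTT")
  Kf <- kmer_set(3, "uni", frag_kmers)
  repf <- simplitigr:::new_representation("simplitigs", 3, "uni", frag_kmers)
  stf <- stats_of(repf, Kf)
  expect_equal(stf$NS, 4)           # = n_kmers, the NS upper bound
  expect_equal(stf$CL, 3 * 4)       # = k * n_kmers, the CL upper bound
  expect_equal(stf$eq1_residual, 0)
  expect_true(stf$ns_bounds_ok && stf$cl_bounds_ok)

  expect_error(stats_of(repf, kmer_set(4, "uni", "AAAA")), "k mismatch")
})

test_that("reduction ratios compare unitigs to simplitigs", {
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
  u <- stats_of(compute_unitigs(K), K)
  s <- stats_of(compute_simplitigs(K), K)
  rr <- reduction_ratios(u, s)
  expect_equal(unname(rr["ns_ratio"]), 3 / 2)
  expect_equal(unname(rr["cl_ratio"]), 9 / 7)
  expect_identical(unname(reduction_ratios(u, u)), c(1, 1))

  empty <- simplitigr:::new_representation("simplitigs", 3, "uni",
                                           character(0))
  se <- stats_of(empty, kmer_set(3, "uni"))
  expect_error(reduction_ratios(u, s2 <- se), "same k-mer set|undefined")
})

test_that("bits per k-mer follows the 8 CL / n_kmers closed forms", {
  expect_equal(bits_per_kmer(7, 3), 56 / 3)
  # single chain: CL = n_kmers + (k - 1), payload rate 8 * (1 + (k-1)/n)
  for (n in c(10, 1000)) {
    k <- 11
    expect_equal(bits_per_kmer(n + k - 1, n), 8 * (1 + (k - 1) / n))
  }
  expect_error(bits_per_kmer(10, 0), "n_kmers")
})

test_that("xz-compressed rate is deterministic and finite", {
  g <- random_genome(20000, 31)
  K <- build_kmer_set(g, 31, "bi")
  rep <- compute_simplitigs(K)
  fa <- tempfile(fileext = ".fa")
  write_fasta(rep, fa)
  a <- compressed_bits_per_kmer(fa, length(K))
  b <- compressed_bits_per_kmer(fa, length(K))
  expect_identical(a, b)
  expect_true(is.finite(a) && a > 0)
  # a random genome is incompressible below ~2 bits/base, so the rate sits
  # well above the 2-bit reference line here
  expect_gt(a, 2)
  unlink(fa)
  expect_error(compressed_bits_per_kmer(charToRaw("ACGT"), 0), "n_kmers")
})

test_that("merging two mergeable sequences drops NS by 1 and CL by k-1", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    len <- k + sample(2:20, 1)
    s <- random_genome(len, 9000 + i)
    if (length(unique(kmers_of_segment(s, k))) != len - k + 1) next
    cut <- sample(k:(len - 1), 1)
    parts <- c(substr(s, 1, cut), substr(s, cut - k + 2, len))
    K <- kmer_set(k, "uni", kmers_of_segment(s, k))
    split_rep <- simplitigr:::new_representation("simplitigs", k, "uni",
                                                 parts)
    merged_rep <- simplitigr:::new_representation("simplitigs", k, "uni", s)
    a <- stats_of(split_rep, K)
    b <- stats_of(merged_rep, K)
    expect_equal(a$NS - b$NS, 1)
    expect_equal(a$CL - b$CL, k - 1)
    expect_equal(a$eq1_residual, 0)
    expect_equal(b$eq1_residual, 0)
  }
})
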