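test_that("greedy simplitigs reproduce hand-executed small cases", {
  # branch at ACG: forward absorbs CGA, CGT is left unextendable
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
  r <- compute_simplitigs(K)
  expect_identical(r$sequences, c("ACGA", "CGT"))

  # single non-branching chain
  K2 <- build_kmer_set("ACGTT", 3, "uni")
  expect_identical(compute_simplitigs(K2)$sequences, "ACGTT")

  # 3-cycle covered by one path from the seed
  K3 <- kmer_set(3, "uni", c("ACG", "CGA", "GAC"))
  r3 <- compute_simplitigs(K3)
  expect_identical(r3$sequences, "ACGAC")
  expect_equal(sum(nchar(r3$sequences)), 3 + (3 - 1) * 1) # CL identity

  # empty set is not an error
  expect_length(compute_simplitigs(kmer_set(5, "uni"))$sequences, 0)
})

test_that("maximal unitigs stop at branching nodes and break cycles", {
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
  expect_setequal(compute_unitigs(K)$sequences, c("ACG", "CGA", "CGT"))

  K2 <- build_kmer_set("ACGTT", 3, "uni")
  expect_identical(compute_unitigs(K2)$sequences, "ACGTT")

  # isolated cycle: broken at the smallest packed code (ACG)
  K3 <- kmer_set(3, "uni", c("ACG", "CGA", "GAC"))
  expect_identical(compute_unitigs(K3)$sequences, "ACGAC")

  expect_length(compute_unitigs(kmer_set(5, "bi"))$sequences, 0)
})

test_that("outputs conserve k-mers exactly once across random instances", {
  for (seed in 1:30) {
    inst <- random_instance(seed, G_max = 2e4)
    s <- compute_simplitigs(inst$K)
    u <- compute_unitigs(inst$K)
    expect_true(verify(s, inst$K)$passed,
                info = sprintf("simplitigs seed=%d k=%d model=%s", seed,
                               inst$k, inst$model))
    expect_true(verify(u, inst$K)$passed,
                info = sprintf("unitigs seed=%d k=%d model=%s", seed,
                               inst$k, inst$model))
  }
})

test_that("unitigs refine simplitigs in the uni-directed model", {
  for (seed in 31:45) {
    inst <- random_instance(seed, G_max = 2e4, models = "uni")
    s <- compute_simplitigs(inst$K)
    u <- compute_unitigs(inst$K)
    expect_lte(length(s$sequences), length(u$sequences))
    expect_lte(sum(nchar(s$sequences)), sum(nchar(u$sequences)))
    expect_true(refinement_ok(s$sequences, u$sequences, inst$k))
  }
})

test_that("greedy output is deterministic under a fixed seed order", {
  inst <- random_instance(101, G_max = 5e3)
  expect_identical(compute_simplitigs(inst$K)$sequences,
                   compute_simplitigs(inst$K)$sequences)
  p1 <- extension_policy("random", seed = 9)
  p2 <- extension_policy("random", seed = 9)
  expect_identical(compute_simplitigs(inst$K, p1)$sequences,
                   compute_simplitigs(inst$K, p2)$sequences)
  # a different random seed still conserves the k-mer content
  p3 <- extension_policy("random", seed = 10)
  expect_true(verify(compute_simplitigs(inst$K, p3), inst$K)$passed)
})

test_that("greedy simplitigs are maximal in the uni-directed model", {
  for (seed in 46:60) {
    inst <- random_instance(seed, G_max = 5e3, models = "uni")
    s <- compute_simplitigs(inst$K)
    res <- is_maximal(s, inst$K)
    expect_true(res$maximal,
                info = sprintf("seed=%d k=%d", seed, inst$k))
  }
})

test_that("is_maximal reports mergeable pairs and rejects bad input", {
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))
  good <- compute_simplitigs(K)
  expect_true(is_maximal(good, K)$maximal)

  # singleton decomposition: ACG -> CGA is a mergeable pair
  frag <- simplitigr:::new_representation("simplitigs", 3, "uni",
                                          c("ACG", "CGA", "CGT"))
  res <- is_maximal(frag, K)
  expect_false(res$maximal)
  expect_true(any(res$violations$from_seq == 1 & res$violations$to_seq == 2))

  chainK <- build_kmer_set("ACGTT", 3, "uni")
  expect_true(is_maximal(compute_simplitigs(chainK), chainK)$maximal)

  # failing exactly-once verification is rejected before checking
  bad <- simplitigr:::new_representation("simplitigs", 3, "uni", "ACGA")
  expect_error(is_maximal(bad, K), "exactly once")
})

test_that("alternative nucleotide orders change paths, not content", {
  inst <- random_instance(202, G_max = 3e3, models = "uni")
  pol <- extension_policy(nucleotide_order = "TGCA")
  r <- compute_simplitigs(inst$K, pol)
  expect_true(verify(r, inst$K)$passed)
  expect_error(extension_policy(nucleotide_order = "AACG"), "permutation")
})
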