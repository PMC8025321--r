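test_that("verify classifies correct, missing and duplicated content", {
  K <- kmer_set(3, "uni", c("ACG", "CGA", "CGT"))

  ok <- verify(simplitigr:::new_representation("simplitigs", 3, "uni",
                                               c("ACGA", "CGT")), K)
  expect_true(ok$passed)

  miss <- verify(simplitigr:::new_representation("simplitigs", 3, "uni",
                                                 c("ACG", "CGT")), K)
  expect_false(miss$passed)
  expect_identical(miss$missing, "CGA")
  expect_length(miss$extra, 0)

  dup <- verify(simplitigr:::new_representation("simplitigs", 3, "uni",
                                                c("ACGA", "ACG")), K)
  expect_false(dup$passed)
  expect_identical(names(dup$duplicated), "ACG")
  expect_identical(unname(dup$duplicated["ACG"]), 2L)
  expect_identical(dup$missing, "CGT")
})

test_that("verify counts canonical occurrences in the bi-directed model", {
  K <- build_kmer_set("ACGT", 3, "bi") # one canonical member, ACG
  # CGT is the reverse complement of ACG: same canonical k-mer twice
  twice <- simplitigr:::new_representation("simplitigs", 3, "bi",
                                           c("ACG", "CGT"))
  res <- verify(twice, K)
  expect_false(res$passed)
  expect_identical(names(res$duplicated), "ACG")

  once <- simplitigr:::new_representation("simplitigs", 3, "bi", "CGT")
  expect_true(verify(once, K)$passed)
})

test_that("verify rejects mismatched k or strand model", {
  K <- kmer_set(3, "uni", "ACG")
  rep_bi <- simplitigr:::new_representation("simplitigs", 3, "bi", "ACG")
  expect_error(verify(rep_bi, K), "model mismatch")
  rep_k4 <- simplitigr:::new_representation("simplitigs", 4, "uni", "ACGT")
  expect_error(verify(rep_k4, K), "k mismatch")
})

test_that("injected corruption is always detected and classified", {
  set.seed(1234)
  for (i in 1:15) {
    inst <- random_instance(600 + i, G_max = 3e3)
    rep <- compute_simplitigs(inst$K)
    if (length(rep$sequences) == 0 || length(inst$K$kmers) < 3) next
    seqs <- rep$sequences

    # delete one whole sequence: its k-mers go missing
    del <- seqs[-1]
    res <- verify(simplitigr:::new_representation("simplitigs", inst$k,
                                                  inst$model, del), inst$K)
    expect_false(res$passed)
    expect_gt(length(res$missing), 0)

    # duplicate one sequence: duplicated multiplicities appear
    dup <- c(seqs, seqs[1])
    res <- verify(simplitigr:::new_representation("simplitigs", inst$k,
                                                  inst$model, dup), inst$K)
    expect_false(res$passed)
    expect_gt(length(res$duplicated), 0)

    # mutate one base across the A/T vs C/G divide, so the canonical
    # k-mer multiset cannot be preserved in either strand model
    s1 <- seqs[1]
    p <- sample(nchar(s1), 1)
    b <- if (substr(s1, p, p) %in% c("A", "T")) "C" else "A"
    substr(s1, p, p) <- b
    mut <- c(s1, seqs[-1])
    res <- verify(simplitigr:::new_representation("simplitigs", inst$k,
                                                  inst$model, mut), inst$K)
    expect_false(res$passed)
    expect_gt(length(res$missing) + length(res$extra) +
                length(res$duplicated), 0)
  }
})
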