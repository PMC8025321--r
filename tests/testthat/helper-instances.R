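# fixture builders shared across test files; everything is generated in code

# one random genome instance: k-mer set plus the genome it came from
random_instance <- function(seed, G_min = 100, G_max = 1e5,
                            k_range = 3:32, models = c("uni", "bi")) {
  set.seed(seed)
  G <- round(10^runif(1, log10(G_min), log10(G_max)))
  k <- sample(k_range, 1)
  model <- sample(models, 1)
  genome <- random_genome(G, seed + 7919L)
  list(G = G, k = k, model = model, genome = genome,
       K = build_kmer_set(genome, k = k, model = model))
}

all_kmers_of_length <- function(k) {
  apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k)), 1,
        paste, collapse = "")
}

# catalogue of small uni-directed k-mer sets (<= 10 members) for comparing
# the greedy heuristic with the exhaustive path-cover oracle
oracle_catalogue <- function() {
  out <- list()
  add <- function(k, kmers) out[[length(out) + 1L]] <<-
    kmer_set(k, "uni", unique(kmers))
  # structured shapes: branch, cycle, chain, isolated nodes, self-loop
  add(3, c("ACG", "CGA", "CGT"))
  add(3, c("ACG", "CGA", "GAC"))
  add(3, kmers_of_segment("ACGTTAGC", 3))
  add(3, c("AAA", "CCC", "GGG", "TTT"))
  add(2, c("AC", "CA", "CG", "GC"))
  add(4, kmers_of_segment("ACGTACGA", 4))
  add(3, c("AAA", "AAC", "ACA", "CAA"))
  # random subsets of the full k-mer universe (dense, highly branching)
  set.seed(42)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    m <- sample(2:10, 1)
    add(k, sample(all_kmers_of_length(k), m))
  }
  # k-mer sets of short random genomes (sparse, chain-like)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    g <- random_genome(sample(8:14, 1), 1000L + i)
    km <- unique(kmers_of_segment(g, k))
    if (length(km) <= 10) add(k, km)
  }
  out
}

# map each unitig onto the simplitig containing it; TRUE iff every maximal
# unitig occurs within exactly one simplitig (uni mode: k-mer uniqueness
# across simplitigs makes "exactly one" equivalent to "at the position of
# its first k-mer"). Unitigs are only defined up to the linearization
# point of cycles, and a greedy simplitig may enter a cycle mid-unitig, so
# when the hosting simplitig spells a cyclic path (its (k-1)-prefix equals
# its (k-1)-suffix) containment is checked in the circular reading.
refinement_ok <- function(simplitigs, unitigs, k) {
  occ <- lapply(simplitigs, function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - k + 1L), seq(k, n))
  })
  seq_id <- rep(seq_along(simplitigs), lengths(occ))
  pos <- unlist(lapply(occ, seq_along), use.names = FALSE)
  all_occ <- unlist(occ, use.names = FALSE)
  first <- substring(unitigs, 1L, k)
  idx <- match(first, all_occ)
  if (anyNA(idx)) return(FALSE)
  ok <- vapply(seq_along(unitigs), function(j) {
    s <- simplitigs[seq_id[idx[j]]]
    p <- pos[idx[j]]
    len <- nchar(unitigs[j])
    if (p + len - 1L <= nchar(s) && substr(s, p, p + len - 1L) == unitigs[j])
      return(TRUE)
    cyclic <- substr(s, 1L, k - 1L) ==
      substr(s, nchar(s) - k + 2L, nchar(s))
    if (!cyclic) return(FALSE)
    ext <- paste0(s, substring(s, k)) # circular continuation
    p + len - 1L <= nchar(ext) && substr(ext, p, p + len - 1L) == unitigs[j]
  }, logical(1))
  all(ok)
}

random_kmer_strings <- function(n, k, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    "")
}
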