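#' Random genome
#'
#' A uniform i.i.d. ACGT string, reproducible under a seed. The global RNG
#' state is left untouched.
#'
#' @param G Genome length in bases (>= 1).
#' @param seed Integer seed.
#' @return A single string of length `G`.
#' @export
random_genome <- function(G, seed) {
  if (length(G) != 1L || is.na(G) || G < 1) stop("G must be >= 1")
  with_preserved_rng(seed, {
    paste(sample(c("A", "C", "G", "T"), G, replace = TRUE), collapse = "")
  })
}

#' Pan-genome simulation configuration
#'
#' Describes a synthetic pan-genome: one random base genome plus mutated
#' copies, emulating a collection of within-species isolate assemblies.
#' Substitutions are the default mutation process — they are what creates
#' branching nodes in the union de Bruijn graph, the phenomenon under
#' study; indels can be enabled but default to 0.
#'
#' @param G Base genome length in bases.
#' @param n_genomes Number of genomes in the collection (the base genome
#'   included).
#' @param mu Per-base substitution probability applied independently to
#'   each derived genome, in `[0, 1]`.
#' @param seed Integer seed.
#' @param indel_rate Per-base probability of a single-base insertion or
#'   deletion (split evenly), in `[0, 1]`; default 0.
#' @return A `pangenome_config` object.
#' @export
pangenome_config <- function(G, n_genomes, mu, seed, indel_rate = 0) {
  if (G < 1) stop("G must be >= 1")
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  if (is.na(mu) || mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if (is.na(indel_rate) || indel_rate < 0 || indel_rate > 1)
    stop("indel_rate must be in [0, 1]")
  structure(list(G = as.integer(G), n_genomes = as.integer(n_genomes),
                 mu = mu, seed = as.integer(seed), indel_rate = indel_rate),
            class = "pangenome_config")
}

#' Simulate a pan-genome collection
#'
#' Genome 1 is a uniform random genome; every further genome applies
#' i.i.d. substitutions to it at rate `mu`, the substituted base drawn
#' uniformly from the three alternatives (plus optional indels). Output is
#' reproducible under the configuration's seed.
#'
#' @param cfg A [pangenome_config()].
#' @return Character vector of `n_genomes` sequences; element 1 is the
#'   base genome.
#' @export
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "pangenome_config"))
  base <- random_genome(cfg$G, cfg$seed)
  if (cfg$n_genomes == 1L) return(base)
  bases <- c("A", "C", "G", "T")
  with_preserved_rng(cfg$seed + 1L, {
    genomes <- c(base, vapply(seq_len(cfg$n_genomes - 1L), function(i) {
      g <- strsplit(base, "")[[1]]
      hit <- which(runif(cfg$G) < cfg$mu)
      if (length(hit)) {
        cur <- g[hit]
        g[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      }
      if (cfg$indel_rate > 0) {
        r <- runif(length(g))
        del <- r < cfg$indel_rate / 2
        ins <- r >= cfg$indel_rate / 2 & r < cfg$indel_rate
        if (any(ins))
          g[ins] <- paste0(g[ins], sample(bases, sum(ins), replace = TRUE))
        if (any(del)) g <- g[!del]
      }
      paste(g, collapse = "")
    }, ""))
    genomes
  })
}

#' Brute-force minimum vertex-disjoint path cover
#'
#' Exhaustive oracle for tiny de Bruijn graphs: the minimum number of
#' vertex-disjoint paths covering all nodes, the optimum that the greedy
#' simplitig heuristic approximates. Covering n nodes with paths built from
#' e compatible edges needs n - e paths, so the search maximises the number
#' of edges that can be selected such that every node keeps in- and
#' out-degree at most 1 and no cycle closes — a depth-first search over
#' edge subsets with pruning, entirely independent of the greedy code path.
#' Only the uni-directed model is supported.
#'
#' @param K A [kmer_set()] with at most 12 members, uni-directed model.
#' @return The minimum NS over all exactly-once path-cover representations
#'   of `K`.
#' @examples
#' min_path_cover_bruteforce(kmer_set(3, "uni", c("ACG", "CGA", "CGT"))) # 2
#' @export
min_path_cover_bruteforce <- function(K) {
  stopifnot(inherits(K, "kmer_set"))
  if (K$model != "uni")
    stop("the brute-force oracle supports the uni-directed model only")
  n <- length(K$kmers)
  if (n > 12L)
    stop("brute-force path cover limited to sets of at most 12 k-mers; got ",
         n)
  if (n == 0L) return(0L)
  k <- K$k
  km <- K$kmers
  # edges by (k-1)-overlap, computed from the strings directly
  suf <- substring(km, 2L, k)
  pre <- substring(km, 1L, k - 1L)
  eu <- integer(0); ev <- integer(0)
  for (u in seq_len(n)) {
    hit <- which(pre == suf[u])
    hit <- hit[hit != u] # self-loops never sit on a vertex-disjoint path
    eu <- c(eu, rep(u, length(hit))); ev <- c(ev, hit)
  }
  m <- length(eu)
  if (m == 0L) return(n)

  best <- 0L
  out_used <- logical(n); in_used <- logical(n)
  # path bookkeeping: pstart[x] = start of the path ending at x,
  # pend[x] = end of the path starting at x (identity for isolated nodes)
  pstart <- seq_len(n); pend <- seq_len(n)

  recurse <- function(i, count) {
    if (count > best) best <<- count
    if (i > m) return(invisible(NULL))
    if (count + (m - i + 1L) <= best) return(invisible(NULL)) # bound
    u <- eu[i]; v <- ev[i]
    if (!out_used[u] && !in_used[v] && pstart[u] != v) {
      # include edge u -> v: merge the path ending at u with the one
      # starting at v
      a <- pstart[u]; b <- pend[v]
      out_used[u] <<- TRUE; in_used[v] <<- TRUE
      pstart[b] <<- a; pend[a] <<- b
      recurse(i + 1L, count + 1L)
      out_used[u] <<- FALSE; in_used[v] <<- FALSE
      pstart[b] <<- v; pend[a] <<- u
    }
    recurse(i + 1L, count)
  }
  recurse(1L, 0L)
  n - best
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
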