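---
title: "Simplitigs: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplitigs: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplitigr)
```

## The model

A node-centric de Bruijn graph over the alphabet {A, C, G, T} is the
directed graph whose nodes are the distinct k-mers of a dataset, with an
edge $u \to v$ whenever the $(k-1)$-suffix of $u$ equals the
$(k-1)$-prefix of $v$. Edges are implicit, so the graph and its k-mer set
are interchangeable. Any set of strings whose k-mer content equals the
node set, with every k-mer occurring exactly once, is a loss-free textual
representation of the graph.

*Unitigs* are spellings of paths whose internal nodes have in-degree 1 and
whose non-terminal nodes have out-degree 1; maximal unitigs stop at
branching nodes. *Simplitigs* drop that restriction: they are spellings of
the paths of an arbitrary vertex-disjoint path cover, so they keep
compacting straight through branching nodes. Every unitig is a simplitig;
neither needs to be maximal. A simplitig set is quantified by its number
of sequences (NS) and cumulative length (CL), which for exactly-once
representations are locked together by

$$\mathrm{CL} = \#\mathit{kmers} + (k - 1)\,\mathrm{NS},$$

because each sequence spells its k-mers plus one $(k-1)$-base overhang.
Minimising NS therefore minimises CL and vice versa; the exact optimum is
the minimum vertex-disjoint path cover, NP-hard in general, so the package
uses a greedy heuristic.

### The greedy algorithm

`compute_simplitigs()` repeatedly draws the next unused k-mer as the seed
of a new simplitig, extends it forward one base at a time — the four
candidate k-mers formed from the current $(k-1)$-suffix are tested in a
fixed nucleotide order and the first member of the working set wins — and,
once forward extension is exhausted, extends backward symmetrically. Every
matched k-mer, the seed included, is removed from the working set the
moment it is used, which guarantees the exactly-once property by
construction. The loop ends when the working set is empty. Work is linear
in the number of k-mers; k-mers are held as 2-bit-packed 64-bit codes
(A=0, C=1, G=2, T=3, so integer order on codes equals lexicographic order
on strings) in a hash set, which restricts $k$ to $[1, 32]$ — larger
values are rejected, never truncated.

The output is not unique: at a branching node the chosen edge depends on
the nucleotide order, and the decomposition depends on where seeds land.
The extension order is fixed at A,C,G,T (configurable as any permutation
via `extension_policy()`), so the seed order is the only source of
variability. The default is ascending packed code, chosen for
cross-platform determinism; `insertion` and seeded `random` orders exist
to study the (small) spread in NS/CL that seed placement induces.

### Strand models

In the uni-directed model every k-mer is its own node. Sequencing data is
strand-ambiguous, so the default bi-directed model identifies each k-mer
with its reverse complement through the canonical form, the lexicographic
minimum of the pair. During extension the growing simplitig is kept in its
emitted orientation while membership and removal act on canonical codes; a
k-mer can thus be consumed through either orientation, and palindromic
k-mers (possible only for even $k$) are ordinary members consumed once.

### Unitigs and cycles

`compute_unitigs()` compacts a node into its predecessor's unitig exactly
when the connecting edge is the unique continuation on both sides
(out-degree 1 at the tail, in-degree 1 at the head; degrees are taken per
traversal orientation in the bi-directed model). An isolated cycle has
every degree equal to 1 and hence no canonical start; it is linearized at
the node with the smallest packed code, a deterministic tie-break.
Unitigs are unique only up to sequence order, reverse complementation and
this choice of cycle break point.

That last ambiguity matters for the refinement property. In the
uni-directed model every maximal unitig lies inside exactly one maximal
simplitig — a unitig's interior can only be entered through its own chain,
and a time-ordering argument over the greedy loop shows its k-mers can
never be split across two simplitigs. But when a simplitig covers a cyclic
component it may enter mid-unitig and wrap around, in which case the
unitig is contiguous only in the *circular* reading of that simplitig
(recognisable by the simplitig's $(k-1)$-prefix equalling its
$(k-1)$-suffix). The package's tests check containment in exactly one
simplitig with circular containment accepted for cyclic simplitigs, and
strict substring containment otherwise; on randomized suites the strict
reading holds for all unitigs outside cycles.

### Maximality

A simplitig set over the full k-mer set is maximal when no end can absorb
an unused k-mer (vacuous once all k-mers are used) and no two sequences
can be merged through a $(k-1)$-overlap. `is_maximal()` implements the
operational reading: a violation requires a merge partner in a *different*
sequence. A single simplitig closing a cycle onto itself nominally has an
in-edge onto its own first vertex, but no extension or merge is possible,
so it is not reported as a violation. In the bi-directed model both
orientations of every sequence are considered when pairing ends; because
the literature leaves bi-directed maximality semantics around palindromes
under-determined, the randomized bi-mode tests assert conservation and
NS/CL bounds rather than strict maximality.

### Verification

`verify()` is deliberately independent of the construction code: it slices
k-mers out of the emitted strings with plain substring arithmetic,
canonicalizes through `Biostrings::reverseComplement()` rather than the
package's own encoder, and counts occurrences. A representation passes iff
nothing is missing, nothing foreign appears, and nothing occurs twice.
This mirrors the field's practice of validating assemblies with an
external k-mer counter.

## Metrics and storage accounting

`stats_of()` reports NS, CL, the identity residual
$\mathrm{CL} - (\#\mathit{kmers} + (k-1)\mathrm{NS})$ (zero for any
exactly-once representation), bound flags
($1 \le \mathrm{NS} \le \#\mathit{kmers}$,
$\#\mathit{kmers} \le \mathrm{CL} \le k\,\#\mathit{kmers}$), and the
payload storage rate $8\,\mathrm{CL}/\#\mathit{kmers}$ bits per distinct
k-mer, which is bounded below by 8 and approaches it as
$\mathrm{NS}(k-1)/\#\mathit{kmers} \to 0$.

Storage is accounted two ways, both reported by `storage_experiment()`:
sequence payload only (clean, comparable to the exact 8-bit bound) and
whole FASTA file, headers and newlines included (matching byte-count
accounting of files on disk). Compressed rates use xz at its best level
(9) through base R's `xzfile()`; the 2-bit reference for compressed
textual representations is a comparison line only and is never asserted
as an inequality, because highly redundant synthetic collections — fifty
near-identical genomes, say — legitimately compress below it (the
mutation-free parts of a pan-genome are almost free once one copy is
stored).

## Synthetic data: what it emulates and what it does not

`random_genome()` draws uniform i.i.d. bases; `simulate_pangenome()`
derives further genomes by i.i.d. substitutions at rate `mu` per base
(default experiments use `mu = 0.005`, within-species distance on the
order of bacterial isolate collections; genome sizes of $10^4$–$2\times
10^5$ keep suites desk-scale). Substitutions are the default mutation
process because each one plants branching nodes in the union graph, which
is exactly the phenomenon that separates simplitigs from unitigs; an
`indel_rate` option exists but defaults to 0.

Uniform random sequence has no repeat structure, skewed composition,
gene content or horizontal transfer, so passing tests demonstrate
correctness of the algorithms and the qualitative scaling behaviour —
unitig NS peaking near $k = \log_4 G$ by edge saturation, the growing
NS/CL gap as genomes accumulate — not quantitative agreement with any
particular organism. Real collections can be substituted anywhere a
generator output is accepted, including through the CLI.

Two statistical checks deserve a note: the unitig-NS-peak location is
asserted as a majority over 5 seeds within $\pm 1$ of $\log_4 G$, and the
GC content of a megabase random genome within 49–51%; both are
law-of-large-numbers bounds with failure probabilities far below test
flakiness thresholds.

## The exhaustive oracle

`min_path_cover_bruteforce()` answers, for sets of at most 12 k-mers,
the exact minimum NS by depth-first search over edge subsets that keep
every in- and out-degree at most 1 and close no cycle (covering $n$ nodes
with $e$ selected edges costs $n - e$ paths). It recomputes edges from
string overlaps and shares nothing with the greedy code, which is the
point of an oracle. It supports the uni-directed model only; bi-directed
path cover would need an orientation-aware search that the test suite
does not require, since greedy-versus-optimum comparisons run on
uni-directed catalogues. On those catalogues the greedy heuristic attains
the optimum on roughly 9 of 10 instances and is never below it.

## Numerical and degenerate-input choices

* $k$ outside $[1, 32]$ is rejected with the supported range named.
* Non-ACGT characters (N, IUPAC codes, gaps) split sequences into
  segments; no k-mer ever spans an ambiguous position. Lowercase is
  folded to uppercase first. Empty records and records shorter than $k$
  contribute nothing and are not errors.
* An empty k-mer set yields an empty representation, not an error;
  ratios and bits-per-k-mer over zero k-mers are rejected as undefined.
* The FASTA cleaning protocol (`clean_records()`, CLI `clean`) splits at
  unknown nucleotides, drops segments under 18 bp by default, uppercases,
  and renames survivors to sequential integers; output FASTA is one-line
  by default so whole-file byte accounting is reproducible.
* Ties everywhere are broken deterministically: extension trials in
  A,C,G,T order, seeds in ascending packed code, cycle breaks at the
  smallest code.

## Problem sizes used by the shipped suites

The randomized test and acceptance suites use 200 genomes with lengths
log-uniform in $[10^2, 10^5]$ and $k \in [3, 32]$ under both strand
models; oracle catalogues hold ~120 sets of at most 10 k-mers; the
pan-genome experiment uses $G = 2\times 10^5$, 50 genomes,
`mu = 0.005`, $k = 31$; the storage comparison compresses the resulting
three representations with xz-9. These sizes were chosen so the full
behaviour — identity, conservation, bounds, refinement, scaling shape,
storage ordering — is exercised end to end on a single CPU in minutes.

## Known limitations

* No CL/NS-optimal simplitig search: the optimum is a minimum
  vertex-disjoint path cover, NP-hard in general; only the greedy
  heuristic and the tiny-instance oracle are provided.
* No k-mer counting or abundance filtering: input k-mer sets are taken
  as-is, so noisy read data should be pre-filtered elsewhere.
* No weighted or colored graphs, no streaming or low-memory variants,
  and no set operations over simplitig files.
* Bi-directed maximality around palindromic k-mers is checked only
  through conservation and bounds, as discussed above.
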