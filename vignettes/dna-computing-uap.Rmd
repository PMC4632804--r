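---
title: "Simulating a DNA molecular computation for the unbalanced assignment problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a DNA molecular computation for the unbalanced assignment problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnassign)
```

## The problem and the molecular idea

The unbalanced assignment problem (UAP) asks for a minimum-cost way of
assigning $n$ jobs to $m < n$ individuals so that every job is done exactly
once and every individual receives at least one job. As a 0–1 integer
program:

$$\min Z = \sum_{i=1}^{m}\sum_{j=1}^{n} c_{ij} x_{ij}
\quad\text{s.t.}\quad
\sum_{i=1}^{m} x_{ij} = 1 \;\forall j,\qquad
1 \le \sum_{j=1}^{n} x_{ij} \le n-m+1 \;\forall i,\qquad
x_{ij}\in\{0,1\}.$$

The upper load bound $n-m+1$ is implied by the others (all loads are at
least 1 and sum to $n$), but it is part of the feasibility contract that
`is_feasible()` checks.

The molecular approach trades time for massive parallelism. Every candidate
assignment is a DNA strand built from *edge units* $sA_ieB_j$ ("job $j$
goes to individual $i$"; $s$ and $e$ are delimiter words). Each of the
symbols $s$, $e$, $A_i$, $B_j$ is a distinct single-stranded DNA word of a
common unit length $t$ mer, so every edge unit is $4t$ mer. The computation
is then a fixed cascade of test-tube operations:

1. **Pool construction.** Hybridization of edge units with complementary
   junction linkers, ligation, and melting produce (after selecting the
   $4nt$-mer length class) all $(mn)^n$ strands of $n$ edges.
2. **Job completeness.** For each job $k$, motif separation with probe
   $(e, B_k)$ keeps strands mentioning job $k$; an $n$-edge strand
   containing all $n$ jobs contains each exactly once.
3. **Surjectivity.** For each individual $k$, separation with
   $(s, A_k, e)$ keeps strands in which individual $k$ appears.
4. **Cost encoding.** For each edge $(i,j)$, the strands containing it get
   a weight tail $w_{ij}$ of length $c_{ij}\cdot u$ mer appended. A
   feasible strand's length is then $4nt + u\,Z$: *length encodes cost*.
5. **Length selection.** Gel-style sorting extracts the shortest strands —
   exactly the minimum-cost assignments — and one is read out.

`solve_uap()` runs this cascade; each stage is also exported
(`generate_pool()`, `filter_jobs()`, `filter_individuals()`,
`append_weights()`, `select_shortest()`) on top of the twelve primitive
tube operations in the strand algebra.

```{r solve}
C <- read_cost_matrix(system.file("extdata", "uap_2x3_costs.csv",
                                  package = "dnassign"))
solve_uap(C)
```

## What is simulated, and what deliberately is not

The simulator is faithful to the *set semantics* of the tube operations,
not to the chemistry:

* **Annealing/ligation is not simulated at base-pair level.**
  `anneal_ligate_pool()` directly constructs the set of all $k$-edge
  concatenations — the set the hybridization chemistry is intended to
  produce once the full-length class is selected. Partial hybrids, hairpins
  and kinetics are out of scope; the sequence-design layer exists precisely
  to make such errors rare in a laboratory realization.
* **Motif separation acts on symbol atoms,** not nucleotides. Nucleotide-
  level matching only appears in the encoding layer (`encode_strand()`,
  `decode_sequence()`).
* **Tubes are multisets** (duplicates are representable and conserved
  exactly by every splitting operation), but the algorithm's answers depend
  only on supports; multiplicity is retained mainly so that conservation is
  testable.
* **`tube_read()` is deterministic.** The laboratory Read reports an
  arbitrary molecule; the simulator returns the lexicographically least
  strand (C-locale ordering of the token string) so runs are reproducible.
  For a solution tube this canonical strand lists its edges in row-major
  $(i,j)$ order, which is also the order `append_weights()` appends tails —
  so the read strand is the canonical printed form of the optimum.

Two readings of the separation primitive circulate (remove-matching versus
keep-matching); `separation()` returns both output tubes (`matched`,
`remaining`) so either is available, and conservation
(`matched` $\uplus$ `remaining` $=$ input) holds exactly.

When every strand in a tube has the same length, `sort_split()` reports the
whole tube as the *shortest* class and leaves the longest class empty: the
pipeline's only consumer of this operation is the final minimum extraction.
Similarly, the final step takes the **shortest** tube — with length
encoding cost, short is optimal — even though a literal composition of the
sort-then-read steps could be misread as taking the longest tube.

Two further interface choices deserve a note. The job-presence motif is
$(e, B_k)$ rather than the three-atom $(e, B_k, s)$: the trailing $s$ can
never follow the final edge of a strand, so the literal three-atom probe
would discard every strand; the two-atom probe is what reproduces the
published strand listings. The individual motif $(s, A_k, e)$ is always
interior to an edge and is used literally. And the surjectivity loop runs
over $k = 1..m$ individuals — its cost is the $O(m)$ term of the
complexity bound.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `t` | unit word length, mer | 5 | the published 3×5 design uses 5-mers; must be large enough that all $2+m+n$ unit words can be distinct |
| `u` | mer per unit cost | 1 | smallest integral length quantum; Theorem-3 bounds scale with $y = u\,\max c_{ij}$ |
| costs | nonnegative **integers** (pipeline) | — | lengths are integral; zero cost gives a zero-length weight atom whose cost is still tracked; the oracle also accepts real costs |
| `pool_cap` | refuse $(mn)^n$ above this | $10^7$ | the pool is materialized in memory; larger instances belong to `brute_force_min()` |
| `temperature` | duplex free-energy temperature | 310.15 K | physiological convention |

## Verification strategy

The pipeline is verified against an **independent oracle**:
`brute_force_min()` enumerates all $m^n$ job-to-individual mappings,
filters to surjections, and minimizes — it shares no code with the strand
machinery. The test suite checks exact agreement of the minimum *and* of
the full optimum set on hundreds of seeded random instances
($m\in\{2,3\}$, $n\in\{3,4,5\}$, integer costs 0–9), plus the two bundled
reference instances (2×3, where the intermediate tube contents are checked
strand-by-strand against the published listings; and 3×5, the headline
result with minimum cost 17).

Three structural properties are tested as invariants:

* **Stage counts.** $|{\rm pool}| = (mn)^n$, then $n!\,m^n$ after the job
  filter, then $n!\,S(m,n)$ after surjectivity, with
  $S(m,n) = \sum_k (-1)^k \binom{m}{k}(m-k)^n$ (`surjection_count()`).
* **Length window.** Every weighted strand length lies in
  $[4tn,\,(4t+y)n]$, $y = u\max c_{ij}$.
* **Operation count.** With one increment per primitive, a solve costs
  exactly $8 + 4n + 4m + 5mn$ operations (pool 6, job filter $4n$,
  surjectivity $4m$, cost appending $5mn$ — after the surjectivity filter
  every edge occurs in some strand, so the detect branch always fires —
  and 2 for sort+read). The tests fit the affine-in-$mn$ form across a grid
  of shapes rather than asserting the constant, which is what the $O(mn)$
  claim is about.

Because the generator produces uniform integer costs, ties are common; the
simulator therefore returns *all* cooptimal assignments (deduplicated from
the $n!$ strand orderings each optimum produces) and the tests compare the
full sets, not just the minima.

## Sequence design

`build_code()` maps each symbol to a concrete word under the classical
library constraints: three-letter alphabet (A/T/C — keeping G for the
probe side lowers library secondary structure), no homopolymer run longer
than four, and pairwise distinctness. Candidate words are drawn at random
and repaired by successive single-base mutations until the constraints
hold or a mutation budget is exhausted (`gen_codeword()`); the run is
seed-deterministic.

Weight words need a decision the printed tables leave open: the algorithm
requires $\|w_{ij}\| = c_{ij} u$ (lengths carry cost), while the published
codeword table prints all-5-mer weight words. Both are supported as modes
of `build_code()`:

* `"algorithmic"` — length-encoded; a zero cost is an empty word. Equal
  costs cannot receive distinct words of the same tiny length over a
  3-letter alphabet, and the tail's identity carries no information (only
  its length does), so weight words are exempt from the distinctness rule
  in this mode.
* `"labeled"` — all words are $t$-mers, distinctness applies to everything;
  this is the form used for printed tables and FASTA export.

`validate_code()` reports every violation; on the bundled 3×5 reference
codeword set it flags exactly one: two weight words share the word
`TTACA`, which the package treats as a defect of that set (kept verbatim in
the fixture). The optional probe rule (4–6 G per probe, aimed at uniform
melting temperatures) is off by default because 5-mer probes cannot
generally satisfy it; it is configurable for longer designs.

The nucleotide layer is bidirectional: `encode_strand()` concatenates
words in the printed 3'–5' orientation, and `decode_sequence()` parses
edges positionally and the weight tail against the grammar's expectation
(falling back to greedy longest-word matching), so encode/decode is an
identity on pipeline strands. Zero-length weight words are unrecoverable
from a nucleotide string by construction. `linker_and_probe_set()` exports
the reverse-complement junction linkers ($\overline{e B_j s}$) and job
probes used by the pool-assembly phase.

## Duplex thermodynamics

`duplex_energy()` scores the perfect-match duplex of a probe with its
library site by the nearest-neighbor model: enthalpy and entropy are sums
of stacked-dinucleotide contributions plus one initiation term per duplex
end, and $\Delta G = \Delta H - T\Delta S/1000$. The shipped parameter set
is the unified oligonucleotide table of SantaLucia (1998), stored as a
plain-text TSV and pluggable via `nn_params(path)`. Following the sign
convention of probe-binding tables, values are reported as positive binding
magnitudes. Reverse-complement symmetry holds exactly (the stack table is
closed under reverse complementation), and `energy_table()` reports one row
per edge strand plus mean/standard-deviation summary rows.

The package does not attempt to reproduce any particular published energy
table numerically: such tables depend on the exact parameter set and probe
registration used, which are not part of the model's interface. Salt
corrections, mismatches, dangling ends and melting curves are out of scope.

## Problem sizes

The simulator materializes the full $(mn)^n$ pool, which is the point of
the exercise — the "chemistry" is an exhaustive parallel search. The
default guard (`pool_cap = 1e7`) admits the 3×5 headline instance
($15^5 = 759{,}375$ strands, a few seconds) and everything smaller; the
test suite runs hundreds of full solves at these sizes. For anything
larger the exact oracle (or a real polynomial algorithm, out of scope
here) is the right tool, and the guard says so.

## Known limitations

* Exponential pool size is inherent; the simulator is a correctness tool
  for the molecular algorithm's logic, not a practical UAP solver.
* Compact strand text (`strand_from_text()`) is ambiguous for indices
  above 9; the internal dotted token form has no such limit.
* The synthetic instance generator draws i.i.d. uniform integer costs; it
  produces the tie structure and scale the tests need, but nothing like
  the correlated cost structure of real scheduling data, so passing tests
  speak to algorithmic correctness, not to field performance.
* `decode_sequence()` assumes the grammar layout produced by the pipeline;
  arbitrary tail permutations fall back to greedy matching, which can in
  principle mis-segment pathological length-encoded tails.
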