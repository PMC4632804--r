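# dnassign

An in-silico simulator of DNA molecular computing (the Adleman–Lipton
test-tube model) applied to the **unbalanced assignment problem**: assign
*n* jobs to *m* < *n* individuals so every job is done exactly once, every
individual gets at least one job, and the total cost

$$\min Z = \sum_{i=1}^{m}\sum_{j=1}^{n} c_{ij} x_{ij}$$

is minimized, where assignments are constrained by
$\sum_i x_{ij} = 1$ per job and individual loads in $[1, n-m+1]$.

The package is for people studying molecular/biological computation who
want an executable, *tested* model of the strand-filtering algorithm rather
than a wet-lab protocol: every tube operation is a real function, every
intermediate tube is inspectable, and the whole pipeline is verified
against an exact combinatorial oracle.

## The algorithm

Each candidate assignment is a DNA strand of edge units `s A_i e B_j`
("job *j* to individual *i*"); each symbol is a distinct DNA word of unit
length *t* mer. A solve is five tube stages:

1. **Pool** — anneal/ligate all `(mn)^n` strands of *n* edges (length `4nt`);
2. **Job filter** — keep strands containing the motif `(e, B_k)` for every
   job *k* (each job exactly once);
3. **Individual filter** — keep strands containing `(s, A_k, e)` for every
   individual *k* (surjectivity);
4. **Weights** — append a tail `w_ij` of length `c_ij · u` mer per edge, so
   strand length `= 4nt + u·Z` encodes total cost;
5. **Length selection** — the shortest strands *are* the optima; read one.

The run costs exactly `8 + 4n + 4m + 5mn` primitive tube operations —
linear in *mn* — and all weighted strands lie in the length window
`[4tn, (4t+y)n]` with `y = u·max c_ij`. Around the pipeline the package
provides the twelve tube primitives, a brute-force oracle
(`brute_force_min()`), constraint-based DNA codeword design
(`build_code()`, `validate_code()`), nearest-neighbor duplex
thermodynamics (`duplex_energy()`), and a CLI.

## Worked example

The bundled 2×3 instance:

```r
library(dnassign)
C <- read_cost_matrix(system.file("extdata", "uap_2x3_costs.csv",
                                  package = "dnassign"))
C
#>    j1 j2 j3
#> i1  2  4  1
#> i2  1  2  3
solve_uap(C)
#> Unbalanced assignment: 2 individuals x 3 jobs
#>   minimum cost Z = 4
#>   optimum: i1 <- {j3}  i2 <- {j1,j2}
#>   solution strands: 6   stage sizes: 216 -> 48 -> 36   ops: 58
#>   read: sA1eB3sA2eB1sA2eB2w13w21w22
```

Reading the output: the pool held `(2·3)³ = 216` strands; 48 survived the
job filter (`3!·2³`), 36 the surjectivity filter (`3!·(2³−2)`); the 6
solution strands are the `3!` orderings of the unique optimum — job 3 to
individual 1, jobs 1 and 2 to individual 2 — whose weight tail
`w13 w21 w22` has length `1+1+2 = 4`, the minimum cost. The run used 58
tube operations (`8 + 4·3 + 4·2 + 5·6`).

Strands encode to nucleotides under a designed codeword set (a reference
25-word set for the 3×5 instance ships as FASTA):

```r
code <- read_code_fasta(system.file("extdata", "codewords_3x5.fasta",
                                    package = "dnassign"))
encode_strand(strand_from_text("sA1eB3"), code)
#> [1] "CTATCTAAAAAACTCATCTA"
duplex_energy("CTATCTAAAAAACTCATCTA")
#> <duplex energy at 310.15 K: dH = 145.80 kcal/mol, dS = 410.10 cal/(mol K), dG = 18.607 kcal/mol>
```

The CLI wraps the same functions:

```sh
inst/scripts/dnassign demo 2x3
inst/scripts/dnassign solve costs.csv --json out.json
inst/scripts/dnassign design --m 3 --n 5 --seed 1 --out code.fasta
inst/scripts/dnassign thermo code.fasta --out energies.tsv
```

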