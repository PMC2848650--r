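# unisig — unique DNA signature discovery

`unisig` finds **unique signatures** in DNA sequence databases: patterns of a
fixed length *l* that occur at exactly one database position and whose hamming
distance to the pattern at every other position exceeds a mismatch tolerance
*d*. A signature therefore stays distinguishable from the rest of the database
even if up to *d* bases mutate or hybridize imperfectly — the core specificity
requirement when screening probes, primers, or diagnostic markers against a
transcript or genome collection.

Formally, writing Ω<sub>l,d</sub> for the signature set of database *D*:

> P ∈ Ω<sub>l,d</sub> ⇔ P occurs at one position of *D* and HD(P, Q) > d for
> the pattern Q at every other position,

where HD is the hamming (mismatch) distance. Patterns satisfying a condition
stricter than (*l*, *d*) — shorter length and/or larger tolerance — are
*implicit signatures* of (*l*, *d*).

## What the package implements

* **Pigeonhole filtration kernels.** Each *l*-pattern is cut into λ
  near-equal partitions; patterns are indexed under every partition substring
  (the α-mer *key*). If HD(P, Q) ≤ d, some aligned partition pair differs by
  at most β, so a pattern only needs comparing against the entries whose keys
  lie within β mismatches of its own (*similar entries*). Two standard
  parameterizations are provided: **UO** (λ = ⌊d/2⌋+1, β = 1) and **IMUS**
  (λ = 2, β = ⌊d/2⌋). `full_discover()` runs them stand-alone;
  `brute_force_discover()` is the quadratic all-pairs oracle.
* **Incremental discovery (PISD).** Signatures under a stricter condition are
  always contained in (substrings of) signatures under a looser one, so
  `pisd_discover()` re-verifies a small candidate set instead of rescanning
  the whole database; `derive_candidates()` expands a looser signature set
  into the complete candidate set for a stricter target.
* **PEL scheduling.** For parallel task lists, `pel_schedule()` is a
  linear-time partial partition that moves heavy index entries to the front
  and splits the heaviest into per-worker parts; `greedy_dispatch()`
  simulates earliest-available-worker assignment and reports per-worker
  loads and the makespan T<sub>n</sub>.
* **Implicit-signature enumeration (CMD).** `cmd_discover()` walks the whole
  condition grid {(l′ ≤ l, d′ ≥ d)}, seeding with one full discovery and
  chaining every other condition from the tightest previously computed
  superset.
* **Synthetic databases.** `generate_db()` and `plant_near_duplicates()`
  produce seeded random databases with planted near-duplicate structure for
  validation.

## Worked example

The bundled toy landscape — three 8-base records — can be enumerated by hand,
which makes it a useful first check:

```r
library(unisig)
db <- sig_db(c(seq1 = "CCCTAATG", seq2 = "TTAATAAT", seq3 = "ATAATGCG"))
full_discover(db, discovery_condition(5, 1, "UO"))
#> signature set Omega_(5,1): 5 unique signature(s)
#>  seq_index offset seq_name string
#>          0      0     seq1  CCCTA
#>          0      1     seq1  CCTAA
#>          1      2     seq2  AATAA
#>          2      2     seq3  AATGC
#>          2      3     seq3  ATGCG
```

Of the twelve 5-patterns in the database, five are unique at one mismatch;
`ATAAT` (for example) is excluded because it occurs twice. Enumerating the
full implicit grid reuses each looser result as candidates:

```r
cmd_discover(db, l = 5, d = 1, l_min = 4, d_max = 2, kernel = "UO")
#> CMD implicit-signature discovery, kernel UO, grid l in [4,5], d in [1,2]
#>   l5_d1: 5 signature(s)  [candidates from full]
#>   l5_d2: 1 signature(s)  [candidates from l5_d1]
#>   l4_d1: 4 signature(s)  [candidates from l5_d1]
#>   l4_d2: 1 signature(s)  [candidates from l4_d1]
```

Scheduling an 11-entry task list (counts 33, 26, 49, 5, 143, 9, 72, 29, 11,
55, 22) for two workers splits the heaviest entry and balances both workers
exactly:

```r
sched <- pel_schedule(data.frame(id = LETTERS[1:11],
  count = c(33, 26, 49, 5, 143, 9, 72, 29, 11, 55, 22)), n = 2)
greedy_dispatch(sched, 2)
#> greedy dispatch over 2 worker(s), makespan T_n = 227
#>   worker 1 (load 227): E, G, D, F, B, I, A
#>   worker 2 (load 227): E, C, J, H, K
```

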