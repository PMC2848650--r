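---
title: "Methods: unique signature discovery by incremental hamming-distance filtration"
author: "unisig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unique signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unisig)
```

## The problem and the model

A DNA database $D$ is an ordered collection of sequences over $\{A,C,G,T\}$.
An $l$-pattern is any length-$l$ window of a record (windows never span two
records; only the forward strand is considered). A pattern $P$ is a **unique
signature** under the discovery condition $(l, d)$ when $P$ occurs at exactly
one position of $D$ and the hamming distance $HD(P, Q) > d$ for the pattern
$Q$ at every other position. We write $\Omega_{l,d}$ for the signature set.
Uniqueness is *occurrence-level*: two identical strings at different
positions disqualify each other, and a pattern is never compared against its
own position. When duplicate surviving strings could arise (they cannot for
true signatures, by definition), a string is reported once with its single
occurrence.

Signatures are the patterns that remain distinguishable under up to $d$
mutations or hybridization mismatches — the specificity criterion for
microarray probes, PCR primers and diagnostic markers. Patterns satisfying a
*stricter* condition — length $\le l$, tolerance $\ge d$ — are **implicit
signatures** of $(l, d)$.

Three containment observations drive everything the package does:

1. Every member of $\Omega_{l-1,d}$ is a substring of a member of
   $\Omega_{l,d}$ (extending a pattern cannot reduce its distance to
   others).
2. $\Omega_{l,d+1} \subseteq \Omega_{l,d}$ (raising the tolerance only
   removes signatures).
3. Combining both: every member of $\Omega_{l-a,d+b}$ is a substring of a
   member of $\Omega_{l,d}$.

Hence a looser condition's signature set is a complete candidate pool for
any stricter condition, and re-verifying that pool is sound and usually far
cheaper than rescanning the database.

## Pigeonhole filtration kernels

Scanning all pattern pairs is quadratic. The filtration index cuts each
$l'$-pattern into $\lambda$ contiguous partitions and stores the pattern,
once per partition *slot*, in an associative map keyed by (partition
substring, slot). If $HD(P,Q) \le d'$ then some aligned partition pair
differs by at most $\beta$ mismatches — otherwise the total would exceed
$\lambda \cdot \beta \ge d'$ — so all near matches of $P$ sit in the entries
whose keys are within $\beta$ of one of $P$'s keys (*similar entries*). Two
standard parameterizations are provided:

| kernel | $\lambda$ (partitions)      | $\beta$ (key tolerance)   |
|--------|-----------------------------|---------------------------|
| UO     | $\lfloor d'/2\rfloor + 1$   | $1$                       |
| IMUS   | $2$ (halves)                | $\lfloor d'/2 \rfloor$    |

Note the degenerate-looking but valid corner: for UO at $d' = 1$,
$\lambda = 1$ and the key is the entire pattern; the similar-entry
neighborhood (hamming ball of radius 1 around the full pattern) still covers
every qualifying pair. The optional frequency-based pre-filter sometimes
attached to the IMUS parameterization is intentionally not implemented; the
kernel here is the pure hamming-distance filtration.

**Non-divisible lengths.** When $\lambda \nmid l'$, partition lengths differ
by one, longer parts first. The pigeonhole bound is unaffected (the argument
above never uses equal lengths). This matters in practice: condition grids
routinely contain lengths not divisible by the partition count.

**All-slot listing.** Each pattern is listed under all $\lambda$ slots, so
every entry's candidate block is self-contained: a candidate is fully
verified by checking it in each of the $\lambda$ entries that list it. Pair
comparisons rediscovered via a second slot are redundant but harmless; an
already-eliminated candidate is skipped, which changes the work counters but
never the result.

**Candidate-first entries.** Within an entry, occurrences to be *verified*
(candidates) precede occurrences that are only *compared against*, and a
pointer marks the boundary; uniqueness checking touches only the leading
block of each entry's own list, while comparisons run over the full lists of
similar entries.

The `comparison_counter` records full string comparisons and the characters
they touch. Each comparison is counted at the full $l'$ characters — the
key-region-skipping refinement is deliberately not implemented, because with
$\beta \ge 1$ the key regions of compared patterns differ and skipping would
require carrying per-key distances. Counts are therefore an upper bound and
are asserted in tests only as monotone, never as exact closed forms.

## Incremental discovery and the condition grid

`pisd_discover()` verifies an arbitrary candidate set under one condition;
`full_discover()` is the special case where every occurrence is a candidate
(the stand-alone UO/IMUS algorithms). `derive_candidates()` expands a
signature set at $(x, y)$ into the complete candidate set at a stricter
$(l', d')$: the member occurrences themselves when $l' = x$, otherwise all
$x - l' + 1$ sub-occurrences of each member, deduplicated by position.

`cmd_discover()` enumerates the grid $\{(l', d') : l_{\min} \le l' \le l,\;
d \le d' \le d_{\max},\; d' < l'\}$, ordered by $l'$ descending then $d'$
ascending. The seed $(l, d)$ is computed in full; every other condition
chains from the *tightest previously computed superset*:

* $(l', d')$ with $d' > d$ uses $\Omega_{l',d'-1}$ (observation 2);
* $(l', d)$ with $l' < l$ uses substrings of $\Omega_{l'+1,d}$
  (observation 1).

This was a genuinely open design point — "the previous looser condition"
admits several readings — and the tightest-superset rule was chosen because
it minimizes candidate counts at every step while remaining covered by the
observations; the test suite validates it by demanding exact equality with
independent full discovery at every grid condition. Conditions whose
partition scheme degenerates ($\lambda > l'$) are skipped with a warning
rather than aborting the run. The default bounds ($l_{\min} =
\max(12, 2\lambda)$, $d_{\max} = d + 2$) keep keys at least two bases long
and the grid finite; both are plain arguments.

## Parallel scheduling: the PEL heuristic

Treating one index entry is a task whose cost is proxied by its candidate
count. Greedy earliest-available dispatch of an arbitrary task order can be
far from the optimal makespan $T_1/n$ when a heavy task surfaces late, or
when a single task exceeds $T_1/n$. Fully sorting $N$ entries costs
$O(N \log N)$; the **parallel entry list** (PEL) heuristic gets the benefit
in linear time:

1. Over the current working region (initially the whole list) compute
   $g = \lfloor \text{total}/w \rfloor$, the floored mean candidate count.
2. Scan $k$ left-to-right for a count $\le g$ and $r$ right-to-left for a
   count $> g$; swap and continue until the scans cross. Counts exactly $g$
   belong to the "light" side. Set $w \leftarrow r$: the first $w$ tasks now
   all exceed $g$.
3. Repeat on the shrunken region while $w > n$; when $w \le n$, remove the
   first $w$ tasks, split each into $n$ parts of near-equal count (floor
   first, remainder to the later parts) and prepend the parts. If at any
   iteration no task exceeds $g$ (an all-equal region), the list is returned
   as-is with no splits.

The stopping rule *iterate while $w > n$* is a reconstruction: it is the
rule consistent with the heuristic's published walkthrough (continuing at
$w = 4 > 2$, stopping at $w = 1 \le 2$) and with the linear total-scan
bound, and the test suite pins the entire walkthrough — region averages 41
and 79, region sizes 4 and 1, the 143-count entry splitting into 71 + 72,
and both workers dispatching to exactly 227. Each iteration halves the
region (every kept count exceeds the regional mean), so total scan work is
$O(N)$; tests assert the element-visit counter stays below $3N + n\,w$.

`greedy_dispatch()` simulates list-order dispatch — each task claims the
worker that frees first, ties to the lower worker id — and reports
per-worker loads $t_i$ and makespan $T_n = \max t_i$, which tests check
against the lower bound $\max(\lceil\text{total}/n\rceil, \max_i c_i)$. The
PEL ordering is a heuristic: single adversarial instances can dispatch worse
than the identity order, so the benefit is asserted only as a mean over a
hundred random instances.

**Execution model.** Inside `pisd_discover()` tasks are executed
sequentially in schedule order within one R process. Each task only *marks
candidates as eliminated*, and elimination is idempotent and commutative, so
the signature set is byte-identical for any worker count and any task order
— the package's determinism contract. The `workers` argument parameterizes
the schedule (splitting and the simulated dispatch), not OS concurrency;
wall-clock parallel speedups are a property of the host and are out of
scope here, while everything schedulable — the reordered list, the split
sizes, the per-worker loads, the makespan — is computed and tested exactly.

## Input handling

FASTA input (plain or gzipped) is read through Biostrings. Sequences are
uppercased; every character outside $\{A,C,G,T\}$ — all IUPAC ambiguity and
"universal" characters, not just `N` — is replaced by `A`; records shorter
than `min_len` (default 36, the conventional EST pre-filter; an argument
everywhere) are dropped, and an empty post-filter database is an explicit
error. Record names are the first header token and must be unique.
Internally all coordinates are 0-based half-open; written reports use
1-based inclusive coordinates. Reverse-complement matching is deliberately
absent: uniqueness is defined on the given strand.

## The synthetic generator

`generate_db()` draws i.i.d. uniform bases, fully determined by one integer
seed (the RNG state is restored afterwards, so library calls never perturb a
caller's stream). `plant_near_duplicates()` overwrites `copies` disjoint
windows — chosen among non-overlapping $l$-tiles so plants can never overlap
— with one random $l$-mer: the first copy verbatim, each further copy
mutated at exactly $m$ positions with substituted bases forced to differ.
Every planted copy is thus within $m$ of the original occurrence, so *all*
planted occurrences are provably non-unique at $d \ge m$; at $d < m$ their
status is checked against the brute-force oracle rather than asserted,
since mutated copies are pairwise up to $2m$ apart and a short background
could, in principle, collide. (Mutating *every* copy instead would leave
pairwise distances up to $2m$ and void the $d \ge m$ guarantee; planting
the original anchors it.)

What the generator emulates is uniqueness structure under i.i.d. noise; it
does not emulate the repeat families, compositional bias, homopolymers or
sequencing-error models of real EST or genomic data. Passing tests on
planted databases therefore demonstrate algorithmic correctness — agreement
with the all-pairs oracle and correct planted-pattern behavior — not
recall/precision on real libraries.

## Validation scale and numerical choices

The oracle for every correctness claim is `brute_force_discover()`, an
independent all-pairs hamming scan (quadratic, so test databases stay at a
few hundred bases). The suite runs, among others: 50 seeded random
databases (80–480 bases, $l' \in [8,16]$, $d' \in [1,4]$, both kernels)
demanding exact member-level equality with the oracle; grid sweeps
demanding CMD-vs-oracle equality at every condition; pigeonhole soundness
over random near pairs at $l \in [4,10]$; and byte-identity of written
reports across worker counts and schedules. These sizes were chosen so the
whole suite completes in well under a minute while still exercising uneven
partitions, both kernels, and every $\beta \in \{0,1,2\}$ regime.

Remaining choices worth stating: `pel_schedule` uses integer floors for $g$
and for split sizes (remainder to later parts, so the smaller part leads);
dispatch ties break to the lower worker id; hamming comparisons are
computed vectorized over full strings (no early exit — simpler, and only
counters could tell the difference); signature sets are sorted by record
then offset before reporting, which is what makes outputs byte-stable.

## Known limitations

* Forward strand only; no reverse-complement or edit-distance (indel)
  tolerance.
* The brute-force oracle and the in-memory index target desk-scale
  validation; chromosome-scale runs would want the dense $4^\alpha$ index
  and true multiprocessing that this package intentionally replaces with an
  associative map and a simulated dispatch.
* Character-comparison counts are upper bounds (full-string comparisons,
  redundant slot pairs), not the closed-form costs of the key-skipping
  variant.
* The frequency pre-filter variant of IMUS is out of scope.
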