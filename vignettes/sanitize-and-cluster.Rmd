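---
title: "Forbidden-pattern avoiding replacement, sanitization and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forbidden-pattern avoiding replacement, sanitization and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringsan)
```

## The problem

A string `w` over an alphabet `Σ` — a DNA fragment, a sequence of visited
locations, a tokenized document — may contain positions that must be
*replaced*: missing values from imperfect measurement, or placeholders
(`#`) left behind by privacy-protecting deletion of sensitive substrings.
Replacement has to respect two kinds of constraints:

* the **context**: the letters to the left (`u`) and right (`v`) of the
  missing region must be preserved, because the sequential structure
  around the gap carries the signal downstream analyses use;
* a finite **antidictionary** `S` of *forbidden patterns*: substrings
  that must not occur in the output, because they are implausible
  artifacts (e.g. biologically unlikely motifs) or confidential
  (re-introducing a sensitive pattern would defeat the sanitization).

Among all strings with prefix `u` and suffix `v` avoiding `S`, we want a
**shortest** one: every extra letter is spurious information. `stringsan`
implements this replacement primitive, uses it to *fully sanitize* private
strings against a set of fixed-length forbidden patterns, and evaluates
how well collections sanitized this way can still be clustered.

## The avoidance automaton

Call a string *dangerous* if it is empty or a proper prefix of a pattern
in `S` (after normalization: duplicates removed and any pattern containing
another dropped, so `S` is *anti-factorial*). Dangerous strings may occur
in a valid output; they are exactly the "live" amounts of progress an
adversary pattern can have made. `prefix_automaton()` builds the
deterministic automaton whose states are the dangerous strings:

```{r automaton}
S <- pattern_set(c("bbbb", "abba", "aaba"))
A <- prefix_automaton(S)
A
automaton_states(A)
```

The transition `delta(q, a)` is the longest dangerous suffix of `q · a`,
computed with the classical breadth-first failure-function recurrence over
the pattern trie; transitions that would complete a full pattern are
marked `FORBIDDEN` (the merged forbidden trie node is deleted). Walking
the automaton over any text tracks its longest dangerous suffix and hits
`FORBIDDEN` exactly when a forbidden pattern appears:

```{r run}
automaton_run(A, "aab")        # a live state
automaton_run(A, "aaba")       # contains a pattern
```

The state count is `1 +` the number of distinct proper prefixes of `S`,
i.e. linear in the total pattern length — crucially *not* exponential in
the pattern length, unlike the complete de Bruijn graph view of the same
problem, which the package never materializes (it appears only as a small
test oracle).

### Sinks, and a closure subtlety

For a fixed right context `v`, a state `q` is a *sink* if appending `v`
to a text ending in state `q` is safe, i.e. `q · v` contains no pattern.
Non-sinks are found by matching every nonempty prefix `p` of `v` against
pattern suffixes: if `s = q · p` for a pattern `s`, then `q` is unsafe.
One further step is required: any state that *ends* with an unsafe state
is unsafe too, so the marked set must be closed under the failure
function. The closure matters in practice — with `S` as above and
`v = "aba"`, the state `aa` is unsafe (`"aa" · "aba"` contains `"aaba"`)
even though no pattern factors as `"aa" · p` with `p` a prefix of `v`:

```{r nonsinks}
non_sink_states(A, "aba")
```

Omitting the closure can produce outputs that contain forbidden patterns
(e.g. left context `"baa"`, right context `"aba"`, `S = {"aaba"}`); the
test suite checks the closed set against the naive definition on every
state of randomized instances.

## Shortest replacement (`solve_mvrs()`)

Given `u`, `v` and `S`, the solver:

1. reports `FAIL` (`PATTERN_IN_CONTEXT`) if a pattern already occurs in
   `u` or `v`;
2. tries the **overlap case** (`|x| ≤ |u| + |v|`): spell `u` from the
   root; after `i` letters, if the remaining suffix of `u` equals a
   prefix of `v` (a suffix/prefix overlap) and the current state is a
   sink, then `u[1..i] · v` is feasible. Longer overlaps are tried first,
   so the first hit is shortest;
3. otherwise runs a **breadth-first search** from the state reached after
   `u` to the nearest sink; the path spells the inserted middle `h` and
   `x = u h v`. A zero-step search (source already a sink) covers
   `|x| = |u| + |v|`;
4. reports `FAIL` (`NO_PATH`) if no sink is reachable.

```{r mvrs}
solve_mvrs("aab", "aba", S)
```

**Tie-breaking.** Any shortest witness is correct; for reproducibility
the BFS expands letters in alphabet-rank order and keeps each state's
first discovery, so the returned middle is the lexicographically smallest
among the shortest. Empty contexts are allowed: with `v = ""` every state
is a sink and the solver returns `u` itself when `u` is pattern-free.

**Correctness harness.** `mvrs_brute_force()` enumerates candidates by
increasing length (overlap merges, then `u h v` for every middle in rank
order) and is compared with the solver on hundreds of random instances;
fixed-length instances are additionally checked against shortest paths in
an explicitly built de Bruijn graph with failing edges.

## Full sanitization

For an antidictionary `S_k` in which every pattern has the same length
`k`, a string `w` is *fully sanitized* into `y` when (i) no pattern
occurs in `y`, (ii) `y` uses only the original alphabet (no `#`), and
(iii) the sequence of non-forbidden k-grams of `w` survives in order as a
subsequence of that of `y` — the utility constraint that keeps `y`
analyzable in place of `w`.

### The partial step (`tfs()`)

The unique shortest *partial* sanitization keeps the non-forbidden
k-grams of `w` in order, separated by `#` where they do not chain. The
construction is an extend-or-restart scan: each kept k-gram either
extends the current segment by one letter (when the segment already ends
with the gram's `(k-1)`-prefix) or opens a new segment after a `#`.
Uniqueness of the optimum makes any correct construction equivalent, and
the scan characterization has one consequence worth spelling out: kept
k-grams on *opposite sides* of a forbidden run still chain whenever their
overlap matches, so a forbidden run can disappear without leaving a gap.
With `w = "CAAAAAC"`, `k = 3`, `S = {"AAA"}`, the kept grams are
`CAA, AAC` and they chain, so the partial optimum is already the full
string `"CAAC"` — one of the package's differences from a scan that
eagerly emits a `#` at the first forbidden gram and never reconsiders.
Segment lengths are always `≥ k` and the number of `#`s never exceeds the
number of forbidden occurrences.

```{r tfs}
tfs("abbbbaaabaa", 4, S)
```

### The splice (`sfss()`)

Each gap `x_i # x_{i+1}` is an independent replacement instance with
`u =` the `(k-1)`-suffix of `x_i` and `v =` the `(k-1)`-prefix of
`x_{i+1}`, solved on one shared automaton and spliced back. Because
`|u| = |v| = k - 1`, no overlap longer than `k - 1` exists and no kept
k-gram can be lost, so the result satisfies the subsequence constraint
and is shortest overall; tiny-instance exhaustive search in the test
suite confirms minimality.

```{r sfss}
sfss("abbbbaaabaa", 4, S)
sfss("CAAAAAC", 3, pattern_set("AAA", alphabet("AC")))
```

### The greedy baseline (`gfss()`) and infeasibility

`gfss()` deletes the letter that would complete a forbidden pattern, in
one left-to-right pass. It is always safe and never longer than `w`, but
a deletion can create a *new* forbidden occurrence out of the surrounding
letters and cascade — `"CAAAAAC"` with `S = {"AAA"}` collapses to
`"CAAC"` by deleting three letters, and in general the k-gram sequence of
`w` need not survive. The pipeline uses it as the speed baseline.

Full sanitization, by contrast, can be genuinely **infeasible** for a
given string: if every one-letter extension of some gap context is
forbidden (a *dead-end* context), the corresponding replacement instance
has no solution and `sfss()` returns `NA` with the failing gap index.
With patterns sampled uniformly from `Σ^k` at rate `R`, the chance that
some `(k-1)`-gram is a dead end grows like `|Σ|^{k-1} R^{|Σ|}`, and
near-duplicate strings share dead-end contexts, so failures arrive in
batches. `sanitize_cluster()` records such strings in a failure manifest
and excludes them from the downstream phases.

## Comparing and clustering sanitized strings

### The LIS k-gram distance

For strings `x`, `y`, concatenate — in the order of `x`'s k-grams — the
sorted occurrence positions of each k-gram of `x` in `y`; the length of a
longest strictly increasing subsequence of this list, `lis_k(x, y, k)`,
counts k-grams of `x` embedded in `y` in order (computed by patience
sorting in `O(h log h)`). The distance is

```
lk_dist(x, y, k) = |x| + |y| - 2(k - 1) - lis_k(x, y, k) - lis_k(y, x, k)
```

It is symmetric, non-negative, and zero on identical strings, but it is
**not a metric**: the triangle inequality can fail, and it can be zero
for distinct strings (`lk_dist("aaa", "aaaaaaa", 3)` is 0 because every
3-gram of either string embeds in the other). These caveats are why the
clustering step uses a medoid heuristic that only needs symmetry and
self-distance zero.

```{r dist}
lk_dist_matrix(c("aaabaaab", "abaaaaaa", "aaaaaaaa"), 4)
```

### Seeded K-medoids

`pam_cluster()` minimizes the K-median cost (sum of distances to the
nearest medoid) by Partitioning Around Medoids: `K` initial medoids drawn
uniformly with the seeded generator, then systematic passes over all
(medoid, non-medoid) pairs in index order, accepting the first
cost-decreasing swap, until a full pass finds none; five random restarts
by default, best run kept. The schedule is one deterministic realization
of "swap while the cost decreases" — randomized swap orders reach
1-swap-optimal solutions of the same quality, but a fixed scan order
makes results reproducible for a given `(matrix, K, seed)`. Assignment
ties go to the lowest medoid index and medoids always represent
themselves (relevant because distinct strings can be at distance zero).

### Agreement measures

`nmi()` is mutual information over the contingency counts normalized by
the larger of the two partition entropies (natural logarithm; the ratio
is base-invariant). Degenerate conventions: both partitions trivial ⇒ 1,
exactly one trivial ⇒ 0. `ari()` defaults to the pair-count ratio
`2(N00·N11 − N01·N10) / ((N00+N01)(N01+N11) + (N00+N10)(N10+N11))` over
the four pair-agreement classes; `variant = "adjusted"` gives the
conventional hypergeometric-expectation (Hubert–Arabie) index for
comparison with other tools — the two differ away from the extremes, so
reports should name the variant. `lis_quality()` scores cluster
compactness as the summed best bidirectional LIS similarity to a medoid;
unlike the distance it is comparable across sanitizers that output
strings of different lengths.

## The synthetic generator

`simulate_clustered_strings()` emulates collections with planted
structure: `K` seed strings drawn uniformly over the alphabet (length
2000 by default; real seeds can be supplied), each cluster consisting of
the seed plus `L - 1` copies mutated by `e` edit operations — type
(substitution / insertion / deletion) uniform, position uniform, letters
uniform with substitutions forced to change the letter. The noise level
is `δ = e / |Q|`; edits are applied sequentially, so later operations may
partially cancel earlier ones and `e` is an upper bound on the edit
distance (checked against a standard dynamic-programming edit distance in
the tests). `sample_patterns()` draws the antidictionary uniformly
without replacement either from all of `Σ^k` (rate `R = |S_k| / |Σ|^k`)
or from the k-grams occurring in the data.

What the generator does *not* emulate: real sequence composition
(codon/GC bias, repeats), heteroscedastic cluster sizes or radii, and
antidictionaries correlated with the data (real sensitive patterns occur
in the strings by definition; the `occurring` mode approximates this).
Passing tests on these collections therefore demonstrate the machinery
and the qualitative regime boundaries, not performance on any particular
real corpus.

## Problem sizes, defaults and degenerate inputs

* The end-to-end evaluation in the test suite uses `K = 3` clusters of
  `L = 10` strings of length 500 over `ACGT`, `k = 8`, `R = 0.1`,
  `δ = 0.1`, five replicates: the pipeline recovers the planted labels
  with NMI ≥ 0.9 on the sanitizable strings. The optimal-vs-greedy
  contrast uses the noisier small-`k` regime (`k = 4`, `δ = 0.7`,
  `R = 0.1`), where greedy deletion cascades and loses cluster structure
  while full sanitization preserves it. `R` is kept at 10% there because
  denser antidictionaries make full sanitization itself infeasible for
  most strings (dead-end contexts, above), which would leave nothing to
  compare.
* `|w| < k`: the k-gram sequence is empty; `tfs()`/`sfss()` return the
  empty string with a warning, `gfss()` returns `w` unchanged (it never
  forms a k-gram). `lk_dist()` requires `k ≤ min(|x|, |y|)` and rejects
  shorter strings rather than extrapolating the formula.
* `#` is reserved: it can never be an alphabet letter or occur in
  patterns or sanitization inputs.
* Per-gap antidictionaries (a list of `d` pattern sets) are accepted by
  `sfss()` at no extra cost, since each gap is solved independently.
* All randomness (initial medoids, synthetic data, pattern sampling) is
  controlled by explicit integer seeds; equal seeds give identical
  results.

## Known limitations

* Clustering is heuristic: 1-swap-optimal, not globally optimal (the
  K-median problem is NP-hard, and the distance's failure of the triangle
  inequality rules out the approximation algorithms that need a metric).
* The distance treats strings as bags-of-ordered-k-grams; two strings
  with heavily repetitive k-gram content can look closer than their edit
  distance suggests (it is a zero-distance pseudometric by design).
* Edit-distance-optimal sanitization and ghost-pattern minimization are
  different objectives and are out of scope; the greedy baseline is the
  only alternative sanitizer shipped.
* Sanitization of a string is deterministic; there is no mechanism for
  trading optimality for randomized output diversity.
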