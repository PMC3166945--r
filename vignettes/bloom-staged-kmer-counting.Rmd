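---
title: "Bloom-staged k-mer counting: model, guarantees and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bloom-staged k-mer counting: model, guarantees and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbloom)
```

## The counting problem and the staging idea

Given reads over the alphabet `{A, C, G, T}`, we want the exact multiplicity
of every *canonical* k-mer — the lexicographic minimum of a length-k window
and its reverse complement — restricted to multiplicities at least a cutoff
`c ≥ 2`. Windows containing any other character (e.g. `N`) are skipped.

With per-base substitution error rate α, a read of length l contributes
`(l − k + 1)(1 − (1 − α)^k)` expected windows that contain at least one
error; nearly all of these are k-mers that occur exactly once in the whole
data set. With `C · G / l` reads over a genome of length G, the expected
number of error-derived k-mers is

```
E[spurious] = (C · G / l) · (l − k + 1) · (1 − (1 − α)^k)
```

(`expected_spurious_kmers()`), which equals G at the crossover coverage

```
C* = l / ((l − k + 1) · (1 − (1 − α)^k))
```

(`crossover_coverage()`; ≈ 5.34 at α = 0.01, l = 100, k = 31). Past that
coverage a plain hash table spends most of its memory on k-mers the cutoff
will discard anyway. `kbloom` therefore stages k-mers in a Bloom filter,
which represents set membership in a few bits per key at the price of a
tunable false-positive rate, and admits a k-mer to the hash table only once
the filter suggests it has been seen `c − 1` times already.

## The two-pass algorithm and its exactness guarantee

**Pass 1.** Stream every canonical k-mer occurrence. For `c = 2`, probe a
Bloom filter: on a miss, insert; on a hit, add the k-mer to the candidate
table with a placeholder count of 0. For `c > 2`, a counting Bloom filter
stores `b = ceiling(log2 c)`-bit counters that saturate at `c − 1`; a k-mer
is tabled when all of its `d` counters already equal `c − 1`. A true k-mer
with multiplicity ≥ c is *always* tabled (counters only ever undercount
nothing — increments are applied to all d positions), so the candidate table
is a superset of the answer. False positives add candidates but never remove
them.

**Pass 2.** Stream the reads again, incrementing only tabled k-mers, then
delete every entry with exact count < c. Since pass 2 counts candidates
exactly and the candidates are a superset of the truth, the output equals
the brute-force tally filtered to counts ≥ c — *regardless of the filter's
false-positive rate*. An undersized filter only inflates the intermediate
candidate table (this is tested down to a quarter bit per k-mer).

**One-pass mode** (`mode = "approximate"`, `c = 2` only) tables a k-mer with
count 2 at its first filter hit and skips the recount. A reported count
exceeds the truth by exactly 1 when the k-mer's *first* occurrence was a
filter false positive, and is exact otherwise, so errors are bounded by +1
and no k-mer with true count ≥ 2 is ever missed. Higher cutoffs are not
offered in this mode because a counting-filter false positive could then
mis-stage a k-mer by more than one occurrence, breaking the clean bound.

## Filter mathematics

For `n` keys in `m` bits with `d` hash functions the false-positive rate is
approximated by the standard

```
p(n, m, d) = (1 − exp(−d·n/m))^d
```

(`false_positive_rate()`; 2.17% at m = 8n, d = 5). `optimal_d(n, m)`
minimizes this by brute force over the integer grid d = 1..64, breaking ties
toward the smaller d (cheaper per lookup); it brackets the continuous
optimum `(m/n)·ln 2` and returns 3 at the default 4 bits per k-mer.

Hashing is double hashing over a 64-bit hash `h` of the packed k-mer bytes:
`index_i = (u + i·v) mod m` with `u = h(x, seed)`,
`v = h(x, seed XOR constant) | 1` (odd, so all m slots are reachable). This
gives d index streams from two hash evaluations; the smaller-d index list is
a prefix of the larger-d list, which the tests exploit.

### Predicting the pass-1 overhead

The candidate table's expected size is the number of true ≥ c k-mers plus
the sum, over the remaining distinct k-mers, of the probability that their
first occurrence was a false positive. For the i-th distinct k-mer in
first-occurrence order that probability is evaluated at filter load `i − 1`:

```
p_i = (1 − exp(−d·(i − 1)/m))^d
```

The load counts distinct k-mers *seen*, not k-mers actually inserted: a key
whose probe returned a (false) positive would have set no new bits had it
been inserted, so the fill of the filter is unaffected by which keys were
swallowed. (The alternative — counting only inserted keys — systematically
underpredicts table size and is rejected by simulation.) The one-pass "+1"
overshoot fraction follows the same per-key `p_i`, and the test suite checks
both predictions against simulation within three standard errors.

## Data structures and numerical choices

* **Packed k-mers.** 2 bits per base (`A=00, C=01, G=10, T=11`), first base
  most significant, right-aligned in `ceiling(2k/8)` bytes. Byte-wise
  comparison then equals lexicographic order, so canonicalization is a
  `memcmp` and the sorted table order is the string order. k is *not*
  capped at 31: any k fits in the byte-array representation.
* **Filter geometry.** `m` is rounded up to a whole 64-bit word. `d` is
  capped at 64. The counting filter packs `b`-bit counters contiguously
  across word boundaries; increments saturate at `c − 1` (all that the
  cutoff test needs), and `c` is limited to 256 (8-bit counters).
* **Counts.** Table counts saturate at `max_count` (default 255, matching
  the 1-byte counts in the binary dump format); the cutoff must not exceed
  it. Pass-1 placeholders are 0, making un-recounted entries visible.
* **Determinism.** The filter hash seed, the simulator seed and the CLI seed
  are all explicit, so every pipeline stage is reproducible bit for bit;
  output tables are radix-sorted for stable diffs.

## The simulator and what it does (and does not) cover

`simulate_genome()` draws an i.i.d. uniform base sequence;
`simulate_reads()` places `round(C·G/l)` reads uniformly on the forward
strand and applies i.i.d. uniform substitution errors at rate α (each error
replaces the base with one of the other three, uniformly). Qualities are
constant placeholders. `naive_count_oracle()` tallies canonical k-mers by
brute force through an independent code path (string windows, a separate
reverse-complement routine, and a generic aggregation library) so
oracle-equivalence tests do not share code with the engine.

This scope is deliberate: it exercises exactly the properties the algorithm
claims (exactness under the cutoff, the +1 bound, strand symmetry,
robustness to filter under-sizing). Passing these tests does **not**
demonstrate performance on repetitive or biased real genomes, indel or
quality-dependent error models, reverse-strand read sampling (the counts are
strand-canonical, so this is immaterial to correctness, and the tests verify
invariance under reverse-complementing all reads), or memory behaviour at
billions of k-mers.

## Problem sizes and limitations

The shipped tests run genomes of 3–50 kb at 5–32× coverage with cutoffs
2–5, and filters of 10^6–10^7 bits — small enough to compare against the
brute-force oracle in minutes while crossing the regimes where singletons
dominate (above the ~5.3× crossover at α = 0.01).

Known limitations: reads are fully materialized in memory by
`read_sequences()` (the two passes re-iterate over the in-memory table), so
exact mode is not a streaming pipeline; the implementation is
single-threaded; `n_kmers`, the expected number of distinct k-mers, must be
supplied by the user to size the filter (a poor estimate costs memory or
pass-1 table size, never correctness); and the approximate mode supports
only `c = 2`.
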