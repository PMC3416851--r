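---
title: "Designing and validating edit-metric sequence tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating edit-metric sequence tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagforge)
```

## The problem

Sequence identification tags (barcodes, indexes, MIDs) are short synthetic
oligonucleotides attached to DNA samples so that many samples can share one
massively parallel sequencing run and be demultiplexed afterwards. A tag is
only useful while it remains recognizable, but errors accumulate at every
stage of the workflow:

* **synthesis** — incomplete coupling leaves n−1 congeners carrying a
  deletion somewhere in the oligo, and no purification removes them all;
* **replication** — polymerases introduce mostly substitutions, with
  insertions and deletions at lower frequency;
* **sequencing** — substitution-dominated on some platforms, but
  insertion/deletion-dominated on pyrosequencing-style chemistry, with
  single-read error rates from under 1% to around 18%.

An error can convert one tag into another (*crossover*, the read is silently
misassigned) or into nothing recognizable (*loss*, the read is discarded).
Codes protect against this by keeping every pair of tags at least a minimum
distance `d` apart under a metric that matches the error process. Hamming
distance only counts substitutions; a single indel shifts the register of
every downstream base, and two tags with Hamming distance 8 can sit at edit
(Levenshtein) distance 2:

```{r}
edit_distance("ACGTACGT", "GACGTACG")
hamming_distance("ACGTACGT", "GACGTACG")
```

The edit metric — minimum number of substitutions, insertions, and deletions
separating two strings — is therefore the right metric for tags that must
survive real error spectra. A set with minimum distance `d` detects up to
`d − 1` errors and corrects up to `⌊(d − 1)/2⌋`:

```{r}
correction_capacity(3)
correction_capacity(5)
```

A related subtlety affects Hamming codes built on a two-bit binary encoding
of the bases (say T = 00, G = 01, C = 10, A = 11). Substitutions happen
between nucleotides, not bits: four of the six unordered base pairs differ
in one bit, but the two "diagonal" pairs (A/T, C/G) differ in two. A code
correcting single-bit errors therefore cannot correct a third of single-base
substitutions, for any systematic two-bit encoding:

```{r}
uncorrectable_substitution_fraction()$uncorrectable
```

## Validating existing sets

`validate_tags()` computes all pairwise distances in a set and reports the
observed minimum, the violating pairs, and the full matrix. Several widely
used published sets fail their own advertised minimum distance, so auditing
before use is worthwhile. Tags embedded in primers or adapters are audited
in place via the `slice` argument (1-based inclusive coordinates in the R
API; the command line accepts 0-based half-open `START:END`).

When a set does not conform, `conforming_tags()` culls it to a conforming
subset: the tag participating in the most sub-threshold pairs is removed
repeatedly (ties drop the lexicographically larger sequence) until no
violating pair remains. This rule is deterministic and usually near-maximal;
the exact maximum conforming subset is NP-hard in general, and the tests
bound the culling result by an exact independent-set computation on small
sets.

## Designing new sets

The designer implements a summary-vector accelerated greedy lexicode:

1. **enumerate** all `4^n` length-`n` candidates in lexicographic order
   (`A < C < G < T`);
2. **filter** candidates on composition (below);
3. **summarize** — for every surviving candidate taken as a *key*, count
   the candidates at each edit distance (`summarize_key()`). Keeping one
   short histogram per key instead of a full pairwise matrix is what keeps
   long tags tractable: a million length-10 candidates imply ~550 billion
   pairs, hundreds of gigabytes as a stored matrix, but only megabytes of
   summary vectors;
4. **reduce** — keep only keys with the maximal count at exactly the target
   distance (`reduce_keys()`), discarding the vast majority of keys;
5. **build** — around each surviving key, scan candidates in order and
   retain those at least `d` from the key and every previously retained tag
   (`build_set()`); return the largest set, ties to the smallest key.

Every designed set passes validation at its distance with zero violations,
every member passes the filters, and the set is *maximal*: no rejected
candidate could be added without breaking the minimum distance. Batch sizes
and the `workers` option only chunk the work — a parallel run is
bit-for-bit identical to a serial run, and the tests assert this.

```{r}
set <- design_tags(5, 3)
set
validate_tags(set)
```

### Composition filters

Defaults: no homopolymer run longer than 2 (runs are error-prone on
pyrosequencing chemistry), GC content within 40–60% **inclusive**, and no
perfect self-complements (palindromic tags favour hairpins and dimers).
The GC bounds are inclusive because length-5 tags take GC values in steps
of 20%: an exclusive reading would empty the candidate pool entirely at
some lengths (length 3 is empty even under the inclusive rule, which the
designer reports as an error rather than returning nothing).

### Ordering sensitivity

A greedy lexicode depends on its scan order. The lexicographic convention
used here is committed and documented, but it is a choice: equally valid
orderings produce valid, maximal sets whose sizes differ by a few tags.
Under this convention the package's own runs (recomputed by the test suite
and the acceptance script) give 28, 64, and 217 tags at lengths 5, 6, and 7
(distance 3), versus 25, 61, and 211 reported for an earlier implementation
whose iteration order is not recoverable from its description. The
structural guarantees — conformance, maximality, filter conservation — are
order-free and are the properties the tests enforce strictly.

`extract_subset()` pulls a higher-distance subset out of a designed set
without a fresh design: each member is tried as a key and the largest
greedily conforming subset wins. It is a shortcut: a from-scratch design at
the higher distance is generally larger, and the subset inherits the
parent's ordering sensitivity.

## Applying tags

`tag_primer()` builds fusion primers as `pigtail + tag + primer`, optionally
collapsing the junction: the longest suffix of the tag equal to a prefix of
the primer is dropped from the primer, once. Collapsing `k` bases changes
the oligo by exactly edit distance `k` (tested), and an error is raised if
the overlap would swallow the whole primer. The default `GTTT` pigtail
promotes +A addition for T/A ligation and is prepended verbatim.

`screen_structure()` is a string-complementarity heuristic for hairpins
(stem ≥ `min_stem` with ≥ `min_loop` unpaired bases between the stem
halves) and self/cross dimers (longest substring whose reverse complement
occurs in the same or the partner oligo). It is not a thermodynamic model:
there are no stacking energies, mismatches, or melting temperatures, and a
palindromic oligo scores its full length as a self-dimer by definition. The
defaults (`min_stem = 4`, `min_loop = 3`) are conventional minima for a
stable stem-loop. `tag_primers()` accepts any replacement screen via its
`screen` argument, so an external evaluator can be plugged in unchanged.

`tag_adapter()`/`tag_adapters()` place tags between fixed adapter arms and
record the tag coordinates, so the assembled adapters can be re-validated
in place — the sliced validation report is identical to the bare tag set's
report (tested).

## Error model and demultiplexing

With a uniform per-base error rate `p` and tag length `L`, the number of
errors in a tag is Binomial(`L`, `p`), so the expected number of affected
reads among `N` is `N · P(X ≥ k)`:

```{r}
expected_error_reads(0.01, 8, 1e6)
```

At `p = 1%`, `L = 8`, `N = 10^6`, about 77,000 reads (roughly 8% of the
run) carry at least one tag error — the quantity that motivates
error-correcting tags in the first place. The description accompanying the
original figure says "more than one error" while its arithmetic matches "at
least one"; both readings are exposed (`min_errors = 1` is the default that
reproduces the printed number, `min_errors = 2` gives the literal reading)
and neither is chosen silently. `simulate_error_reads()` is the Monte-Carlo
counterpart (seeded, reproducible, within sampling error of the closed
form), and the substitution/insertion/deletion mix only matters when
corrupted sequences themselves are needed (`corrupt_tag()`).

`assign_tag()` is a minimal error-correcting demultiplexer: an observed
sequence maps to the unique tag within the correction radius
`r = ⌊(d − 1)/2⌋`, or to `NA` when nothing (or more than one tag) is that
close. It refuses to operate on a set that fails validation, since the
radius is meaningless there. The round-trip guarantee — *every* corruption
of a tag by up to `r` edits, of any type, assigns back to that tag — is
checked exhaustively in the tests by enumerating entire edit neighborhoods
(`edit_neighborhood()`) for distance-3 and distance-5 designs.

## Numerical and scale choices

* Distances are computed in C++ (single-row dynamic programme, stack
  buffers); a full length-7 design (16,384 candidates, ~57 million
  pairwise distances) takes a few seconds, and the test suite runs designs
  up to length 7 routinely. Lengths above 12 are refused.
* Exhaustive oracles are kept small by design: the naive-recursion edit
  distance oracle runs on strings up to length 4, exact maximum-code sizes
  (via igraph's independence number) on pools up to ~90 candidates, and
  subset brute force on sets of ≤ 10 tags.
* All tie-breaks (key choice, culling order) are lexicographic and
  documented, so every pipeline output is deterministic; there is no
  randomness outside the explicitly seeded Monte-Carlo simulator and
  `corrupt_tag()`.

## Limitations

* Greedy lexicodes are not provably maximum codes; evolutionary search can
  find larger sets at the cost of determinism.
* The structure screen is a heuristic, not thermodynamics; use the
  pluggable hook for real primer QC.
* No FASTQ-scale demultiplexing: `assign_tag()` operates on extracted tag
  sequences, not reads, and position-dependent error profiles along reads
  are out of scope (the error model is uniform per base).
* Quality-aware and boundary-corrected (sequence-Levenshtein) metrics are
  not implemented.
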