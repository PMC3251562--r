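---
title: "Aligning and clustering multi-track signal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and clustering multi-track signal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profclust)
```

## The problem

ChIP profiling (ChIP-seq, ChIP-on-chip) measures where a protein or a
histone modification sits on the genome. Around regulatory elements, the
*combination* of such signals — which marks are present, how strong they
are, and where their peaks sit relative to one another — carries biological
meaning, and many of the interesting patterns are asymmetric (a mark on one
side of a bound factor but not the other). Discovering such patterns without
prior annotation requires grouping genomic windows by the *shape* of their
multi-track signal, which in turn requires aligning the windows first: peak
callers center windows imprecisely, and an asymmetric pattern can occur in
either genomic orientation.

`profclust` implements this joint alignment-and-clustering. A window becomes
a **profile**: a `T × L` matrix of `T` signal tracks binned into `L`
equidistant positions. Profiles are compared at every admissible rigid shift
and, optionally, in mirrored orientation; agglomerative clustering then
repeatedly merges the most similar pair into a coverage-weighted average
representative.

## The model and its steps

**Binning and interpolation.** Each track's per-base signal is averaged per
bin (interval-weighted mean, so values are resolution-independent and tracks
of different native resolution can be combined). Bins with no defined signal
are filled by linear interpolation between the nearest defined bins;
leading/trailing gaps use the nearest defined value, because linear
interpolation needs an anchor on both sides. A track with no signal at all
in a window becomes a zero row. After extraction, profiles are dense:
missingness never reaches the alignment stage.

**Normalization.** Tracks differ in dynamic range (antibody affinity,
sequencing depth). Under a squared-distance score an intense track dominates
and the clustering degenerates to sorting by intensity. By default every
track is divided by its dataset-wide maximum absolute value
(`per_track_max`); a dataset-wide z-score is available, as is no
normalization. Scaling constants are computed once over *all* profiles, so
relative intensities between profiles remain comparable.

**Alignment.** For profiles `P1` (length `L1`) and `P2` (length `L2`), bin
`i` of `P1` is compared with bin `i + r` of `P2`; positive `r` moves `P2`
left. Every shift whose overlap reaches
`ceiling(min_overlap_fraction × min(L1, L2))` bins is scored in the forward
and (by default) mirrored orientation of `P2`, and the dissimilarity at a
shift is

```
score(r) = Σ_tracks Σ_overlap (P1[t,i] − P2[t,i+r])² / (n_overlap × T)
```

The per-overlap, per-track normalization is a deliberate design choice: raw
sums of squares would favour short overlaps simply because they have fewer
terms. A consequence worth knowing: zero-padding both profiles changes the
scores of *suboptimal* shifts (their overlaps absorb padding terms), so only
the perfect-match score is padding-invariant. Ties between shifts are broken
deterministically — lower score, smaller `|r|`, non-mirrored, smaller signed
`r` — so the entire pipeline is reproducible bit for bit.

**Clustering.** The pool starts as all profiles. Each iteration aligns all
pool pairs (cached scores between untouched members are reused; a full run
costs `choose(N,2) + choose(N−1,2)` alignments, the quadratic growth being
the price of exhaustiveness), merges the lowest-score pair into its
coverage-weighted average laid out at the chosen shift/orientation, prunes
the result, and re-aligns it against the pool. This is centroid linkage:
iterated coverage-weighted merging reproduces exactly the coverage-weighted
mean of all leaves re-projected by their cumulative placements, which is the
invariant the test suite checks against an independent re-projection oracle.
Merge scores become dendrogram heights; as with any centroid method, height
inversions can occur and are not suppressed. Equal-score pair ties are
resolved by insertion order, so a fixed input order yields a fixed tree.

**Pruning.** Merging at an offset grows the representative and leaves
thinly-supported flanks (few leaves cover them). After each merge, maximal
*edge* runs whose coverage falls below `prune_fraction × weight` are
trimmed — interior bins are never removed — keeping the recurrently aligned
core. If everything falls below threshold, the leftmost maximum-coverage run
is kept rather than emptying the profile. The default `prune_fraction` of
0.25 is this package's choice (the approach prescribes pruning but no
threshold); `0` disables pruning entirely, which the consistency oracles
rely on.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bin_size` | user | bp per bin at extraction; value is a mean, so resolution-independent |
| `min_overlap_fraction` | 0.5 | fraction of the shorter profile that must overlap; smaller values admit more extreme shifts at the cost of flimsier evidence |
| `allow_mirror` | TRUE | compare both orientations; required to detect asymmetric patterns without strand knowledge |
| `normalization` | `per_track_max` | dataset-wide track rescaling |
| `prune_fraction` | 0.25 | edge-coverage threshold as fraction of cluster weight |

## What the synthetic generator emulates — and what it does not

`generate_planted_dataset()` builds profiles whose tracks are sums of
Gaussian bumps: each cluster has a characteristic combination of peak
positions/widths/amplitudes across tracks, each member shifts all its peak
centers by a uniform integer in `[−max_shift, +max_shift]` (the pattern
moves inside a fixed window, mimicking imprecise peak calling), is mirrored
with probability 0.5, and receives i.i.d. Gaussian bin noise. The default
world — 3 clusters × 20 members, 4 tracks, 100 bins, shifts ±10, noise at
10% of the 10-unit peak amplitude — is the validation scenario used by the
acceptance tests.

This emulates exactly the structure the algorithm consumes: peak shape,
position, track combination, orientation, noise. It does *not* emulate read
sampling, fragment-length effects, GC bias, copy-number artefacts,
correlated (non-i.i.d.) background, or overlapping/composite sites. A green
planted-recovery test therefore establishes that the implementation recovers
structure it is designed to see, not that real ChIP data is this easy.

## Numerical and design choices

* Scores are compared exactly (`<`) during the exhaustive scan; the
  deterministic candidate order makes ties reproducible. Real-valued data
  essentially never ties; integer-valued toy data resolves by the tie chain.
* Merging uses per-bin integer coverages, so the weighted mean is exact up
  to one floating rounding per merge; the re-projection oracle tolerance is
  `1e-9` relative.
* `cut_tree(k)` splits the current root set's highest subtree `k − 1` times
  rather than literally deleting the `k − 1` globally highest merges: under
  height inversions the literal rule can fail to produce `k` connected
  parts; on monotone trees the two coincide.
* Newick branch lengths are `parent height − child height` floored at zero,
  again because of possible inversions.
* Orientation–annotation correlation is the Pearson/phi coefficient of ±1
  encodings. A cluster frame is only defined up to a global mirror, so the
  magnitude maximized over that flip is reported, with the flip and the raw
  signed value retained. A constant column makes the statistic undefined and
  is reported as such, never as 0.
* Parallelism (the `workers` argument) only chunks the initial all-pairs
  scoring; scoring is pure, so results are identical for any worker count —
  a contract the tests enforce.
* Wiggle `fixedStep` blocks default `span` to `step` (contiguous coverage);
  an explicit `span` always wins. This deviates from UCSC's default of 1 and
  is the interpretation this package commits to.

## Known limitations

* Only rigid shifts: no gapped or elastic alignment, by design.
* Only the normalized-SSD similarity; the parameter enum is extensible but
  nothing else is implemented.
* The pool loop recomputes only the merged node's alignments but still scans
  all cached pairs each iteration; at `N` in the tens of thousands the
  quadratic alignment count, not this scan, dominates — but this
  implementation targets desk-scale validation, not a 64-core production
  run.
* Regions of unequal length are allowed (profiles simply differ in `L`);
  extreme length disparity combined with aggressive pruning can in principle
  leave unalignable pool members, in which case a forest is returned.
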