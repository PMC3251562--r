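# profclust

Exhaustive alignment and centroid hierarchical clustering of multi-track
genomic signal profiles.

## What it is for

ChIP profiling experiments (ChIP-seq, ChIP-on-chip) yield genome-wide signal
tracks for DNA-binding proteins and histone modifications. Around regulatory
elements these signals form recurrent spatial *patterns* — characteristic
combinations of peaks across tracks, often asymmetric. Finding such patterns
without prior annotation means clustering genomic windows by signal shape,
and because peak calling centers windows imprecisely and asymmetric patterns
occur in both genomic orientations, the windows must be *aligned* (shifted
and possibly mirrored) while they are clustered.

`profclust` is for computational biologists who have (a) a BED file of
candidate windows and (b) one or more bedGraph/wiggle signal tracks, and who
want an unsupervised, deterministic, exhaustively aligned clustering of the
windows' multi-track profiles — plus a synthetic planted-cluster generator
to validate every step without external data.

## The algorithm

A profile is a `T × L` matrix (T tracks, L bins; bin value = interval-mean
of per-base signal, missing stretches linearly interpolated). Two profiles
are compared at every rigid shift `r` meeting a minimum-overlap constraint
(default: half the shorter profile), in forward and mirrored orientation,
with dissimilarity

    score(r) = Σ_t Σ_overlap (P1[t,i] − P2[t,i+r])² / (n_overlap · T)

Clustering keeps a pool of profiles, repeatedly merges the lowest-score
pair into its coverage-weighted average representative laid out at the
chosen shift/orientation (unweighted pair-group centroid linkage), prunes
sparsely covered alignment edges (`coverage < prune_fraction · weight`,
edges only), and re-aligns the merged profile against the pool. The merge
sequence defines a dendrogram; every leaf's cumulative offset and
orientation is reported. A full run costs `C(N,2) + C(N−1,2)` pairwise
alignments. All ties break deterministically, so results are bit-identical
across runs, input permutations (up to relabeling) and worker counts.

## Worked example

Using the small fixture shipped with the package (10 windows of 500 bp, two
signal tracks, two planted pattern groups at varied offsets/orientations):

```r
library(profclust)
regions <- parse_bed(system.file("extdata", "regions.bed", package = "profclust"))
tracks <- list(
  parse_bedgraph(system.file("extdata", "markA.bedgraph", package = "profclust"), "markA"),
  parse_bedgraph(system.file("extdata", "markB.bedgraph", package = "profclust"), "markB"))
profiles <- extract_profiles(tracks, regions, bin_size = 25)
profiles[[1]]
#> <signal_profile 'win01'> 2 track(s) x 20 bin(s), bin_size=25 bp, weight=1
#>   tracks: markA, markB

root <- cluster_profiles(profiles, cluster_params())
root
#> <cluster_node 'node_19'> 10 leaf(s), height=0.00929124, representative 23 bin(s)

cut_tree(root, k = 2)
#> List of 2
#>  $ : chr [1:5] "win02" "win03" "win05" "win01" "win04"
#>  $ : chr [1:5] "win08" "win10" "win06" "win07" "win09"

head(root$placements)
#>   leaf_id offset mirrored length
#> 1   win02      0    FALSE     20
#> 2   win03      2     TRUE     20
#> 3   win05      3     TRUE     20
#> 4   win01     -1    TRUE      20
#> 5   win04      1    FALSE     20
#> 6   win08      0    FALSE     20
```

Reading the output: the dendrogram root merges at height 0.0093 (the
normalized squared distance of the final merge — low, because all windows
share signal structure); `cut_tree(k = 2)` recovers the two planted pattern
groups exactly (`win01..win05` vs `win06..win10`); the placements table says
e.g. `win03` enters the cluster frame shifted by 2 bins and mirrored —
orientation flags are meaningful up to one global flip per cluster.
`to_newick(root)` exports the tree; `write_cluster_exports()` produces the
average-profile TSV and the members BED.

The same run from the shell:

```sh
Rscript -e 'quit(status = profclust::run_cli())' --args \
  cluster --regions inst/extdata/regions.bed \
  --track inst/extdata/markA.bedgraph --track inst/extdata/markB.bedgraph \
  --bin-size 25 --cut-k 2 --out-dir out/
```

writes `tree.nwk`, `clusters.tsv`, per-cluster profile TSVs and member BEDs,
a run log with the merge sequence, and a `manifest.json` with parameters and
input checksums. Subcommands `simulate`, `align` and `orient-corr` cover
synthetic data generation, pairwise alignment tables, and per-cluster
orientation–strand correlation (phi coefficient, flip-maximized magnitude).

## Validation and the acceptance report

Validation is property-based against independent oracles (brute-force
alignment enumeration, leaf re-projection, a re-implemented pool loop,
closed-form statistics) plus planted-cluster recovery at a stated synthetic
world: 3 clusters × 20 members, 4 tracks, 100 bins, shifts ±10, mirroring
probability 0.5, noise 10% of peak amplitude. See
`tests/testthat/test-acceptance.R`.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs an end-to-end seeded self-check of the installed package and writes the
acceptance JSON (empty: all acceptance checks are pass/fail properties, not
numeric targets — the motivating genome-scale numbers require external
datasets).
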