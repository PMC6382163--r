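# gridspike

Spike-level grid scores and orientations for two-dimensional neuronal
firing patterns.

Grid cells of the medial entorhinal cortex fire in strikingly hexagonal
spatial patterns, and the standard way to quantify this — rotating the
spatial autocorrelogram of a rate map and correlating it with itself —
yields a single number per cell. That global score says nothing about
*where* or *when* a grid is good. Recent experiments show that grids
drift in orientation across an arena, develop local defects near walls,
and decay and reappear within seconds when the lights go off; studying
such effects needs a score with local resolution.

`gridspike` implements a spike-level alternative borrowed from the
physics of two-dimensional crystals. For spike *k* with neighbors at
angles φ<sub>l</sub> (measured from the positive x-axis), the M-fold
bond-orientational order parameter is

```
psi_k^(M) = (1/N) * sum_l exp(i * M * phi_l)
```

where the *neighbors* are all spikes whose distance from spike *k* lies
in an annular shell of radii (5/6)ℓ to (7/6)ℓ around it, ℓ being the
grid spacing estimated from the second peak of the smoothed
pairwise-distance histogram. Each spike receives

* a **grid score** ψ̂<sub>k</sub> = |ψ<sub>k</sub><sup>(6)</sup>| if the
  hexagonal modulus strictly exceeds |ψ<sub>k</sub><sup>(M)</sup>| for
  all competing symmetries M ∈ {2, 3, 4, 5, 7}, and 0 otherwise (this
  comparison suppresses false positives from, e.g., collinear field
  arrangements), and
* an **orientation** θ<sub>k</sub> = arg(ψ<sub>k</sub><sup>(6)</sup>)/6
  ∈ (−30°, 30°].

Averaging ψ̂<sub>k</sub> over all spikes gives an arena-wide score Ψ;
averaging over spikes in any spatial region, time window, or set of
cells gives local scores at arbitrary resolution. The package is aimed
at systems neuroscientists analyzing spatial spike data and at
methodologists benchmarking grid-cell classifiers.

Alongside the spike-based score the package provides:

* the conventional correlogram grid score ρ (rate map →
  autocorrelogram → rotation correlations,
  `min(r60, r120) − max(r30, r90, r150)`) as a reference;
* shuffling-based grid-cell classification with a per-cell "flexible
  threshold" (95th percentile of scores on 100 position-shuffled maps);
* spatial partition summaries, multi-cell pooling, temporal boxcar
  filtering, within-trial block averages, reference-map scoring, and
  covariate correlation;
* a synthetic spike-map generator (hexagonal Gaussian fields with field
  jitter, shearing, background spikes, orientation changes/drift, and
  temporal regime switches) that makes every analysis testable without
  recordings;
* support for 4-fold and 2-fold symmetry via adjusted shells
  (`shell_for_symmetry`, `M_target`).

## Worked example

```r
library(gridspike)

map <- generate_grid_map(grid_spec(seed = 42))  # perfect grid, 2000 spikes
map
#> Spike map: 2000 spikes
#>   arena: [0, 1] x [0, 1] m

scores <- psi_scores(map)                # shell detected automatically
scores
#> Spike scores (M = 6): 2000 spikes, mean psi_hat = 0.296, 1076 with score 0
global_scores(scores)
#> Psi = 0.2956  Theta = 0.66 deg  (n = 2000 spikes, 924 in Theta)

rho_pipeline(map)                        # conventional correlogram score
#> rho = 1.460  annulus [0.252, 0.58] m

classify_cell(map, score = "psi", seed = 1)
#> PSI-based classification: grid cell (score 0.2956, threshold 0.0024, 100 shuffles, p95)
```

The map was generated with a grid spacing of 0.5 m; the detected
spacing here is 0.487 m (second histogram peak). Ψ ≈ 0.30 is typical
for a perfect grid: over half of the spikes sit at field edges where a
competing symmetry wins and ψ̂<sub>k</sub> = 0, so Ψ never approaches 1.
The orientation estimate 0.66° recovers the generator's 0° lattice.
ρ ≈ 1.5 is the usual perfect-grid value of the correlogram score. The
classification threshold (95th percentile of Ψ on 100 uniformly
shuffled maps) is far below the actual score, so the cell is called a
grid cell.

Local analyses operate on the same per-spike scores, e.g.:

```r
parts <- strip_partition(map$arena, 3, axis = "x")
partition_means(scores, map, parts)            # west-to-east Psi profile
ser <- temporal_filter(score_series(times, scores$psi_hat), window = 100)
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/gridspike.R`:

```sh
Rscript inst/cli/gridspike.R simulate --preset perfect --output spikes.csv --seed 3
Rscript inst/cli/gridspike.R score --input spikes.csv --arena 0,1,0,1 \
    --output-scores scores.csv --summary summary.json
Rscript inst/cli/gridspike.R classify --input spikes.csv --arena 0,1,0,1 \
    --n-shuffles 100 --percentile 95 --output classification.json
```

Subcommands: `simulate`, `score`, `classify`, `partition`, `temporal`,
`reference-score`; spike maps are plain CSV (`x,y[,t]` in meters and
seconds), reports are JSON/CSV, configuration via `--config`
(JSON/YAML, see `default_config()`).

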