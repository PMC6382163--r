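---
title: "Spike-level grid scores: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-level grid scores: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridspike)
```

## The model

`gridspike` scores the hexagonality of a spatial spike pattern one spike
at a time, using the M-fold bond-orientational order parameter of
two-dimensional crystal physics. For spike $k$, let $\varphi_l$ be the
angles (counter-clockwise from the positive x-axis) of the vectors from
spike $k$ to its $N$ neighbors. Then

$$\psi_k^{(M)} = \frac{1}{N}\sum_{l=1}^{N} e{}^{\,i M \varphi_l},
\qquad |\psi_k^{(M)}| \in [0, 1].$$

If the neighbors sit on the corners of a regular $M$-gon,
$|\psi_k^{(M)}| = 1$ and $\arg(\psi_k^{(M)})/M$ is the polygon's
orientation. Three adaptations make this usable for spike maps rather
than atoms:

1. **Neighborhood shell.** An atom's neighbors are its adjacent atoms;
   a spike's nearest spikes, however, belong to the *same* firing
   field. The relevant neighbors are spikes of the *adjacent fields*,
   so the neighborhood is an annulus of radii $\tfrac{5}{6}\ell$ to
   $\tfrac{7}{6}\ell$ centered on the spike, where $\ell$ is the grid
   spacing. The shell width $\ell/3$ reflects the empirically constant
   ratio of field size to spacing; the score is robust to moderate
   changes of this width.
2. **Spacing detection.** $\ell$ is estimated from the histogram of all
   pairwise spike distances: its first peak reflects the field size,
   its second the grid spacing (`detect_spacing`, mode
   `"second_peak"`). Because a handful of firing fields produce a noisy
   histogram, the histogram is smoothed with a Gaussian kernel of
   $\sigma = 1\%$ of the maximal pairwise distance. Two remedies exist
   for hard cases: `"cutoff"` takes the first peak beyond 15% of the
   arena side (useful when background spikes blur the field-size peak),
   and `"manual"` accepts a user value (e.g. read off the histograms of
   several cells of the same grid module; `spacing_from_module`
   automates the pooled median).
3. **Competing symmetries.** A large $|\psi^{(6)}|$ alone does not
   certify a hexagon: collinear fields also produce one. The spike
   score is therefore
   $$\hat\psi_k = |\psi_k^{(6)}| \cdot
   \mathbf{1}\{|\psi_k^{(6)}| > |\psi_k^{(M)}| \ \forall M \in \{2,3,4,5,7\}\},$$
   a strict inequality, so exact ties (e.g. two diametrically opposite
   neighbors, where $|\psi^{(2)}| = |\psi^{(6)}| = 1$) score zero.
   Orders above 7 were found not to change results and are omitted by
   default (`M_set = 2:7`).

The per-spike orientation is $\theta_k = \arg(\psi_k^{(6)})/6$,
reported in degrees on the half-open interval $(-30, 30]$ — the
fundamental domain of a hexagonal lattice. Arena-wide summaries are
$\Psi$, the plain mean of $\hat\psi_k$ over *all* spikes (zeros
included), and $\Theta$, a circular mean of $\theta_k$ computed on the
60°-periodic circle (unit vectors at $6\theta_k$, summed, argument
divided by 6). Arithmetic averaging of angles would be wrong near the
±30° boundary; the circular construction returns 30° for
$\{29°, -29°\}$, as it should.

Everything local follows from the per-spike values: means over arena
partitions (`partition_means`), over cells (`pool_cells`), over time
windows (`temporal_filter`, a centered boxcar over *time*, not spike
index, with truncated edge windows), within-trial blocks
(`block_average`), and against a reference pattern
(`reference_scores`, which scores each query spike using neighbors
drawn only from a reference map — e.g. dark-trial spikes against the
light-trial pattern).

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| shell radii (M = 6) | $[\frac56\ell, \frac76\ell]$, closed | m | spikes of the six adjacent fields; boundary inclusion is a measure-zero choice, closed is simplest |
| shell radii (M = 4 / M = 2) | centered at $\frac23\ell$ / $\frac12\ell$, half-width $\ell/6$ | m | only the four nearest fields / exclude the next band; half-width reuses the hexagonal value, the center radii being the only published quantities |
| histogram bin width | 0.5% of max pairwise distance | m | the 1%-smoothing kernel then spans two bins, so binning cannot alias peaks; detection is robust to halving/doubling (tested) |
| histogram smoothing | 1% of max pairwise distance | m | suppresses finite-count noise |
| cutoff fraction | 15% of arena side | – | between typical field size and spacing |
| `M_set` | {2, …, 7} | – | higher orders have no effect |
| rate-map bins | 1/50 of arena side (2 cm at 1 m) | m | ≥10 bins per field at typical spacings |
| rate-map smoothing | half a bin (1 cm at 1 m) | m | see calibration note below |
| correlogram annulus | $[\max(r_c, 0.5\,\bar d),\ 1.15\,\bar d]$ | m | $\bar d$ = mean distance of the six inner peaks, $r_c$ = central-peak extent (first dip below 0.1 or first local minimum); see below |
| shuffles / percentile | 100 / 95th | – | the standard flexible-threshold construction |
| temporal window | 100 | s | matches the demonstration analyses; a knob in practice |

All of these are exposed as function arguments and in `default_config()`.

## The synthetic generator

`generate_grid_map` draws spikes from isotropic Gaussian firing fields
whose centers form a triangular lattice (spacing `ell` = 0.5 m in a
1 m × 1 m arena by default, 2000 spikes). Fields extend one lattice
constant beyond the arena so that boundary fields keep their six
neighbors; each spike picks a field uniformly and is re-drawn until it
falls inside the arena. When no phase is given, the lattice offset is
drawn uniformly over one unit cell per realization, so replicate maps
differ in grid phase as recorded cells do. Perturbation families:

* `jitter_fields` — i.i.d. Gaussian displacement of field centers,
  optionally restricted to a region (regional grid defects);
* `shear_fields` — the area-preserving map $(x, y) \mapsto
  (x + s\,(y - y_{mid}),\ y)$ (elliptic distortion);
* `add_background` — replaces a fraction of spikes by uniform draws,
  keeping the count fixed (poor single-unit isolation);
* `orientation_variants` — abrupt north/south orientation change, or a
  south-to-north drift realized as ≥6 horizontal strips of linearly
  increasing orientation (a deterministic, testable stand-in for a
  continuously deformed lattice);
* `temporal_transition` — uniform spikes followed by grid spikes at a
  constant rate (1 Hz), for time-resolved analyses.

**Field width.** The generator's one free shape parameter is the field
width. The default is `field_sigma = ell/7`. This choice was made once,
on two grounds: (i) it keeps the field-diameter-to-spacing ratio in the
range reported for real grid cells, with clearly separated fields and a
detectable field-size peak in the distance histogram; and (ii) it
places the mean score of a *perfect* grid at the operating point
commonly reported for this class of score, $\Psi \approx 0.35$ — the
value is far below 1 because roughly half of all spikes sit at field
edges where a competing symmetry wins and $\hat\psi_k = 0$. $\Psi$ of a
perfect grid depends directly on this ratio (wider fields mean noisier
neighbor angles), which is why it is a visible, documented knob rather
than a hidden constant.

**What the generator does not emulate:** animal trajectories and
occupancy (spikes are drawn i.i.d., so rate maps are spike densities
without occupancy normalization), temporal spike statistics (no theta
modulation, no refractoriness), firing-rate differences between fields,
and elliptic field shapes. Tests passing on these synthetics therefore
certify the *score computations*, not robustness to every artifact of
real recordings; the shell-detection remedies (`cutoff`, `manual`,
module pooling) exist precisely because real data are harder.

## The reference correlogram score

For comparison, `rho_pipeline` computes the conventional score: a
binned, Gaussian-smoothed spike-density map; its spatial
autocorrelogram (Pearson correlation at every integer lag over the
overlap region, lags with fewer than 20 overlapping bins masked); an
annulus around the six peaks closest to the center; and
$\rho = \min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150})$, where
$r_a$ is the correlation between the annulus and its copy rotated by
$a$ degrees (bilinear interpolation, masked bins dropped pairwise).
Since an autocorrelogram is centrally symmetric, $r_{120} = r_{60}$ and
$r_{150} = r_{30}$ up to interpolation error; the full five-angle form
is kept for fidelity to the standard definition.

**Calibration note.** The fine print of this score varies between
laboratories (annulus rules, smoothing), and the variant used alongside
the spike-based score is not fully specified by public sources. The
package fixes the reconstruction by requiring it to reproduce *both*
reference operating points of the score on the synthetic generator
simultaneously: $\rho \approx 1.5$ for perfect grids and
$\rho \approx -0.5$ for fully randomized field locations. A joint sweep
over the rate-map smoothing and the annulus radii selected smoothing =
half a bin and annulus $[0.5\,\bar d, 1.15\,\bar d]$: narrower annuli
lose the anticorrelation at 30° for perfect grids, wider ones dilute
the rotation correlations of random patterns toward zero. These
constants were frozen before the acceptance checks and are exposed as
arguments (`sigma`, `inner_factor`, `outer_factor`).

**Distributional note.** Across random realizations $\rho$ of
non-grid patterns is strongly right-skewed (occasional accidental
hexagonality), so seed-ensembles are summarized by *medians*, the same
summary the score's box-plot presentations use. $\Psi$ ensembles are
summarized the same way for consistency.

## Classification

`classify_cell` implements the flexible threshold: the score (Ψ or ρ)
is computed on the actual map and on 100 maps with all spike positions
redrawn uniformly over the arena; the threshold is the 95th percentile
(linear interpolation between order statistics, R's quantile type 7,
pinned for cross-implementation determinism) of the shuffled scores,
and the cell is a grid cell only if its actual score strictly exceeds
it. Uniform relocation is used because it preserves exactly what the
flexible threshold needs — the spike count — while destroying all
spatial structure: a hexagonal pattern buried under many background
spikes has a low score, but its shuffled nulls carry the same
background and the threshold scales down accordingly. Shell (or
annulus) detection is re-run on every shuffled map, matching the
end-to-end pipeline; detection failures enter the null at the score's
floor value (0 for Ψ, −2 for ρ), and a failure on the actual map yields
a negative classification with an explicit flag. Because an actual
uniform map and its shuffles are exchangeable, the construction has a
nominal false-positive rate of about 5%, which the test suite verifies
empirically over 200 null maps.

## Numerical and design choices

* **Zero-neighbor spikes** score 0 (flagged `no_neighbors`) rather than
  `NA`, so Ψ is always defined; their orientation is `NA`.
* **Θ over contributing spikes.** Whether spikes with
  $\hat\psi_k = 0$ should enter Θ is unspecified in the sources this
  score family comes from; the package restricts Θ to spikes with
  $\hat\psi_k > 0$ (their $\theta_k$ is hexagonally meaningful) and
  exposes `theta_spikes = "all"` as a switch.
* **Shell boundaries closed** on both sides (a measure-zero choice).
* **Histogram peaks** are strict local maxima of the smoothed curve;
  plateaus take their leftmost bin (determinism).
* **Smoothing uses zero padding**, so rate-map mass is conserved up to
  boundary truncation.
* **Spacing-detection failure is not an error** in the pipeline:
  `psi_scores` returns all-zero, flagged scores, mirroring how such
  cells appear downstream (wrongfully low scores rather than crashes);
  the bare `detect_spacing` signals a typed condition carrying the
  histogram for diagnostics.
* **Partition membership** uses half-open rectangles `[min, max)`
  closed at the arena's outer maximum edges, so strip partitions tile
  the arena with every spike in exactly one region; overlapping custom
  regions resolve by first match.
* **Temporal smoothing at spike times.** The boxcar is evaluated at
  the spike times themselves (not on a regular time grid); with
  identical inputs the two conventions agree wherever spikes exist,
  and the spike-time convention needs no interpolation rule for empty
  stretches.
* **Seeds.** Every stochastic function takes an explicit `seed`;
  generators are bit-reproducible given the seed.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to give stable
statistics: exact-oracle comparisons on 300–600-spike maps (per-spike
equality to 1e-12 against a plain-loop implementation), operating-point
checks on 12–20 maps of 2000 spikes, the null-calibration of the
classifier on 200 uniform maps of 300 spikes, and the Ψ–ρ agreement on
a sweep of 8 jitter levels × 25 maps. The acceptance script
(`scripts/acceptance.R`) re-runs the operating-point and sweep analyses
from scratch at the same sizes.

## Known limitations

* The shell is global: patterns whose spacing varies across the arena
  would need per-spike shells, which the package does not attempt.
* Rate maps are occupancy-free spike densities; with real trajectory
  data the ρ reference should be fed occupancy-normalized maps.
* Strongly elliptic grids can defeat automatic spacing detection
  (the manual and module-pooling modes exist for this case); no
  ellipticity compensation of the correlogram is performed.
* Local averages in small partitions of a *single* cell are biased
  wherever the partition misses that cell's fields; pooling cells of
  different phases is the intended remedy, and single-cell resolution
  is bounded by the grid spacing.
* Three-dimensional firing patterns are out of scope.
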