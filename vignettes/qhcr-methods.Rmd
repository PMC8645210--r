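---
title: "Models and methods behind qhcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qhcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the forward
model the simulator implements, the estimators built on top of it, the
parameters that matter and why their defaults are what they are, and the
places where a design was genuinely open and a choice had to be made.

## Why a simulator

HCR (hybridization chain reaction) imaging amplifies the signal at every
probe-bound target molecule by growing a tethered fluorescent DNA polymer.
Its key quantitative property is that amplified signal scales
approximately linearly with target abundance, which permits *relative*
quantitation of proteins and RNAs at subcellular voxel resolution.
Validating an analysis pipeline for such data requires images where the
abundance of every pixel is known exactly — which no microscope can
provide. The `sim` layer of this package therefore generates multichannel
images from a known ground truth, emulating the statistical structure the
analysis assumes, so that every estimator can be tested against truth at
desk scale.

## The forward model

**Ground truth.** `n_cells` axis-aligned elliptical cells are placed
uniformly in the field (semi-axes drawn within ±30% of
`cell_radius_um`); overlap is permitted, with the later-placed cell
overwriting the earlier in the overlap. Each cell draws a molecule
density per target from the abundance law — lognormal by default, since
per-cell expression in tissue spans orders of magnitude and is
right-skewed — and per-pixel counts are Poisson at that density. A
deterministic law (`density` molecules per pixel exactly) exists for
hand-countable tests. Cells are the only spatial structure; the point is
spatially clustered abundance, not anatomy.

**Detection.** A pixel with $m$ molecules offers
$m \cdot \mathrm{initiators\_per\_probe}$ initiator slots; each triggers
independently with probability
$p_\mathrm{eff} = p\,(1-\iota)$ for antibody probes carrying a full
initiator, or $p^2(1-\iota)$ for split-initiator pairs (both half-probes
must bind adjacently to colocalize a functional initiator), where $p$ is
the binding efficiency and $\iota$ an optional interference probability
between redundant probes competing for epitopes (default 0). Triggered
initiators are Binomial.

**Amplification.** Each initiator grows a polymer whose length in
hairpins follows a geometric law with support ≥ 1 and the configured mean
($1/p$, variance $(1-p)/p^2$). The geometric choice models memoryless
sequential hairpin addition with a constant per-step stopping
probability; only a mean length is reported for real experiments, so the
distribution is an explicit modeling assumption, and a deterministic law
is provided for exact tests. In `h1_only` mode each initiator binds
exactly one hairpin — polymerization cannot proceed without the second
hairpin — so realized length is 1 regardless of the law. Summing $n$
geometric lengths is drawn in one shot as $n + \mathrm{NegBin}(n, p)$.

**Background.** Three components, in fluorophore-equivalent units:

* *AF* (autofluorescence): Gaussian-filtered white noise rescaled to mean
  `af_mean`, relative spread `af_rel_sd` (default 0.3) and correlation
  length `af_corr_length` (µm), clipped at zero. The spread parameter is
  needed because a flat AF field would make the correlation length
  meaningless; 30% relative variation is typical of structured tissue
  autofluorescence.
* *NSD* (nonspecific detection): Poisson(`nsd_rate`) probes per pixel.
  On antibody channels each nonspecifically bound probe still carries a
  full initiator and is amplified under the channel's hairpin mode; on
  split-initiator channels a lone half-probe cannot trigger HCR and
  contributes only single-hairpin-scale signal. This asymmetry is the
  mechanism of automatic background suppression, and the simulator's
  expected antibody/split NSD ratio equals the mean polymer length.
* *NSA* (nonspecific amplification): Poisson(`nsa_rate`) single hairpins
  per pixel — a nonspecifically bound hairpin never nucleates a polymer.

**Optics.** The total fluorophore field is convolved with a Gaussian PSF
(`psf_sigma` in µm, converted to pixels), scaled by `photon_scale`
(counts per fluorophore), subjected to Poisson shot noise if enabled,
then Gaussian read noise and a constant `dark_offset` are added and the
image clips at zero. The convolution uses a circular boundary, which
conserves the image total exactly; this is what lets the noise-free,
certain-binding, deterministic-length configuration satisfy a closed-form
intensity budget (mean intensity = slope × molecules + background + dark)
to 1e-6 relative, a property the test suite asserts.

**Determinism.** One master seed fixes everything. Per-stage and
per-channel substream seeds are derived from it by a seeded
`sample.int`, and the control images (unstained = AF only;
hairpins-only = AF + NSA; h1-only = the full experiment with every
amplifier forced to single-hairpin mode) reuse the same stage seeds, so
controls share the exact AF field realization of the experiment — as
matched control sections aim to in practice.

## Voxel quantitation

**Binning.** Subcellular voxels are non-overlapping pixel blocks;
trailing partial blocks are discarded. The voxel size must be an integer
multiple of the pixel size: a 0.16 µm pixel cannot tile a 2.00 µm voxel
(12.5 pixels), so `bin_voxels()` refuses and `realized_voxel_size()`
implements the package's convention — the largest integer block whose
physical size does not exceed the request (12 pixels = 1.92 µm). The
strict-plus-helper split keeps the core operation exact and the
convention explicit and testable. The default aggregator is the mean,
which keeps intensity units; normalization removes the distinction, and
the sum aggregator (which conserves pixel totals exactly) is available.

**Normalization.** Voxel values have the dark offset and an estimated
background level subtracted, clip at zero, and are divided by their
0.995 quantile, clipping at 1. A quantile slightly below the maximum
resists single hot voxels; with percentile 1.0 the transform is plain
max-normalization. A degenerate all-equal grid maps to all ones (defined,
not an error); a grid with nothing above background has no scale and is
an error.

**Expressing-voxel mask.** Correlations computed over the whole field are
dominated by the dense blob of empty extracellular voxels at the origin,
which inflates $r$ without saying anything about quantitation. The mask
keeps voxels exceeding background mean + $k\sigma$ (default $k = 2$) in
at least one channel. On simulated data with signal-to-background ≥ 20
the mask recovers ≥ 95% of truly expressing voxels (asserted in tests).

**The scatter fit.** The two-channel line is fitted by total least
squares — the principal eigenvector of the 2×2 covariance — because
under redundant detection both channels carry comparable noise and
ordinary least squares would attenuate the slope. OLS is available for
comparison. The fit reports slope, intercept, Pearson $r$, and the RMS
perpendicular distance to the line (`orth_rms`). Accuracy is judged by
the intercept: the package adopts $|b| \le 0.05$ on the normalized scale
as "approximately zero" (no published tolerance exists, so the package
defines one). Zero variance in either channel is an error — $r$ is
undefined there, and silently returning something would hide a broken
input. A vertical principal axis (infinite slope) is likewise an error.
The brute-force oracle used in tests minimizes orthogonal SSE over an
(angle, offset) grid with refinement, independent of the
eigendecomposition.

**Read-out / read-in.** Read-out returns the normalized intensity pairs
of every voxel whose pixel footprint intersects an anatomical region
(empty intersection is an empty result, not an error). Read-in marks the
pixel footprint of every voxel whose pair falls inside a simple polygon
in expression space; the boundary counts as inside, and self-intersecting
polygons are rejected by a pairwise segment-intersection check. The
point-in-polygon test is an even-odd ray cast with an explicit
on-boundary check, written in the package because no installed library
offers the boundary-inclusive semantics with this error contract.

## Signal, background, gain

**Component decomposition** is sequential subtraction over matched
controls: AF from the unstained control; NSA from the hairpins-only
control in excess of AF; NSD from a non-expressing region of the
experiment in excess of both. Estimates clip at zero with a warning
(never silently negative), and a missing control leaves its component —
and everything downstream of it — reported as unresolved (`NA`), never
silently zero. Components add to the total exactly by construction.

Because autofluorescence has spatial structure, the package measures
control means over the region the estimate will be applied to (the
`region` argument; default the whole image), and the NSD step is always
region-matched internally: AF and NSA are re-measured on the
non-expressing mask before subtraction. Without this, AF fluctuations of
a few percent leak into NSD and, more damagingly, into the small h1-only
signal of a gain measurement.

**Signal-to-background** is the mean dark-subtracted intensity over a
signal mask, minus the background total, divided by it. Negative signal
clips to zero with a warning; zero background is an error (the ratio is
undefined). The ratio is invariant under multiplying the image and its
controls by any positive constant (dark 0), which the acceptance suite
checks to 1e-6.

**Amplification gain** is the ratio of background-subtracted signal
between the paired-hairpin and h1-only arms. With equal fluorophores per
hairpin in both arms — an assumption the package documents rather than
checks — the ratio is the mean polymer length in hairpins. Background is
subtracted per arm (whether published measurements subtract per-arm or
jointly is not stated anywhere we could consult; per-arm is the
conservative choice since the two arms have different NSD scales).
Nonpositive h1-only signal makes the gain unidentifiable and is an
error. The median over scenarios uses the usual convention: middle value
for odd counts, mean of the middle two for even.

**Crowding diagnostic.** A saturation effect (local fluorophore crowding,
detector nonlinearity) could compress both channels together and let
voxel pairs slide along the fitted line undetected. The diagnostic
stratifies masked voxels into quantile bins of total intensity
$x_1 + x_2$ (default 4 strata, each requiring ≥ 10 voxels on average),
fits the TLS slope per stratum, and flags when any stratum deviates from
the global slope by more than 20% relative. The threshold is
package-defined: large enough to ignore stratum-level estimation noise
at a few hundred voxels, small enough to catch a cap anywhere inside the
dynamic range (both behaviors asserted over seeds in the tests).
Zero-variance strata are dropped and reported rather than fatal.

## Defaults at a glance

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `mean_polymer_length` | 180 | hairpins | published median gain scale |
| `length_law` | geometric | — | memoryless growth; only the mean is known |
| `binding_efficiency` | 1 | probability | exact tests; demo uses 0.45 |
| `interference` | 0 | probability | redundant-probe interference is possible but unquantified |
| `af_rel_sd` | 0.3 | relative | structured-tissue AF variation |
| voxel request | 2 | µm | subcellular scale used in published analyses |
| normalization percentile | 0.995 | quantile | outlier-resistant scale |
| mask `k` | 2 | SDs | standard detection threshold |
| crowding threshold | 0.2 | relative slope | see above |
| intercept acceptance | 0.05 | normalized units | package-defined "approximately zero" |

## Problem sizes and what passing tests show

The simulated studies run at 288² pixels (0.16 µm pixels, ≈ 46 µm field,
20 cells) for the full worked example, 512² for background-component and
S/B recovery, and 64–128² for property checks over many seeds; these
sizes give a few hundred expressing voxels and component standard errors
comfortably inside the asserted tolerances while keeping the whole suite
fast on one CPU. The demo's emergent signal-to-background (≈ 80–120
across seeds) lands in the range reported for real FFPE/cell experiments,
which is a consistency check on the chosen background scales, not a
calibration to any particular published value.

The generator emulates linear signal scaling, polymer-length dispersion,
the three background components, PSF blur and camera noise. It does
**not** emulate: real anatomy (cells are ellipses), probe depletion or
epitope saturation at extreme density (so the crowding diagnostic's null
is genuinely linear by construction), chromatic registration error,
bleed-through between channels, photobleaching, or 3D optics (z-planes
would be independent). A pipeline passing these tests is therefore shown
to be correct *given* linear amplification physics; it is not evidence
about any particular real sample.

## Numerical conventions

Images are row-major matrices, origin top-left, physical sizes in µm;
voxel footprints map back to 0-based pixel offsets. Intensities are
stored on disk as 32-bit TIFF samples scaled by an exact power of two
recorded in a JSON sidecar, so round trips are exact to the 2⁻³² sample
quantization and repeated writes are byte-identical. All simulator
randomness flows through substream seeds derived from one master seed;
reruns are bit-identical, including controls and every CLI output.
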