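# qhcr

Quantitative analysis and simulation of hybridization chain reaction (HCR)
fluorescence imaging.

HCR signal amplification grows a tethered fluorescent polymer at every
probe-bound target molecule, and the amplified signal scales approximately
linearly with target abundance. That linearity is what makes *qHCR
imaging* possible: relative quantitation of protein and RNA targets at
subcellular voxel resolution, directly in an anatomical context. This
package implements the analysis side of that idea for people developing or
validating HCR-style imaging pipelines:

- **Voxel quantitation** — binning multichannel images into subcellular
  voxels, background-subtracted normalization, and the two-channel
  accuracy/precision analysis for redundant detection (one target, two
  spectrally distinct amplifiers). Accuracy is linearity with zero
  intercept; precision is the scatter around the line.
- **Signal/background decomposition** — estimating autofluorescence (AF),
  nonspecific detection (NSD) and nonspecific amplification (NSA)
  components from unstained and hairpins-only controls, and the
  signal-to-background ratio.
- **Amplification gain** — estimating the mean polymer length in hairpins
  by comparing paired-hairpin (h1 + h2) against h1-only experiments, in
  which polymerization cannot proceed.
- **Read-out / read-in gating** — mapping anatomical regions into
  two-channel expression space and polygonal expression-space gates back
  onto anatomy.
- **A synthetic image generator** with known ground truth that emulates
  the relevant physics — probe binding, geometric polymer growth, the
  three background components (with the antibody/split-initiator
  suppression asymmetry), PSF blur, shot and read noise — so every
  analysis stage is testable without microscope data.

## The model in brief

For a channel with per-molecule effective trigger probability
`p_eff` (= `binding_efficiency · (1 − interference)` for antibody probes
carrying a full initiator, and `binding_efficiency² · (1 − interference)`
for split-initiator pairs), a pixel with `m` molecules triggers
`Binomial(m · initiators_per_probe, p_eff)` initiators. Each initiator
grows a polymer of `L` hairpins, `L ~ Geometric` with support ≥ 1 and mean
`1/p` (or deterministic), contributing `L · fluors_per_hairpin`
fluorophores. The camera sees the fluorophore field convolved with a
Gaussian PSF, scaled to photons, with Poisson shot noise, Gaussian read
noise and a constant dark offset.

The two-channel line is fitted by **total least squares** (orthogonal
regression, via the principal axis of the 2×2 sample covariance), because
both channels carry comparable noise under redundant detection. The
amplification gain is `signal_paired / signal_h1_only` after per-arm
background subtraction, which equals the mean polymer length when both
arms use equal fluorophores per hairpin.

## Worked example

```r
library(qhcr)
demo <- qhcr_demo(seed = 1, out_dir = "demo_out")
print(demo)
```

```
qHCR worked example (synthetic redundant-pair experiment)
  voxels: 1.92 um, 239 fitted
  scatter: r = 0.9985, slope = 1.0044, intercept = -0.00095, orth RMS = 0.00860
  S/B: ch1 86.9, ch2 81.7
  amplification gain: 180.4 hairpins (truth 180)
  crowding: not flagged (max rel slope dev 0.100)
```

The demo simulates one target detected redundantly in two channels at
published-protocol scale (0.16 µm pixels; requested 2 µm voxels realized
as 1.92 µm = 12×12 pixel blocks; geometric mean polymer length 180), then
runs the full analysis. The Pearson `r` near 1 and intercept near 0 say
the amplified signal tracked abundance linearly through both channels;
the orthogonal RMS of 0.0086 (on the normalized [0, 1] scale) is the
precision; the gain estimate of 180.4 hairpins recovers the simulated
polymer length; and the crowding diagnostic confirms the per-stratum
slopes are consistent with the global one, ruling out a saturation
artifact sliding points along the line. `demo_out/` receives the TIFF
stacks, a `report.json`, the voxel pair CSV and a sidecar echoing every
resolved parameter.

The same stages are scriptable individually (`simulate_experiment()`,
`bin_voxels()`, `normalize_voxels()`, `fit_scatter()`,
`estimate_background_components()`, `signal_to_background()`,
`estimate_gain()`, `crowding_diagnostic()`, `read_out()`/`read_in()`) or
from the shell via `inst/cli/qhcr` (subcommands `simulate`, `quantify`,
`sb`, `gain`, `crowding`, `demo`; every run is byte-reproducible given its
seed).

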