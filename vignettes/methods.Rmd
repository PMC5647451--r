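---
title: "Methods: sequential PIXE/PIGE quantification of root-dentin lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential PIXE/PIGE quantification of root-dentin lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpixe)
```

## The measurement problem

Root caries begins with acid-driven loss of mineral (mainly calcium) from
exposed root dentin; fluoride-containing materials (FCMs) are thought to slow
it by supplying fluorine that stabilizes the apatite.  Proton-microbeam line
scans quantify both sides of this exchange on the *same* specimen, before and
after an in-vitro acid challenge: the Ca K&alpha; X-ray yield (PIXE) tracks
calcium, the ¹⁹F(p,&alpha;&gamma;)¹⁶O gamma yield (PIGE) tracks fluorine, and
a 4 µm copper foil placed 800 µm inside the dentin edge provides the
positional reference that lets the two scan occasions be superimposed.  A
micro-CT grey-value profile of the same line, calibrated against
hydroxyapatite phantoms, provides an independent mineral-density measurement.

`seqpixe` implements the full analysis chain — calibration, fiducial
registration, lesion-boundary detection, the four integral lesion metrics,
and the cohort statistics — together with a synthetic-specimen generator so
every stage is testable without instrument data.

## The lesion model behind the generator

No parametric lesion model is part of the measurement itself; the generator
needs one so that ground truth exists.  With depth $z$ (µm) measured from the
original dentin edge:

* **Calcium.** Before demineralization the profile is flat at `ca_sound`
  (default 27 wt%, a domain-typical intact-dentin value).  After
  demineralization, material shallower than `erosion` is gone, and the
  remaining profile ramps sigmoidally from `ca_surface_after` back to
  `ca_sound`:
  $\mathrm{Ca}(z) = c_s + (c_0 - c_s)\,\sigma\!\big((z - e - m)/w\big)$,
  with midpoint $m$ (`lesion_mid`) and width $w$ (`lesion_width`).  The
  sigmoid was chosen because every boundary crossing and depth integral has
  a closed form (`true_ca_loss()`), giving analytic oracles for the tests.
* **Fluorine.** An exponential uptake profile
  $F(z) = F_0 e^{-z/\lambda}$, with decay length `f_decay` before
  demineralization and `f_decay * f_depth_gain` (default gain 1.8) after —
  fluorine penetrates deeper once the lesion is porous.  Control specimens
  have $F_0 \approx 0$.
* **Coupling.** For FCM specimens, `lesion_mid` and `erosion` are attenuated
  by $1 - \kappa \min(F_0/F_{\mathrm{ref}}, 1)$ with `coupling_kappa`
  $\kappa$ (default 0.6): higher fluorine uptake produces a genuinely milder
  lesion.  This single multiplicative mechanism is the simplest one that
  produces the negative fluorine–Ca-loss association the cohort statistics
  are designed to detect.
* **Pairing.** Each tooth contributes one FCM and one control specimen.  The
  two halves share the tooth's chemistry (`ca_sound`, `f_decay`) and a
  log-normal lesion-severity latent (sd `severity_sd`, default 0.25) that
  scales `lesion_mid` and `erosion`; all other lesion parameters are drawn
  per specimen.  This reproduces the paired design (halves of one tooth are
  more alike than two teeth) without making the halves identical.

### Counting model

Each scan point accumulates charge $q$ and reports Poisson counts with mean
$\text{yield} \times \text{concentration} \times q + \text{background}$ per
channel.  The Cu channel responds through the overlap of a Gaussian beam spot
(FWHM `spot_fwhm`, default 10 µm) with the 4 µm foil top-hat.  The default
step is 10 µm over a 1000 µm line with the dentin edge at stage position
100 µm.  Each scan occasion carries an independent rigid stage offset
$\sim N(0, \texttt{offset\_sd})$, default sd 20 µm.  A documented noise-free
mode (`noise = "none"`) returns the Poisson means exactly, which is what
makes the calibration round-trip tests exact.

The numeric yields (50 counts per wt%·charge for Ca, 0.2 per ppm·charge for
F, backgrounds of a few counts per point) are generator stand-ins, not
estimates of any instrument; they were chosen once to give a few-percent
relative Poisson error on sound dentin.

### What the generator does *not* emulate

Real dentin tubule structure, lateral heterogeneity between the two analysis
lines (the lines differ only by counting noise here), energy-resolved
spectra, matrix/stopping-power effects, detector dead time, and any 2-D
geometry.  Passing tests therefore demonstrate that the *analysis chain* is
correct under its stated statistical model — not that the model captures
every property of real specimens.

## Calibration

Yield is modelled as linear in concentration (first-order physics for both
PIXE and PIGE), fitted by least squares with an intercept that absorbs the
per-unit-charge background; micro-CT grey values are affine in mineral
density, fitted against the phantom set (100–400 mg/cm³ hydroxyapatite disks
plus a 1550 mg/cm³ aluminium pole).  A quadratic option (`degree = 2`)
exists for curvature checks but is off by default.

The fluorine channel is calibrated against the fluoridated-apatite series
Ca₁₀(PO₄)₆(OH)₂₋₂ₓF₂ₓ, x = 0, 0.25, 0.5, 0.75, 1, whose fluorine content is
computed stoichiometrically (`reference_f_content()`; 0 to ≈3.77 wt%).  The
same series is nearly constant in *calcium* (39.7–39.9 wt%), which makes it
an ill-conditioned design for the Ca channel — fitted slopes become wildly
unstable under noise.  The pipeline therefore calibrates Ca against a
synthetic dilution series (0–40 wt% in 10 wt% steps); the reference-material
interface accepts any direct-concentration table.

Calibrated concentrations below zero are floored at zero: counts below
background cannot mean negative concentration.  The floor slightly biases
near-zero fluorine upward (visible in control-group F uptake), which is
documented rather than hidden because removing it would put negative
concentrations into the uptake integrals.

The fluorine detection limit defaults to the concentration equivalent of
$3\sqrt{\text{background}}$ (`derive_f_lod()`), the usual counting-statistics
convention, because "undetectable" is otherwise undefined.

## Registration

One reference point determines translation only, so registration is a rigid
1-D shift.  The foil centre is located per scan as the background-subtracted,
counts-weighted centroid of the contiguous Cu cluster exceeding
$\text{bg} + 3\sqrt{\text{bg}}$ around the global maximum — centroiding gives
sub-step precision (the tests require the recovered shift within half a step
for offsets drawn at the study's 20 µm scale).  The after profile is then
linearly interpolated onto the before grid; grid ends not shared by both
scans are flagged missing, never extrapolated.  If several disjoint clusters
of fiducial-like height appear, the one containing the global maximum wins,
with a warning.

Micro-CT profiles carry no fiducial.  `align_uct_pair()` implements a
grid-search rigid shift minimizing the squared difference over a sound-region
window, but a featureless plateau identifies translation only weakly (about
half a voxel when an edge is in the window), so the generator's default µCT
inter-scan offset is 0 — scanner-bed coordinates are treated as reproducible
— and the alignment is flagged approximate.

## Lesion metrics

All metrics work on 10 µm bin averages anchored at the Cu reference
(`bin_width`, half-open bins centred at $\mathrm{ref} - k w$), mirroring the
protocol of averaging at 10 µm intervals from the surface to the reference
point:

* **Intact dentin** is the mean Ca over a 200 µm window adjacent to the
  reference (`intact_window`); the protocol does not specify the averaging
  region, so a fixed window on the sound side of the analysis region was
  chosen.
* **Boundaries**: the outermost lesion surface is the first
  linearly-interpolated crossing of 5% of intact Ca scanning inward; the
  innermost surface is the first crossing of 95% at or after it.  A profile
  that never drops below 95% has no lesion; one entirely below 5% never
  reached the tooth and errors.  A profile that *starts* above 5% takes its
  first point as the surface (the scan began inside the tooth).
* **Ca loss** (wt%·µm) is the rectangle-rule sum of
  $(\mathrm{Ca}_{\mathrm{before}} - \mathrm{Ca}_{\mathrm{after}})$ bins from
  the **before** profile's outer surface to the reference.  The before
  surface is used so that eroded material counts as loss.  Negative bin
  differences are kept by default (unbiased under noise); a
  `clamp_nonnegative` flag exists.  Missing bins are excluded and counted.
* **F uptake** (ppmF·µm) cumulates fluorine bins over the same region; by
  default both occasions integrate from the before surface (one common
  region), with a `respective`-surface option.
* **F penetration** (µm) is the distance from the outer surface to the first
  bin below the detection limit, 0 if the first bin is already below it.
  Bin-level resolution was chosen to match the binned protocol.
* **Mineral loss** (mg/cm³·µm) applies the same integral to the aligned
  density profiles, with the reference set 800 µm inside the detected
  surface to mirror the foil placement.

Two analysis lines per specimen are analysed independently and averaged into
one set of per-specimen metrics before any statistics, mirroring the
two-lines-per-specimen instrument protocol.

### Numerical behaviour worth knowing

With the default step equal to the bin width there is exactly one sample per
bin, and the rectangle sum carries an irreducible discretization bias of a
few percent relative to the analytic truth integral (the surface half-bin
and point-sampling of the curved profile).  This is a property of the
10-µm-interval protocol, not of the implementation: the noise-free
analytic-recovery test samples at 1 µm (ten points per bin) and the same
code then matches the closed-form truth to within 1–2%.  At the study's
default conditions the estimated-vs-true Ca-loss regression slope stays
within the 0.9–1.1 band the tests enforce.

## Cohort statistics

Groups are compared with a two-sided Mann–Whitney U test (95% confidence,
as in the protocol); correlations use Spearman's rank coefficient (99%
confidence).  For the study's sample sizes (n = 9 per group) the U test is
*exact*: all $\binom{n_1+n_2}{n_1}$ labelings are enumerated with midranks,
so ties are handled exactly too.  The enumeration threshold (both n ≤ 10)
was chosen to cover n = 9; larger samples use the tie-corrected,
continuity-corrected normal approximation.  Spearman p-values use the
t-approximation by default with an exact permutation option for n ≤ 9.
Two-sided tests were chosen throughout because the protocol does not state
sidedness and two-sided is the conservative convention.  The specimens are
paired by tooth, yet the protocol applies an *unpaired* test; the package
mirrors that choice rather than "improving" on it.

`cohort_report()` assembles per-group medians and ranges for all six
metrics, the six group comparisons, and four Spearman correlations
(Ca loss vs mineral loss; F uptake before vs Ca loss; F penetration before
vs Ca loss; and the FCM-only penetration correlation).  A group with fewer
than two specimens flags the report underpowered and skips the tests
instead of failing, so a single-pair pilot run still produces a complete
artifact.

## Worked example

```{r example, eval = FALSE}
library(seqpixe)
config <- pipeline_config(quiet = TRUE)        # 9 tooth pairs, 2 lines each
res <- run_pipeline(config, "run1", seed = 1)
print(res$report)
```

## Problem sizes and determinism

Every simulator is a pure function of its parameters and seed; a master seed
spawns independent per-scan streams, and the RNG state of the caller is
never disturbed.  The test suite exercises the pipeline at the study's
design size (9 pairs) and at 25-pair (50-specimen) cohorts for the recovery
and correlation properties; the type-I-error property uses 2000 simulated
null cohorts with the exact U distribution memoized per sample-size pair.

## Known limitations

* The lesion and uptake profiles are parametric stand-ins; none of the
  generator's numeric yields or concentrations estimate a real instrument
  or specimen.
* Micro-CT alignment from a featureless plateau is weakly identified; the
  pipeline relies on reproducible scanner coordinates.
* The zero floor on calibrated concentrations biases near-zero fluorine
  upward, so control-group F uptake is a background-level positive number
  rather than exactly zero.
* At one sample per bin, integral metrics carry a few-percent
  discretization bias relative to the continuous truth; finer scan steps
  remove it.
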