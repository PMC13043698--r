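---
title: "Quantitative pleural/subpleural lung ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pleural/subpleural lung ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bedside assessment of lung aeration in very preterm infants currently
relies on chest X-ray (ionising radiation, poor quantitation) or on visual
lung-ultrasound scoring (categorical, operator-dependent). The pleural
line and the tissue immediately beneath it respond to pressure- and
volume-mediated changes in aeration, so a narrow pleural/subpleural region
of interest (ROI) carries aeration information that can be quantified
objectively from the image itself.

`qlus` implements that quantification as a tested pipeline: read a
monochrome ultrasound frame, rasterise a pleural ROI, compute one
first-order feature (mean grey value, MGV) and five second-order
grey-level co-occurrence matrix (GLCM) features, average the eight imaged
lung zones into a single Q-LUS value per infant, and rank-correlate those
values against two noninvasive oxygenation indices — the oxygen saturation
index (OSI) and the SpO2/FiO2 (S/F) ratio — overall and per ultrasound
machine.

## The region of interest

The ROI is a band hanging from the pleural line:

* superior boundary: the pleural line itself (included), supplied as a
  polyline of `(column, row)` vertices with strictly increasing columns;
* lateral boundaries: a half-open column interval `[col_min, col_max)`,
  in practice the gap between the adjacent rib shadows. Half-openness
  makes adjacent intercostal windows compose without double counting;
* inferior boundary: a fixed depth below the pleural row, default 50
  pixels (roughly 1 mm at typical neonatal linear-probe settings;
  `depth_from_mm()` converts a physical depth given the pixel spacing).

Pleural rows at non-vertex columns are linearly interpolated and rounded
half-up — an arbitrary but deterministic tie-break. A band that would run
past the bottom of the frame is an error rather than a silent clip,
because clipping changes the pixel count and hence every downstream
feature. Masks below a configurable minimum size (default 100 px) are
rejected as degenerate. ROI placement is authored externally (JSON) or
taken from the synthetic generator's ground truth; the package
deliberately does not segment the pleural line on clinical images.

## Image quantisation

Frames are held as integers on the standardised 256-level greyscale range
(0–255). Deeper stored data (e.g. 16-bit DICOM) is reduced with floor
scaling, `floor(raw * 255 / source_max)` with
`source_max = 2^BitsStored - 1`: deterministic, monotone, and the identity
on data that is already 8-bit. A round-half-up variant is available for
parity with viewers that round. Only single-frame monochrome images are
accepted (uncompressed little-endian DICOM or 8-bit greyscale PNG);
colour, compressed transfer syntaxes and cine loops are rejected.

## Texture model

The GLCM counts ordered pixel pairs displaced by `offset = (d_row,
d_col)` in which **both** endpoints lie inside the ROI mask, so pairs
straddling a rib shadow or the band edge never contribute. Defaults:

| parameter | default | why |
|---|---|---|
| `levels` | 256 | full 8-bit range, no re-binning; coarser binning is config |
| `offset` | `(0, 1)` | 0°, distance 1 — horizontal neighbours only |
| `symmetric` | `TRUE` | each pair also counts transposed, `p(i,j) = p(j,i)` |
| entropy base | `e` | natural log; base 2/10 available |

With probabilities `p(i,j)` over grey levels `i, j` in `0..255`, the five
features are

* angular second moment `ASM = sum p(i,j)^2` (uniformity),
* `contrast = sum (i-j)^2 p(i,j)` (local variation),
* `correlation = (sum i j p(i,j) - mu_x mu_y) / (sigma_x sigma_y)` with
  `mu, sigma` from the marginals (linear dependency of neighbouring grey
  levels; the one *relative* feature),
* inverse difference moment `IDM = sum p(i,j) / (1 + (i-j)^2)`
  (homogeneity),
* `entropy = -sum p log p` with `0 log 0 = 0` (randomness),

plus MGV, the plain masked mean. On a constant region the marginal
variances vanish and correlation is **undefined**: the package returns
`NA` and excludes that zone from the subject's correlation mean (with a
warning) rather than imputing 0 or 1 — any imputation would bias the
cohort ranks. The single-direction default mirrors the horizontal-only
analysis this pipeline quantifies; vertical structures such as B-lines are
consequently under-represented in the texture features, which is a known
limitation of the approach rather than of the implementation.

The pair counting and the feature sums are implemented in a small C++
kernel (long-double accumulators, so results match R's extended-precision
summation); the test suite checks every feature against a naive
double-loop enumeration oracle at 1e-10 on hundreds of random frames.

## Oxygenation indices

For each infant: `S/F = SpO2[%] / FiO2[fraction]` always, and
`OSI = MAP * FiO2 / SpO2` whenever a mean airway pressure is available —
under CPAP the set pressure is taken as the MAP; infants on no support or
nasal high flow have no MAP and contribute to the S/F column only. FiO2
and SpO2 enter the OSI on a common percentage scale (so
`OSI(10, 1.0, 100) = 10`), the standard clinical convention; a
raw-fraction variant sits behind a flag. S/F is computed for every infant,
not only the MAP-less ones, so both index columns can be populated
cohort-wide.

Zone aggregation is strict by default: all 8 zones (LAL, LAU, LLL, LLU,
RAL, RAU, RLL, RLU) must be present, and each feature's subject value is
the arithmetic mean over the zones where it is defined. A lenient mode
(≥ 6 zones, with a warning) exists for ablation experiments.

## Correlation engine

Spearman's rho is the Pearson correlation of average ranks (ties get mean
ranks), computed explicitly rather than through the tie-free
sum-of-squared-differences shortcut. Supporting machinery:

* **p-values** — exact permutation distribution over all `n!` rank
  permutations for `n <= 8`, t-approximation
  `t = rho sqrt((n-2)/(1-rho^2))` above. The t-approximation is coarse at
  tiny n: across the full rank space its worst-case deviation from the
  exact p is about 0.077 at n = 5, 0.048 at n = 6 and 0.027 at n = 7.
* **confidence intervals** — seeded bootstrap percentile (2000 pair
  resamples) by default, Fisher-z `tanh(atanh(rho) ± z/sqrt(n-3))` as the
  alternative. Fisher-z bounds always lie in `[-1, 1]`; published tables
  built on un-truncated normal approximations can show bounds outside
  that range, which is one reason both methods are provided and neither
  claims to reproduce any particular published interval.
* **strength labels** — half-open intervals on `|rho|`:
  weak `< 0.30 <=` fair `< 0.50 <=` moderate `< 0.70 <=` strong. The
  half-open closure of the printed category gaps (0.49→0.50, 0.69→0.70)
  makes the classifier total.
* **table assembly** — one cell per (feature × index × subgroup), with
  subjects dropped pairwise per cell, cells under 4 subjects omitted with
  a warning, degenerate cells kept with `NA` and a note, significance at
  p < 0.05, and no multiple-testing correction by default (a
  Benjamini–Hochberg flag exists for reuse). The wide rendering marks
  non-significant cells `NS`.

## The synthetic cohort generator

Because clinical images cannot be redistributed, the generator produces
cohorts in the study's shape — 70 infants × 8 zones, two machine
subgroups — with a known latent aeration level `a ~ Beta(2, 2)` per
infant driving both sides:

* **imaging**: Rayleigh speckle (the standard first-order ultrasound
  envelope model), a bright pleural band of mean `b0 + b1 a`
  (80 + 100·a) following a gently jittered polyline, vertical B-line
  streaks numbering `round((1-a) * 6)` (bright columns below the pleural
  line, perpendicular to it, as the artefact appears in vivo), dark rib
  shadows at the lateral edges, and a per-machine global grey remapping
  (gain/offset) emulating vendor post-processing;
* **clinical**: `SpO2 = clip(88 + 10 a + N(0, 2), 80, 100)`,
  `FiO2 = clip(0.21 + 0.5 (1-a) + N(0, 0.05), 0.21, 1)`,
  `MAP ~ N(9, 1.5)` clipped to `[5, 16]` cmH2O, 60% of infants on a
  MAP-delivering mode; zone-level aeration is `clip(a + N(0, 0.1), 0, 1)`.

The link coefficients and noise levels were fixed once so that the
simulated OSI (roughly 2–8) and S/F (roughly 120–420) spans resemble a
preterm cohort
on noninvasive support; they are module defaults, not estimates from any
clinical dataset. Frame geometry is 80 × 96 px with the pleural line near
row 18 — small enough to run hundreds of full-pipeline replicates on one
core while leaving the full 50-pixel ROI depth intact.

What the generator does **not** emulate: wave propagation, A-lines,
consolidation "shred signs", pleural effusion, probe-pressure artefacts,
or realistic inter-operator gain variation. Passing tests therefore
demonstrate that the pipeline's arithmetic and plumbing recover a known
monotone aeration→oxygenation link from speckled images; they say nothing
about clinical discrimination on real lungs.

## The sign-recovery experiment and its null

`sign_recovery_experiment()` repeats the whole study end to end and
reports the fraction of replicates in which `rho(MGV, OSI) < 0` **and**
`rho(MGV, S/F) > 0`. Under the default generator this rate is essentially
1 across 200 replicates of 70 infants.

With the link severed (`null_params()`: `b1 = s1 = f1 = 0`) each
individual sign behaves as a fair coin and the joint rate collapses to
chance level. One caveat belongs on record: the joint event is not
exactly the product of two independent coins, because OSI and S/F are
built from the same FiO2 and SpO2 draws and their rank correlations with
any feature are therefore negatively dependent
(`analysis/04_sign_recovery.R` prints the observed dependence between
the two rhos across null replicates). Negative dependence between
`{rho1 < 0}` and `{rho2 > 0}` nudges the joint probability somewhat
above the naive 1/4, so measured null rates land in the high 0.2s to
low 0.3s depending on the seed — consistent with, but not centred on,
the independence value. The measured rate for any given seed is reported
by `scripts/acceptance.R` as `null_joint_sign_rate`.

## Numerical choices, in one place

* floor scaling for bit-depth reduction; exact in double precision for
  raw values up to 2^46/255;
* half-up rounding for interpolated pleural rows and mm→px depths;
* GLCM normalisation checked to 1e-12; undefined correlation as `NA`,
  never imputed;
* entropy convention `0 log 0 = 0`; natural log;
* permutation p-values use a 1e-12 slack when counting `|rho_perm| >=
  |rho_obs|` to absorb floating-point ties;
* every stochastic step (simulation, bootstrap, Monte-Carlo experiments)
  is a pure function of an integer seed; derived sub-seeds stay below
  2^31.

## Problem sizes used by the test suite

Chosen as the package's own trade-off between evidence and runtime on a
single core: 200 random 16 × 16 frames for the GLCM oracle; 100 random
ROI specifications against per-pixel brute force; 1000 replicates at
n = 70 for type-I calibration; 200 full-pipeline replicates of a
70-infant cohort for the sign-recovery experiment (and 200 more for its
null). The complete suite runs in roughly a quarter of an hour.

## Known limitations

* One GLCM direction (0°) by default; multi-offset averaging is left as a
  configuration extension.
* No automated pleural-line or rib-shadow detection: ROI placement is an
  input.
* The machine effect is a global monotone grey remapping; real
  vendor-specific processing is richer and can reorder textures, which is
  precisely why the relative correlation feature is of interest.
* OSI and S/F are themselves imperfect surrogates of aeration; the
  synthetic link is monotone by construction, which real physiology is
  not guaranteed to be.
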