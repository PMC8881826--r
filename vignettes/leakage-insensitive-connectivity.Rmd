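---
title: "Leakage-insensitive MEG functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-insensitive MEG functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megconn)
```

## The problem

Source-reconstructed M/EEG signals are linear mixtures of the underlying
neuronal sources: beamforming cannot fully unmix volume conduction and field
spread, so any two region-of-interest (ROI) time series share an
instantaneous (zero-lag) component. Naive connectivity measures — zero-lag
correlation, plain amplitude envelope correlation (AEC), coherence — are
inflated by this leakage and produce spurious networks. `megconn` implements
the two standard metrics that are insensitive to zero-lag mixing, together
with the surrounding resting-state analysis pipeline and a synthetic
generator that provides ground truth for every stage.

## Metrics

**Phase lag index (PLI).** With instantaneous phases $\varphi_x(t_k)$,
$\varphi_y(t_k)$ from the analytic signal of the band-filtered channels and
$\Delta\varphi(t_k) = \varphi_x(t_k) - \varphi_y(t_k)$,

$$\mathrm{PLI} = \bigl|\,\langle \operatorname{sign}[\,\sin \Delta\varphi(t_k)\,]\rangle\,\bigr| .$$

The PLI measures the asymmetry of the phase-difference distribution around
zero. A mixture of sources at zero lag concentrates $\Delta\varphi$
symmetrically around $0$ (or $\pi$), contributing nothing; a constant lag
strictly inside $(0, \pi)$ gives PLI $= 1$. `sign(0) = 0`, so an exactly
zero-lag pair scores exactly 0.

**Corrected amplitude envelope correlation (AEC-c).** For each ordered pair,
the zero-lag component of $x$ is removed from $y$ by least-squares regression
of the band-filtered series (with intercept); the Hilbert envelope of the
residual is then Pearson-correlated with the envelope of $x$. The two
directions are averaged as raw correlations and rescaled $(\bar r + 1)/2$
into $[0, 1]$, so independent envelopes score $0.5$. The uncorrected AEC,
$(r + 1)/2$ of the raw envelopes, is retained only as a leakage-sensitivity
comparator.

Orthogonalization acts on the *signals*, not the envelopes (a
`on = "envelope"` variant exists behind an argument switch). The zero-lag
leakage model is linear in the signals, so signal-level regression removes it
exactly; envelope-level regression removes it only approximately. Signals are
demeaned before envelope extraction, which makes the metric exactly invariant
to positive affine scaling of either channel.

Degenerate pairs (exactly collinear channels, whose residual vanishes) map to
the metric's theoretical null (PLI 0, AEC/AEC-c 0.5) rather than aborting the
matrix; the count is kept in the matrix's `n_degenerate` attribute.

## Pipeline conventions

* **Sampling and epochs.** Recordings at 1250 Hz are downsampled by 4 (to
  312.5 Hz) after a brick-wall anti-alias low-pass at 0.8 × the new Nyquist
  frequency, then segmented into non-overlapping 4096-sample epochs
  (13.1072 s). Each epoch carries an integer quality score, 1 (artefact-free)
  to 4 (strong artefacts); the 10 best-scoring epochs per subject enter the
  analysis, ties broken by earlier position in the recording. Note the
  numerically *lowest* score is the best quality.
* **Filtering.** All filters are brick-wall DFT masks: a bin with folded
  frequency $f$ is kept iff $f_{lo} \le f < f_{hi}$. The half-open convention
  makes the five canonical bands — delta 0.5–4, theta 4–8, alpha 8–13, beta
  13–30, gamma 30–48 Hz — an exact partition of 0.5–48 Hz, so the five
  band-filtered signals sum to the 0.5–48 Hz-limited signal to rounding
  error.
* **Hilbert transform.** Phases/envelopes are computed on the full epoch with
  no padding or trimming; epochs are fixed-length and artefact-free by
  selection, and property tests exclude 5% of samples at each edge where the
  finite-length analytic signal is distorted.
* **Relative power** is the periodogram power in each band divided by the
  total over 0.5–48 Hz (the union of the five bands), so the five fractions
  sum to one. A single non-tapered DFT per epoch is used, averaged across the
  selected epochs. **Peak frequency** is the periodogram argmax restricted to
  4–13 Hz, ties resolved toward the lower frequency; a range with only
  numerical dust returns the 8.5 Hz midpoint with a warning.
* **Matrices.** Each metric/band/epoch gives a symmetric 90 × 90 matrix with
  zero diagonal over the AAL-90 parcellation (78 cortical + 12 deep
  grey-matter regions, ordered left frontal 1–15, left parietal 16–21, left
  occipital 22–27, left temporal 28–39, the right-hemisphere mirror 40–78,
  subcortical 79–90). ROI strength is the row mean over the 89 off-diagonal
  entries; global FC is the mean strength; epoch results are averaged per
  subject.

## Group statistics

Group contrasts are ordinary least squares on z-scored outcome and z-scored
predictors with diagnosis coded SCD = 0, AD = 1, so the group coefficient is
a standardized beta (the point-biserial correlation in the single-predictor
model) and a negative beta means lower FC in the AD-like group. Covariate
models add z-scored age or band-matched relative power. In place of a visual
normality check, a Shapiro-Wilk gate at $\alpha = 0.05$ selects identity,
log (only if the values are strictly positive and the log passes), or
mid-rank transform ("ANOVA on ranks"); reported group means stay on the raw
scale.

Regional comparisons use the two-sided Mann-Whitney U test with the
tie-corrected normal approximation (group sizes near 28 make exact
enumeration unnecessary; the tests verify against full enumeration on tiny
inputs), corrected with Benjamini-Hochberg FDR over the 90-ROI family within
each metric × band. Spearman correlations are Pearson correlations of
mid-ranks with the $t$ approximation on $n - 2$ degrees of freedom; matrix
reproducibility offers both the 4005-pair upper-triangle mode and the 90-ROI
strength mode, each reporting its own $n$ and dof, because published matrix
correlations are sometimes quoted with strength-level degrees of freedom
while describing upper-triangle input.

## Split-sample reproducibility

`split_cohort()` halves the pooled cohort at random, stratified by diagnosis
with at most one subject imbalance per group. `evaluate_split()` refits the
plain GLM independently in each half; an effect is *reproduced* only when it
is significant in both halves **and** the beta has the same sign — dual
significance with opposite directions is not reproducibility.
`multi_split()` repeats this for (by default) six derived-seed splits and
tallies reproduced counts per metric × band. The original study design
additionally hand-balanced demographics across halves; the harness uses pure
random stratification, which slightly understates between-half similarity.

## The synthetic generator

Each ROI signal is built as 1/f-shaped background noise (white noise,
spectrally shaped to power $\propto f^{-1}$ by default, DC removed) plus
band-limited oscillations: complex narrowband Gaussian carriers of 2 Hz
bandwidth around the configured center frequencies, defaults theta 6 Hz
(amplitude 0.4), alpha 10 Hz (1.0), beta 20 Hz (0.5) relative to unit-RMS
noise — an eyes-closed, alpha-dominant resting spectrum.

* **Phase coupling** replaces a pair's carriers with
  $s \cdot \mathrm{driver} + (1 - s)\cdot \mathrm{private}$, the second
  channel taking $\mathrm{Re}(z\,e^{-i\,\mathrm{lag}})$ of the shared
  analytic driver — an exactly constant lag, so strength 1 with no noise
  gives PLI $= 1$ by construction.
* **Envelope coupling** multiplies independent carriers by strictly positive
  slow (< 1 Hz) modulators whose standardized fluctuations mix a shared and
  a private component with weights $\sqrt{w}$ and $\sqrt{1 - w}$. The shared
  share of the modulator *variance* is then exactly $w$, so the modulator
  correlation of the pair equals the weight. (An amplitude-convex mixture
  $(1-w)m_i + w m_s$ was considered and rejected: its induced correlation,
  $w^2 / (w^2 + (1-w)^2)$, is nearly flat below $w \approx 0.3$, which makes
  small coupling weights statistically invisible at realistic scan sizes.)
  Independent carriers keep the PLI at its null, isolating the amplitude
  channel.
* **Leakage** is a row-stochastic mixing matrix applied last: diagonal
  $1 - \lambda$, off-diagonal mass $\lambda$ spread with random
  (distance-free) weights, rows summing to one. $\lambda = 0$ is the
  identity.

Cohorts draw per-subject seeds deterministically from a master seed; ages are
truncated normals (SCD $\mathcal N(56.5, 9)$, AD $\mathcal N(65, 7)$, on
[40, 90] years), MMSE uniform integers (SCD 24–30, AD 12–29), and epoch
quality uniform on {1, 2, 3, 4} independent of group — matching the location
and spread of a memory-clinic AD/SCD contrast so the covariate and gating
code paths are exercised. The default 160 s recording yields 12 epochs, so
the 10-of-12 quality selection is non-trivial.

**What the generator does not emulate:** biophysical forward models and
realistic head geometry, sensor noise and artefact structure (eye movements,
drowsiness), distance-dependent leakage, non-stationarity across a 5-minute
recording, and any quantitative model of disease-related coupling change —
group-effect magnitudes are free simulation parameters, not clinical
estimates. Passing tests therefore demonstrate correctness of the metrics and
statistics under a controlled linear-mixing model, not clinical validity.

## Calibration and problem sizes

Thresholds in the property suite were frozen after Monte-Carlo calibration of
the generator, before the corresponding assertions were written:

* The per-epoch PLI of independent sources is biased above zero by serial
  correlation of the sign process; the bias scales inversely with (band
  bandwidth × epoch length). At 4096-sample epochs the leakage-immunity suite
  therefore evaluates a wide 13–48 Hz analysis band, where the null bias is
  about 0.03, comfortably inside its 0.05 bound — narrowband-dominated bands
  (e.g. alpha with a 10 Hz rhythm) have a slow phase difference and a null
  bias an order of magnitude larger, which is a property of the estimator at
  this epoch length, not of the implementation.
* Planted group effects use beta-band envelope-coupling weights 0.7 (SCD-like)
  vs 0.3 (AD-like), which produce standardized betas near −0.45 at the
  published group sizes (29/28) — the small-to-medium effect-size regime the
  pipeline is meant to resolve.
* Test problem sizes: immunity and null-calibration runs use 2–3 ROIs and one
  epoch per subject; monotonicity scans use 50 replicates per weight on the
  grid {0, 0.2, 0.5, 0.8}; null error control uses 200 simulated cohorts of
  12 + 12 subjects and 200 null regional runs at 90 ROIs. These sizes keep
  each simulated condition's Monte-Carlo error well below the asserted
  margins while the full suite stays desk-scale; the 90-ROI path itself is
  exercised on single epochs.

## Known limitations

* The brick-wall DFT filter is non-causal and rings on broadband transients;
  it is the stated filtering convention for this pipeline, appropriate for
  stationary resting-state epochs, not a general-purpose filter.
* Mann-Whitney p-values use the normal approximation; below ~8 subjects per
  group it is inaccurate (the package is not intended for such sizes).
* The rank ("ANOVA on ranks") model ranks the outcome only; covariates enter
  untransformed.
* PLI and AEC-c are blind to true zero-lag physiology by construction; real
  zero-lag coupling is indistinguishable from leakage and is discarded.
* `subject_connectivity()` recomputes filters per metric; for large cohorts
  at 90 ROIs, expect minutes per metric × band on one core.
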