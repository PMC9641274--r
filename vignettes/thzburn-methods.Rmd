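---
title: "Wavelet-packet entropy features for THz burn assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-packet entropy features for THz burn assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzburn)
```

## The measurement and the problem

Terahertz time-domain spectroscopy (THz-TDS) in reflection records, at every
pixel of a raster scan, the electric field of a picosecond THz pulse
reflected from the skin through an imaging window.  Each per-pixel trace
contains two overlapping reflections — one from the air/window interface,
one from the window/tissue interface — and the second carries the tissue's
broadband spectral response.  Burn injuries alter skin hydration and
structure, which changes that response; the analysis task is to turn the
per-pixel waveforms of a measurement site into features that predict (a)
whether the wound will have fully re-epithelialized four weeks later (FR
vs. NPR) and (b) the histological severity grade (healthy H, superficial
partial-thickness SPT, deep partial-thickness DPT, full-thickness FT,
defined by dermal burn depth <60%, 60–90% and >90%).

`thzburn` implements the complete chain: a synthetic scene simulator,
signal conditioning, a maximal-overlap discrete wavelet packet transform
(MODWPT), energy-to-Shannon-entropy-ratio (ESER) features deconvolved by an
air reference, and cross-validation-tuned SVM classifiers with a
repeated-split evaluation protocol.

## Feature model

For a conditioned trace $X(t)$ of length $N$, the MODWPT at level $J$
produces $2^J$ sequency-ordered sub-bands $\tilde W_{J,n}(t)$, each of
length $N$ (no down-sampling), with nominal passband
$[n, n+1]\, f_{\mathrm{Nyq}} / 2^J$.  The packet recursion is
$$\tilde W_{j,n}(t) = \sum_k \tilde u(k)\,
  \tilde W_{j-1,\lfloor n/2\rfloor}\big((t - 2^{j-1}k) \bmod N\big),$$
with $\tilde u = \tilde g$ (scaling filter) when $n \bmod 4 \in \{0,3\}$
and $\tilde u = \tilde h$ (wavelet filter) when $n \bmod 4 \in \{1,2\}$ —
this filter-selection rule yields sub-bands directly in sequency order.
The filters are the Daubechies extremal-phase pairs db1–db10 rescaled by
$1/\sqrt 2$, so $\sum \tilde g = 1$, $\sum \tilde h = 0$ and
$\sum \tilde g^2 + \sum \tilde h^2 = 1$.  Under circular (periodic)
filtering this normalization makes the full tree conserve energy exactly,
which is the property the feature algebra below rests on.  (A $1/2$
normalization, sometimes seen in print, breaks energy conservation and is
rejected by the package's conservation tests.)

Each selected sub-band contributes one feature:
$$P(t) = \frac{|\tilde W_{J,n}(t)|^2}{\sum_t |\tilde W_{J,n}(t)|^2},\qquad
  H_n = -\sum_t P(t)\log P(t),\qquad
  E_n = \frac{\sum_t |\tilde W_{J,n}(t)|^2}{\sum_t |X(t)|^2},\qquad
  \mathrm{ESER}_n = E_n / H_n.$$
Both $E_n$ and $P$ are invariant to rescaling $X$, so ESER measures
spectral *shape*, not absolute reflectivity.  Tissue ESER vectors are
divided element-wise by the ESER vector of an identically conditioned
air/mirror reference, cancelling the instrument's spectral signature (and
the entropy log base, which is why the base is immaterial; nats are used).

Numerical choices: entropy uses $0\log 0 = 0$; a sub-band whose energy is
below $10^{-12}$ of the trace energy has an undefined $P$, so it is flagged
degenerate and assigned $H = 0$, $\mathrm{ESER} = 0$ — this keeps feature
vectors finite without inventing information.  The denominator of $E_n$ is
the energy of the gated, band-passed trace fed to the transform: within
this pipeline that gated pulse *is* the signal under analysis, and using it
makes $\sum_n E_n = 1$ over a full tree.  The air reference is gated around
its own principal reflection with the same window, so the deconvolution
compares like with like.

## Signal conditioning

1. **Alignment.**  Every pixel trace is circularly shifted by the integer
   lag that maximizes the cross-correlation of its first reflection
   (gated around the air/window arrival) against a template — the air
   reference for absolute alignment, or the site-median trace for purely
   relative drift removal.  Only integer lags are searched: the drifts
   being corrected are small, and sub-sample interpolation would introduce
   behavior the rest of the chain cannot verify.  Alignment runs on the
   *raw* traces; because integer circular shifts commute with the circular
   zero-phase filter, this is equivalent to aligning after filtering, but
   it avoids a bias we observed in testing — band-pass ringing of a
   strongly tilted tissue reflection can leak into the first-reflection
   gate and pull the correlation peak by a few hundredths of a picosecond.
2. **Band-pass.**  A zero-phase frequency-domain mask with raised-cosine
   tapers of width 10% of each band edge, unit gain across 0.1–1 THz
   (the instrument's usable band).  Zero phase leaves reflection peak
   positions untouched for the stages that depend on them.
3. **Biopsy-pixel rejection.**  Punch biopsies leave an air gap that
   produces a delayed Fabry–Pérot echo after the tissue reflection.
   Pixels whose energy in a post-pulse gate exceeds the site median by
   more than `k_mad = 5` robust standard deviations (MAD) are removed;
   the threshold factor is exposed in the configuration because no
   principled universal value exists.  The four corner pixels are always
   removed (the scanner housing clips the beam there).
4. **Blackman gate.**  The tissue reflection is isolated by multiplying
   with a 25-ps Blackman window centered on the absolute-amplitude peak of
   the second reflection and cropping to the window support (2500 samples
   at the 0.01-ps default step).  For a whole site the center is located
   once on the site-mean trace and applied to every pixel, so all gated
   traces of a site share a time base and can be averaged coherently.
   The gated trace records its gate, making re-gating with the same
   specification a no-op (idempotence) rather than a silent double taper.
5. **ROI averaging.**  The grid is tiled into non-overlapping 5×5-pixel
   regions of interest; a block containing any invalid pixel is dropped;
   each surviving block's pixel-wise mean trace is one observation.
   Requiring all 25 pixels keeps observations comparable and closer to
   independent for the ROI-level splits.  (Sliding/overlapping ROIs and
   partial blocks are a defensible alternative reading; tiling was chosen
   because overlapping ROIs would share pixels across observations and
   make the train/test split leakier than it already is — see
   *Limitations*.)

## The synthetic scene generator

No real porcine THz dataset is distributed, so the generator is the
package's study environment, and its defaults are the package's study
conditions.  Per pixel it produces
$$x(t) = a_1\,\psi(t-\tau_1) \;+\; \mathcal{T}_c\,\psi(t-\tau_2)
        \;+\; [\text{biopsy}]\; f_a\,\mathcal{T}_c\,\psi(t-\tau_2-\delta)
        \;+\; \varepsilon(t),$$
where $\psi$ is a single-cycle pulse (second derivative of a Gaussian,
unit peak, 2-ps intensity FWHM so its spectral peak sits inside
0.1–1 THz), and $\mathcal{T}_c$ applies the class response
$\rho_c e^{-\beta_c f}$ in the frequency domain: a broadband reflectivity
scale and an exponential spectral tilt, the simplest two-parameter family
that produces a severity-ordered ESER trend without pretending to be a
dielectric model of skin.  The default ladder is
$\rho = 0.45/0.50/0.55/0.60$ and $\beta = 0.3/1.2/2.5/4.5\ \mathrm{THz}^{-1}$
for H/SPT/DPT/FT: severe burns reflect more strongly (edema) and attenuate
high frequencies more, which drives the mean in-band deconvolved ESER
*down* with severity.  All pixels of a site share one integer timing drift
(±5 samples) emulating mechanical drift; white Gaussian noise is added at
30 dB SNR relative to the clean trace RMS; the air reference is recorded at
20 dB lower noise.  Sites get labels whose dermal-burn percentage falls in
the class's histological interval and whose day-28 re-epithelialization is
negatively correlated with severity.

Defaults: `dt = 0.01` ps (Nyquist 50 THz, so level-12 sub-bands 10–80 span
0.122–0.989 THz, matching the instrument band), `n_samples = 8192`.  The
trace must be long enough to hold the first reflection, the *dispersed*
tissue reflection — whose band-passed peak sits up to ~3 ps after
$\tau_2$ for the strongest tilt — and the full 25-ps gate around it; an
81.92-ps trace provides that with margin, a 40.96-ps one does not.
Default site counts (13/16/11/27 for H/SPT/DPT/FT on 27×27-pixel grids)
are sized so the per-class ROI-observation yields land near 300/332/224/569.

What the generator does **not** emulate: frequency-dependent absorption
with a physical dielectric (Debye) model, Mie scattering from surface
roughness and appendages (only its remedy, spatial averaging, is
exercised), sub-sample timing jitter, correlated (pink) noise, and
within-site heterogeneity of the burn.  Consequently, passing tests show
the *pipeline* recovers planted structure and ordered effects correctly —
they say nothing about effect sizes in real porcine or human skin.

A reduced profile (`dt = 0.1` ps, 512 samples, level 8) is used for the
classification tests; there `tau2 = 28.05` ps places the tissue-reflection
peak safely inside one sample.  At an exact sample-grid tie, site-mean
noise flips the integer gate center between two adjacent samples, giving
each site a small idiosyncratic feature offset; with ROI-level splits a
classifier can memorize such site signatures, which would contaminate the
null-calibration experiment (we measured ~56% "null" accuracy at a tie,
chance-level away from it).  This is a real property of peak-centered
gating worth knowing about, not just a simulation artifact.

## Classification and evaluation

Features are z-scored per sub-band using training-set statistics only.
`burn_svm()` searches the supplied grid exhaustively — kernel family,
kernel scale $s$ (Gaussian $K = e^{-\|x-y\|^2/s^2}$, polynomial
$(1 + x^\top y/s^2)^d$ with $d \in 2..20$), box constraint, multiclass
coding, and, when features are recomputable, mother wavelet (db1–db10) and
decomposition level (8–13) — selecting the candidate with the smallest
mean five-fold cross-validation misclassification loss, then refits it on
the whole training set.  Binary tasks use one SVM with Platt-calibrated
probabilities; multiclass tasks use an error-correcting output code
ensemble of binary SVMs (one-vs-one: $\binom{K}{2}$ learners; one-vs-all:
$K$), decoded by coding-weighted decision values with softmax-normalized
scores as probabilities — the decision-value orientation is normalized
against libsvm's data-order convention.  Ties in the grid search go to the
first candidate in grid order (deterministic).

`burn_experiment()` repeats: stratified 80/20 ROI-level split → tune by
five-fold CV → refit → score training, validation (the winner's pooled
five-fold predictions) and test sets, recording per-class sensitivity,
specificity, accuracy and tie-aware ROC-AUC (the normalized Mann–Whitney
statistic, cross-checked against an independent ROC implementation in the
tests).  Splits are stratified because the class counts are unbalanced
enough for an unstratified 20% draw to lose the smallest class.  Metrics
are reported as mean ± sd over the split iterations (20 by default).

## Problem sizes used by the tests and the acceptance script

Transform correctness runs on traces of 64–256 samples (all wavelets,
levels up to 8); planted-structure recovery and the classification
experiments use the reduced profile with 5 sites per class (~120
observations per class) and 5 split iterations over a small Gaussian-kernel
grid; the severity-ladder check uses the full default profile with one site
per class.  These sizes keep a complete run in a few minutes while leaving
every statistical conclusion comfortably clear of its threshold (the
strong-effect accuracy sits at 100% against a 95% requirement; the ESER
ladder's class gaps are ~30× the seed-to-seed scatter).

## Limitations

* ROI-level splitting shares measurement sites between training and test
  sets, so site-level nuisance (drift residue, gate quantization) can leak;
  the package exposes the split only at ROI granularity, mirroring the
  protocol it implements, and flags site-level splitting as the sounder
  design once enough sites exist.
* The validation metrics are the winning configuration's own pooled CV
  predictions, not a nested outer loop, so they are mildly optimistic —
  the external test set is the honest number.
* The generator's effect sizes are design choices, not estimates of
  biological contrast; absolute accuracies on synthetic data do not
  transfer to real tissue.
* The inverse transform is intentionally absent: the pipeline only
  analyzes, never reconstructs.
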