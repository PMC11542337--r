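---
title: "Equimolar synergy screening and high-content dominance analysis"
author: "synscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equimolar synergy screening and high-content dominance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

## The screen this package models

A medium-scale drug-combination screen tests every unordered pair of a
small compound panel — here twelve drugs spanning six mechanistic classes
(mTOR, microtubule, HSP90, proteasome, DNA-synthesis, and HDAC inhibitors)
— in an *equimolar* design: each drug is serially diluted 3.5-fold over six
steps (C1 highest to C6 lowest), and two drugs are mixed at the same molar
concentration at each step. The equimolar trick collapses the usual
two-dimensional dose matrix onto a single shared axis, which makes an
all-pairs screen feasible at the cost of not exploring dose ratios.

Two read-outs are analyzed:

* **Growth**: live-cell counts per well before treatment and at endpoint,
  converted to a normalized growth rate and then to three synergy scores.
* **High-content (HC) phenotype**: three-channel fluorescence images (a
  nuclear reporter, a protein reporter, a whole-cell reporter) reduced to
  per-cell features, population-level Kolmogorov–Smirnov profiles, and a
  supervised embedding in which combination responses are compared with
  single-drug responses.

## Growth metrics

The normalized growth rate of a treated well is

$$GR = 2^{\log_2(X_c/X_o)/\log_2(X_{dc}/X_o)} - 1,$$

where $X_c$ is the endpoint count under drug, $X_o$ the shared
pre-treatment count, and $X_{dc}$ the endpoint vehicle count. $GR = 1$
means untreated growth, $0$ cytostasis, $-1$ complete kill. The formula is
invariant to rescaling all three counts, which is what makes plates
comparable. Luminescence viability assays use relative growth
$RG = (LS_d - LS_m)/(LS_c - LS_m)$ instead (vehicle = 1, blank medium = 0).

Replicates (3–4 per condition) pass through a deliberately conservative
outlier rule: at most one replicate is removed, and only if it deviates
from the replicate mean by more than one sample standard deviation
(computed with the candidate included). The rule is applied once and never
iterates. Note that with four replicates the most deviant value exceeds one
SD quite often — this is a property of the rule itself, which we implement
as stated rather than "improve".

## Dose–response model

Responses are fit with the four-parameter logistic

$$y(x) = d + \frac{a - d}{1 + 10^{\,b(c - x)}},$$

with $x$ the log10 dose (µM), $d$/$a$ the lower/upper asymptotes in percent
inhibition, $b > 0$ the slope, and $c$ the log10 of the (relative) IC50.
Fitting is Levenberg–Marquardt with box constraints and a small start grid
(two midpoint guesses × three slopes), because the 4PL surface has flat
ridges at $b \to 0$ that can trap a single start. Degenerate series (flat
responses) return a best-effort fit flagged `converged = FALSE`, and IC50
is reported as undefined when the fitted span is below 10 % or the midpoint
falls more than one decade outside the dosed range.

### Which inhibition scale is fitted

Growth rates must be mapped to a 0–100 % inhibition axis before fitting
(the sensitivity-score normalization presumes that scale). Two adapters are
provided:

* `gr_inhibition(gr)` $= 100\,(1 - \log_2(1 + GR))$, the **default**. Since
  $GR = 2^{g_\mathrm{drug}/g_\mathrm{ctrl}} - 1$, this recovers the
  fractional reduction of the exponential growth rate itself. If a drug
  inhibits the growth rate with Hill kinetics
  $I(x) = I_{max}/(1 + (IC50/x)^h)$ — the assumption the synthetic
  generator makes — then the observed curve on this scale is *exactly* a
  4PL with $c = \log_{10} IC50$ and $b = h$, so fitted midpoints are
  unbiased estimates of the underlying potency. Cytostasis maps to 100 %
  (growth fully inhibited) and net kill saturates there.
* `inhibition_from_gr(gr)` $= 50\,(1 - GR)$, the affine alternative, on
  which cytostasis is 50 % and complete kill 100 %. It preserves the *GR*
  curve's shape but its 4PL midpoint sits systematically below the Hill
  IC50 (by about 0.15 decades for $h = 1$), because the exponential map
  from growth-rate inhibition to cell number is convex. We expose it
  (`synergy_screen(..., scale = "linear")`) for users who want the death
  endpoint resolved, and default to the log scale because potency
  estimation is the screen's primary use of the fits.

### AUC and the drug sensitivity score

The area under the fitted curve has the closed form

$$\int_{x_1}^{x_2} y\,dx = Y(x_2) - Y(x_1), \qquad
Y(x) = \frac{(a-d)\log_{10}\!\left(1 + 10^{b(c-x)}\right)}{b} + a\,x,$$

evaluated with a numerically stable $\log_{10}(1 + 10^z)$ so large $|z|$
does not overflow; tests hold it to adaptive quadrature at $10^{-8}$
relative tolerance. The drug sensitivity score normalizes the area above a
minimum activity level $t$ (10 % by default):

$$DSS = \frac{AUC - t\,(x_2 - x_1)}{(100 - t)(C_{max} - C_{min})},$$

with $x_1$ the dose at which the fitted curve crosses $t$ (closed form) and
$x_2 = C_{max}$; a curve that never reaches $t$ scores 0, and the score is
clamped at 0 (no negative sensitivity). $\Delta DSS$ is the combination's
score minus the better single agent's.

## Synergy scores and classification

Three scores are computed per pair, each with its published direction:

* **Excess over Bliss** on the $(1-GR)$ scale:
  $EOB = (1-GR_{com}) - (1-GR_a) - (1-GR_b) + (1-GR_a)(1-GR_b)$, positive
  for synergy. Per-dose EOBs are computed from replicate-mean growth rates
  and summed over C1–C3 (high), C4–C6 (low), and all six doses. No clamping
  is applied (a clamped variant exists behind a flag).
* **Loewe combination index**
  $CI = IC50_{a(a+b)}/IC50_a + IC50_{b(a+b)}/IC50_b$, below 1 for synergy.
  In the equimolar design the combination series is fit once on the
  per-component dose axis and its IC50 serves as both combination IC50s:
  each component is present at exactly that concentration at the
  combination midpoint, and the sham identity (a drug combined with itself
  gives CI = 1) then holds exactly, which the tests verify through the full
  simulate–fit–score path. An undefined IC50 propagates to an undefined CI,
  never an imputed one.
* **$\Delta DSS$**, positive for synergy.

`classify_synergy()` applies strict inequalities at configurable cutoffs
(defaults CI < 1, EOB sum > 0, $\Delta DSS$ > 0) and reports the three
flags plus their conjunction; `venn_counts()` tallies a screen. The
packaged reference table of 66 pairwise scores reproduces the published
counts (8 Loewe, 6 Bliss, 3 all-three; 2 pairs at the stricter CI < 0.6
with EOB > 0.2; 3 at EOB > 0.2 with ΔDSS > 10 %), and the per-pair
annotation column is exactly derivable from its three score columns. The
published AUC-only count (41) is not recoverable from the printed scores
(counting ΔDSS > 0 gives 42 at printed precision) and is therefore
documented rather than asserted.

### What a Bliss-independent null does to the three methods

The three methods answer different questions, and their disagreement under
a *Bliss-independent* ground truth is worth stating plainly because the
package's own simulations expose it. A Bliss-independent combination is
genuinely more potent than either single agent, so $\Delta DSS$ is
systematically positive, and its IC50 shifts left far enough that the Loewe
CI sits near or below 1 for most realistic Hill slopes — Loewe and Bliss
are different additivity nulls, not two estimators of one quantity. Only
the EOB is centered near zero there, and with 5 % count noise, four
replicates, and three control doublings its six-dose sum has a standard
error of about 0.05, comparable to the |0.03| scale-mismatch bias of the
noiseless screen. Consequently the *conjunction* of the three default
cutoffs still flags a substantial fraction of Bliss-null pairs (tens of
percent per screen in the packaged simulations, reported honestly by
`scripts/acceptance.R` as `null_screen_false_positive_pct`), while the
stricter published cutoffs (CI < 0.6, EOB > 0.2) flag essentially none.
This is a property of the scoring rules under these study conditions, not
a tuning target: we keep the prescribed noise level, replicate count, and
default cutoffs, and document the behavior. An engineered pair with a
+0.25 Bliss offset is detected by all three methods in every simulated
screen.

## The synthetic-data generator

The generator exists so every downstream stage can be tested against known
truth; its defaults are the screen's study conditions and are not adjusted
per analysis.

* **Plates**: twelve drugs, two per class; 6-dose 3.5-fold series from
  10 µM; four replicates; 3000 cells seeded per well; three control
  doublings over 72 h; multiplicative lognormal count noise with 5 % CV;
  one shared pre-treatment count per plate. True potencies place most IC50s
  between the 3rd and 4th dilution steps, matching where the screen's
  published IC50s cluster; the individual values are invented (no per-drug
  truth is published) and are meant to be overridden when calibration
  exists. Single-drug inhibition is Hill; pairs combine by the Bliss
  product rule plus an optional signed offset (the interaction ground
  truth), or by numerically solved Loewe dose additivity for sham-like
  pairs. Because counts are $x_0 2^{g(1-I)}$ with $I \in [0,1]$, simulated
  plates span growth rates in $[0, 1]$; the net-death regime is exercised
  through constructed count triplets rather than the generator.
* **Images**: Gaussian-profile nuclei (channel 1), correlated whole-cell
  blobs (channel 3), a per-cell treatment-shifted reporter intensity
  (channel 2), a linear background gradient, and Poisson–Gaussian noise
  scaled to a requested spot SNR, with exact truth records. Not modeled,
  deliberately: optics (PSF, vignetting), cell-cycle or apoptosis kinetics,
  crowding-induced shape changes. Passing segmentation tests therefore
  demonstrate algorithmic correctness on well-posed fields, not performance
  on hard real microscopy.
* **Feature tables**: thirty registry features drawn from Gaussians
  translated by `dose_scaling * shift` standard deviations — the direct
  fixture for the profiling branch. Combination tables blend the two
  components' shifts weighted by each drug's inhibition level times its
  shift magnitude, so "dominance" has a constructed ground truth: the class
  with the larger phenotype effect should win its combinations.

## High-content pipeline

* **Background**: grayscale morphological opening with a disc larger than a
  nucleus (the rolling-ball equivalent), subtracted and floored at zero.
  EBImage's morphology operates on the [0, 1] intensity scale, so channels
  are normalized around the call.
* **Segmentation**: Gaussian smoothing → Otsu threshold →
  distance-transform watershed (merge tolerance 0.2 px on the distance map,
  chosen to split touching nuclei without shattering single ones) → discard
  objects under 9 px². Deterministic throughout.
* **Counting**: Laplacian-of-Gaussian blob response at the nucleus scale,
  local maxima above a threshold *relative* to the strongest response
  (default 0.2), so counts are invariant to global gain. A noise-only field
  has no meaningful "strongest response"; blank-field behavior is defined
  for empty (zero) input, and counting on pure noise is an acknowledged
  limitation of any relative-threshold detector.
* **Features**: 30 named features (`channel.group.metric`) spanning
  intensity statistics (channel 1 over the nucleus, channels 2–3 over the
  cell body grown from nucleus seeds), nucleus/cell morphology, gradient
  and co-occurrence texture, entropy, and channel-2 mass displacement. This
  registry is a deliberate desk-scale stand-in for the hundreds of features
  a production HC platform extracts — enough for profiles to be
  discriminative, small enough to simulate quickly. Border-touching cells
  are dropped from feature tables but kept in counts, and reported in a QC
  attribute.
* **KS profiles**: one signed two-sample KS statistic per feature against
  matched vehicle wells. The magnitude is the classical sup-gap (delegated
  to `stats::ks.test`, held exactly to a brute-force ECDF scan in tests);
  the sign is ours — the sign of the median difference, with pure spread
  changes counted positive. Magnitudes never depend on the convention.
* **Embedding**: PCA (`stats::prcomp`) for unsupervised views; for
  classification, Fisher LDA with the pooled within-class scatter shrunk
  toward a scaled identity, $S_w(\lambda) = (1-\lambda)S_w +
  \lambda\,\mathrm{tr}(S_w)/p\,I$, $\lambda = 0.5$ by default. Shrinkage is
  required because the profile dimension can exceed the training count; at
  $\lambda = 0$ and ample samples the model matches `MASS::lda`'s leading
  discriminant, which the tests check. Training uses single-drug profiles
  at the second-highest dose (C2) only — the dose at which single-drug
  responses are strong but death does not yet dominate — while
  nearest-neighbor references include single-drug profiles at *all* doses,
  so dose-resolved trajectories can be matched.
* **Assignment and confidence**: 1-nearest-neighbor by Euclidean distance
  in LDA space with a lexicographic tie-break. The confidence score is a
  posterior: kernel-density estimates (Gaussian kernel, Silverman
  bandwidth) of within-class and between-class training distances give
  $CS = f_s(d)\pi / (f_s(d)\pi + f_d(d)(1-\pi))$ with prior $\pi = 0.5$.
  Degenerate (all-identical) training distances fall back to an indicator
  with a warning. The exact published construction lives in prior work we
  cannot inspect; this density-ratio form satisfies every property stated
  for it (bounded in [0, 1], decreasing in distance beyond the within-class
  mode, 0.5 at equal densities) without claiming identity.
* **Dominance**: a confident assignment (CS ≥ 0.9) to one component's class
  makes that drug dominant and the partner recessive; a confident match to
  a third class is reported as `unassigned` rather than silently dropped.
  Below the threshold, the call is `codominant` when the two nearest
  distinct single-drug classes are exactly the two component classes within
  a 1.5 distance ratio — an operationalization of "positioned in between
  the two single-drug responses", which is described only narratively in
  the source material — and `interactive` otherwise. Per-class dominance
  percentages are reported with and without the confidence filter, and a
  class with no qualifying combinations is `NA`, never 0 %.
* **Concentration traces**: per-dose mean profiles of one treatment,
  projected and connected from the lowest to the highest dose with endpoint
  flags and explicit gap reporting. Timepoints are never pooled.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run, as the package's own
validation design: 200 noisy six-dose series for IC50 recovery (coverage of
±0.1 log10 ≥ 90 %); two full 66-pair null screens plus five engineered-pair
screens for detection; 1000 random 4PL draws for the AUC identity; fields
of 150–1000 synthetic cells for segmentation and counting; 48 profiles in
six 5-SD-separated classes for LDA hold-out accuracy; and a 12-drug screen
at three doses and two replicates (396 combination profiles) with a 5×
dominant proteasome class for dominance recovery. Tolerances worth knowing:
4PL convergence is declared from the optimizer's own status plus the
canonical orientation $a \ge d$; the closed-form AUC uses the stable
$\log_{10}(1+10^z)$ branch split at $z = 0$; KDE evaluations are floored at
$10^{-300}$ before the posterior ratio; equimolar doses of 0 (vehicle) are
excluded from fits.

## Known limitations

* The equimolar design cannot see ratio-dependent synergy; the checkerboard
  EOB module covers full dose matrices when those data exist.
* The three-method conjunction is conservative against true synergy but not
  calibrated as a hypothesis test under a Bliss null (see above); users who
  need a false-positive guarantee should use the stricter cutoffs or model
  the EOB noise explicitly.
* Image simulation is deliberately simple; segmentation parameters
  (smoothing sigma, watershed tolerance, minimum area) are honest knobs
  that will need retuning for real fields.
* The feature registry is 30 features, not the hundreds of a production
  platform; KS profiles on real data will be both richer and noisier.
* Confidence scores depend on the training-distance pools; with a single
  replicate and narrow within-class pools they are conservative (few calls
  clear 0.9), which the dominance statistics report as reduced call counts
  rather than inflated percentages.
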