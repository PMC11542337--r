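# synscreen

Drug-combination synergy screening and high-content dominance analysis for
equimolar screens in cancer cell lines.

## The problem

Finding synergistic drug pairs by brute force is expensive: a full
dose-matrix screen of 12 drugs is thousands of conditions. An *equimolar*
design — serially dilute every drug 3.5-fold over six steps (C1 highest to
C6 lowest) and mix pairs at equal molar concentration at each step —
collapses each pair onto a single dose axis, making an all-pairs screen of
12 drugs (66 combinations) tractable with image-based cell counting. A
second question follows once combinations are screened: when two drugs are
mixed, *whose* phenotype does the cell show? High-content imaging answers
it by comparing each combination's phenotypic profile with the single-drug
profiles.

`synscreen` implements both halves as a tested R pipeline, plus synthetic
generators (count plates, 3-channel fields, per-cell feature tables) with
known ground truth so every stage is verifiable without lab data.

## Models and scores

**Growth rate** from a count triplet (treated endpoint `Xc`, pre-treatment
`Xo`, vehicle endpoint `Xdc`):

    GR = 2^( log2(Xc/Xo) / log2(Xdc/Xo) ) - 1

1 = untreated growth, 0 = cytostasis, -1 = all dead. Replicates pass a
one-removal outlier rule (drop the most deviant replicate only if it is
more than one sample SD from the mean).

**Dose response**: four-parameter logistic `y = d + (a-d)/(1 + 10^(b(c-x)))`
on log10 dose, fit by constrained Levenberg–Marquardt; relative IC50
`10^c`; closed-form AUC via the antiderivative
`Y(x) = (a-d) log10(1 + 10^(b(c-x)))/b + a x`; drug sensitivity score

    DSS = (AUC - t (x2 - x1)) / ((100 - t)(Cmax - Cmin)),   t = 10% default.

**Synergy** per pair, three ways:

* excess over Bliss `EOB = (1-GRcom) - (1-GRa) - (1-GRb) + (1-GRa)(1-GRb)`,
  summed over high/low/all doses (positive = synergy);
* Loewe combination index
  `CI = IC50_a(a+b)/IC50_a + IC50_b(a+b)/IC50_b` (< 1 = synergy; a sham
  combination gives exactly 1);
* `ΔDSS = DSS_comb - max(DSS_a, DSS_b)` (> 0 = synergy);

plus the three-method conjunction, Venn counts, and checkerboard EOB
matrices for full dose-grid (relative-growth) surfaces.

**High-content branch**: morphological background subtraction, Otsu +
distance-watershed nucleus segmentation, Laplacian-of-Gaussian bright-spot
counting, a 30-feature per-cell registry, signed two-sample KS profiles
against vehicle, shrinkage LDA trained on single-drug profiles at the
second-highest dose, 1-NN class assignment with a Bayesian confidence
score, and dominance calls (dominant / recessive / codominant /
interactive) with per-class statistics and concentration traces.

## Worked example

Simulate a 3-drug mini-screen in which one pair (INK + PAN, an mTOR/HDAC
combination) carries an engineered +0.25 Bliss offset, then score it:

```r
library(synscreen)
cfg <- screen_config(
  drugs = default_screen_drugs()[c(2, 5, 11)],          # INK, AAG, PAN
  interactions = list(interaction_spec("INK", "PAN", "synergistic", 0.25)),
  seed = 1)
rep <- run_synergy_screen(cfg)
rep
#> Equimolar synergy screen: 3 pairs, 3 single drugs
#> Venn: Loewe 3 | Bliss 1 | AUC 3 | all three 1
rep$records[, c("drug_a", "drug_b", "eob_sum_all", "ci", "ddss", "all_three")]
#>   drug_a drug_b eob_sum_all    ci  ddss all_three
#> 1    AAG    PAN     -0.0827 0.957 0.054     FALSE
#> 2    INK    AAG     -0.0327 0.894 0.108     FALSE
#> 3    INK    PAN      0.8813 0.653 0.232      TRUE
```

Only the engineered pair clears all three criteria: its summed excess over
Bliss (0.88) is far above the noise scale, its combination index 0.65
means each component needs only ~65 % of the summed single-agent dose for
the same half-maximal effect, and its sensitivity score beats the better
single agent by 0.23. The two Bliss-independent pairs show near-zero EOB;
their CI and ΔDSS sit near the additivity boundary, which is exactly the
disagreement between the three null models that the conjunction rule is
there to absorb.

Fitting a single dose series directly:

```r
f <- fit_4pl(log10(c(10, 2.857, 0.816, 0.233, 0.0666, 0.019)),
             c(97, 86, 57, 23, 7, 2))     # % inhibition
f
#> 4PL fit: a=100.795 d=0.722 b=1.194 c=-0.180 (IC50=0.6613 uM) rss=0.07815
dss(f, dss_config(10, log10(0.019), 1))
#> [1] 0.397
```

The high-content half runs the same way: `run_hc_analysis(cfg)` returns KS
profiles, the LDA model, per-combination dominance calls, and per-class
dominance percentages.

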