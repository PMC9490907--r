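---
title: "Weakly supervised attention-MIL for myelin histopathology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised attention-MIL for myelin histopathology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Age-related cognitive impairment has no single histologic gold standard.
Rather than annotating lesions by hand, this package treats each stained
brain slide as a *bag* of image tiles carrying only a noisy slide-level
label — whether the donor showed antemortem evidence of cognitive
impairment — and asks a weakly supervised classifier to find tissue
features that separate the groups. The classifier's attention weights then
serve as an interpretability signal: which tiles drove the call, and what
do they look like under deterministic machine-vision measurements of myelin
(dark-blue Luxol-fast-blue-like) staining.

The package implements the full chain on synthetic data with planted
ground truth: cohort simulation, label derivation, tissue segmentation and
tiling, feature extraction, attention-based multiple instance learning
(MIL) under Monte Carlo cross-validation, attention interpretation,
hue-range positive pixel counting, and downstream association statistics.

# Cognitive-impairment labels

Three clinical measures enter the label: the Clinical Dementia Rating
(CDR, impaired when >= 0.5), a clinical diagnosis of impairment, and the
Mini-Mental State Examination (MMSE, impaired when <= 24). Recorded CDR
severity values above 3 are truncated to 3 for cross-centre consistency.
Donors with no available measure are excluded.

Two defensible readings exist for combining the measures, and both are
implemented in `label_policy()`. The default, `any_evidence`, calls a donor
impaired when *any* available measure is positive and unimpaired when at
least one measure is available and all are negative; this matches the
grouping rule "any evidence of impairment vs negative on all available
measures", under which the positive measures may overlap. The alternative,
`hierarchical`, lets the first available measure in the order CDR ->
diagnosis -> MMSE decide alone. The two disagree only for donors whose
first available measure is negative while a later one is positive (e.g.
CDR 0 with a positive diagnosis); because such profiles are rare and the
correct reading is genuinely ambiguous, both are kept and the choice is a
single config switch.

# The synthetic data generator

No real slide cohort ships with the package, so the generator defines the
study conditions under which everything is tested. All of its
distributions are package choices, exposed in `sim_config()`; none are
claimed to be estimates of real tissue.

**Cohort.** Age is normal (default mean 85, sd 10 years). True impairment
is Bernoulli with a logistic dependence on centred age (slope 0.08/year),
with a marginal rate of 0.49. Braak stage, CERAD, ARTAG and
cerebrovascular disease are drawn with mild positive shifts in impaired
donors, echoing the covariate structure of aging cohorts of this kind.
Recorded measures are generated from the true state, contradicted with
probability `label_noise` (default 0.1) and masked with probability
`missingness` (default 0.15) per measure. A few impaired donors receive
raw severity scores above 3 so the capping rule is exercised end-to-end.

**Slides.** Each donor gets one `slide_px`-square image (default 1024):
an elliptical tissue blob, rotated at random, whose inner concentric
ellipse (area fraction `wm_fraction` = 0.4) is white matter and whose rim
is grey matter. Grey matter is eosin-pink with Poisson-scattered dark
violet nuclei (denser than in white matter), giving the feature extractor
non-stain texture, as a hematoxylin counterstain would. White matter is a
pale, weakly saturated background filled with short randomly oriented blue
strokes — the myelinated fibres.

Stroke intensity is uniform on [60, 210] on the 0-255 scale. Strokes
darker than 120 constitute the "dark blue" myelin signal; the stroke hue
sits at 240 degrees and drifts toward cyan (about 205 degrees) for bright
strokes so that high-intensity blues remain representable in RGB at
saturation >= 0.15. The planted effect thins dark strokes with probability
`effect_size` inside the affected patch (a `patchiness` fraction of white
matter; 1 = uniform, smaller values give scattered discs), so the planted
dark-pixel density in affected tissue is `base_density * (1 -
effect_size)`. The per-tile realised dark-pixel fraction before any gain
is recorded as ground truth for recovery tests.

Finally the whole image is multiplied by a gain drawn from Normal(1,
`stain_gain_sd`) and clipped, modelling systemic staining variation
across slides. Because stroke intensities are spread across both band
edges, a gain shifts dark and light counts in the same direction, and the
dark/light ratio is less gain-sensitive than the raw dark count — which is
exactly the normalization role the ratio plays in the analysis, and is
asserted on simulation in the test suite.

What the generator deliberately does *not* emulate: real fibre
morphology, infarcts or plaques, scanner pyramids, chromatic aberration,
or spatially structured staining gradients within one slide. Passing
tests therefore show that the pipeline recovers planted effects under the
stated noise model, not that it would perform identically on real tissue.

# Tiling and features

Tissue is segmented by thresholding HSI saturation (default 0.02) after a
3x3 median filter; all disconnected pieces are kept. The filter is an
authored pmin/pmax median-of-9 selection network, brute-force verified,
chosen for speed at megapixel scale. Slides are cut into non-overlapping
256 x 256 tiles on a grid anchored at the origin (no offset search —
the simplest reproducible convention); edge remainders are dropped and a
tile is kept when at least half its pixels are tissue.

The default tile embedding is hand-crafted and deterministic: a 12-bin
saturation-gated hue histogram, per-channel means and standard deviations,
an 8-bin intensity histogram, and gradient-magnitude statistics, zero
padded to the configured dimension. The MIL contract only requires an
informative fixed-length vector per tile; a pretrained CNN embedding can
be plugged in through the same `feature_extractor` interface (`id`, `dim`,
`fn`). The demo configuration uses dimension 64 to keep desk-scale runs
fast; the padding default is 1024 to match the dimensionality convention
of CNN tile embeddings.

# The attention-MIL model

Standardized tile features pass through a shared ReLU embedding layer
(width 64). Gated attention scores each embedded tile $h_k$:

$$e_k = w^\top\left(\tanh(V h_k) \odot \sigma(U h_k)\right), \qquad
a = \operatorname{softmax}(e), \qquad z = \sum_k a_k h_k,$$

and a linear two-class head classifies the pooled representation $z$. The
training objective is the bag-level cross-entropy plus 0.3 times an
instance-clustering loss: within each bag the top-B and bottom-B tiles by
attention (B = 8, halved for small bags) receive binary pseudo-labels
(top tiles of a positive bag positive, the rest negative) scored by an
auxiliary instance head. The instance term regularises the shared
embedding; setting its weight to 0 recovers pure bag-level training.

Optimisation is Adam at learning rate 2e-4, one bag per update, with
gradients derived analytically and verified against numerical
differentiation in the tests. Early stopping monitors validation bag loss
(patience 10, maximum 200 epochs) and restores the best-epoch weights;
loss rather than AUC is monitored because with ~12 validation bags AUC is
too granular to rank epochs. Dropout is omitted — at desk scale the
instance term plus early stopping is regularisation enough, and omitting
it keeps the forward pass deterministic.

Evaluation uses 10-fold Monte Carlo cross-validation: independent
label-stratified 80/10/10 splits keyed by donor (a donor never appears in
two parts of one fold), sizes rounded by largest remainder. Per fold the
test AUC is the Mann-Whitney concordance (ties count one half) and
balanced accuracy is (TPR + TNR)/2 at probability threshold 0.5 — the
threshold is a symmetric default. Across folds, the per-fold AUCs are
compared to chance with a one-sample Wilcoxon signed-rank test using the
normal approximation with continuity correction, ROC curves are averaged
vertically with linear interpolation on a fixed FPR grid (step 0.01), and
the best fold is the argmax of the mean of AUC and balanced accuracy.

# Attention interpretation

Attention scores are z-transformed *within* each slide (sample sd,
degenerate slides map to zeros); the per-slide scope matches heatmaps that
are normalised to the rest of the same slide, and a `z_scope` choice of a
cohort-wide transform would only rescale the paired comparison. Each tile
is assigned to the region containing its centre pixel — unambiguous, and
faithful to converting region annotations into tile space. Per slide and
region the median z-attention is computed, and white vs grey matter is
compared across slides with a paired t-test.

Top-attention tiles are ranked by raw attention with ties broken by
row-major tile index; since ranking is invariant to monotone transforms,
raw vs z-scored attention is immaterial here. The default of 100 tiles
follows the analysis convention; demo slides hold ~16 tiles, so the
selection clamps to all tiles with a warning.

# Stain quantification

RGB converts to HSI by the classic arccos formulation (I the channel
mean; S = 1 - 3 min/sum; hue reflected when B > G, undefined at S = 0).
A pixel is band-positive when its circular hue distance to the band
centre is within half the band width, saturation >= 0.15, and intensity
falls in the band's half-open interval. The shipped bands — dark blue:
hue 240 +/- 40, I in [0, 120); light blue: same hue band, I in [120, 190)
— are artifact defaults consistent with the generator's stroke
distribution, not published stain annotations; real analyses should
annotate their own ranges and pass them through `hue_range()`.

Per slide, counts are taken over the top-attention tiles; tiles with zero
dark pixels are dropped as outliers (a config flag extends the rule to
either band), and the slide summary is the median dark count and median
dark/light ratio. Groups (predicted or labeled impairment) are compared
with Welch t-tests, and the joint (dark, ratio) distribution is contrasted
with 2-D kernel density estimates (`MASS::kde2d`, normal-reference
bandwidths) drawn as contour lines.

# Association statistics

Rank (Spearman) correlations relate slide probabilities and stain medians
to cohort traits, with pairwise-complete observations and the t
approximation for p-values. Differential correlation between groups uses
the Fisher z difference of within-group Spearman correlations (no
small-sample correction) with a two-sided empirical p-value from random
permutations of group membership; the smallest attainable p is
1/(permutations + 1), and the permutation seed is recorded in the result.

Conditional independence is tested with the likelihood-ratio chi-square:
continuous variables are discretised into 3 quantile bins (the
discretisation any such test must choose for continuous inputs; 3 bins
keep expected cell counts usable at n ~ 100), the statistic is G = 2N
times the conditional mutual information of the three-way table in
natural-log units, and degrees of freedom are (|X|-1)(|Y|-1) times the
number of non-empty conditioning strata (empty strata are dropped with a
warning). Both G and the raw mutual information are reported. One consequence of
discretisation worth noting: conditioning on a binned mediator removes only
the dependence the bins can carry, so for very tightly coupled chains a
correctly implemented discretized test will still detect residual
dependence; the structure-recovery simulations in the tests use moderate
couplings for which three bins suffice. Reported
p-values are unadjusted; a Benjamini-Hochberg flag is deliberately out of
scope of the defaults.

# Problem sizes and numerical choices

The demo configuration — 120 donors, 1024 px slides (~16 tiles each, ~6
kept), feature dimension 64, 10 folds — was chosen so a full pipeline run
finishes in about 3 minutes on one CPU, and the matched null run (no
effect, permuted labels) in about the same. Calibration simulations use
200 replicates with 199 permutations each for the differential-correlation
null and 100 chain replicates at n = 500 for structure recovery.

Other numerical conventions: softmax is computed with max-subtraction;
probabilities are floored at 1e-12 inside logs; feature standardisation
statistics are estimated on the training bags of each fold and stored in
the model; constant attention maps render at mid-scale; zero-variance
guards return zero statistics (z-transform, region t-test) or errors
(KDE axes, Fisher z at |rho| = 1) as documented per function.

# Known limitations

* The synthetic planted effect is far stronger and cleaner than real
  myelin pallor; desk-scale AUCs (~0.8) say nothing about attainable
  accuracy on real cohorts (reported accuracies there are modest).
* The hand-crafted extractor sees colour and texture summaries only; it
  cannot represent morphology (fibre orientation, vacuolisation), so
  attention differences are driven by stain statistics.
* Slide-level probabilities come from the single best fold, as in the
  analysis convention this package follows; they are not ensembled and
  inherit that fold's variance.
* Hue bands are generator-consistent defaults; transferring them to real
  LFB stains requires re-annotation.
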