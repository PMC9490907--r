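# lfbmil

Weakly supervised attention-based multiple instance learning (MIL) for
myelin histopathology, with interpretable downstream quantification.

## What this is for

Postmortem clinicopathologic correlation in brain aging rarely has pixel
annotations: what exists is a slide image and a noisy, slide-level record of
whether the donor was cognitively impaired (from CDR, clinical diagnosis, or
MMSE). `lfbmil` implements the full weakly supervised analysis chain for this
setting, for researchers in digital neuropathology:

1. **Labeling** — derive the binary cognitive-impairment (CI) label from the
   clinical measures (CDR >= 0.5, diagnosis, MMSE <= 24; CDR capped at 3),
   under either an any-evidence or a hierarchical policy.
2. **Tiling + features** — segment tissue by saturation thresholding, cut
   non-overlapping 256 x 256 tiles, embed each tile as a fixed-length feature
   vector (deterministic HSI/texture features by default; pluggable CNN
   embeddings via the same interface).
3. **Attention MIL** — classify each slide (bag of tiles) with gated
   attention pooling,

   e_k = w'(tanh(V h_k) ⊙ σ(U h_k)),  a = softmax(e),  z = Σ_k a_k h_k,

   trained with Adam (lr 2e-4) on bag cross-entropy plus an
   instance-clustering loss, with early stopping, under 10-fold Monte Carlo
   cross-validation (80/10/10 stratified splits). Per-fold AUCs are compared
   to chance with a one-sample Wilcoxon signed-rank test and ROC curves are
   vertically averaged.
4. **Interpretation** — per-slide z-transformed attention, white-matter vs
   grey-matter median attention with paired t-tests, attention heatmaps, and
   top-k attention tiles.
5. **Stain quantification** — HSI hue-range positive pixel counting of dark
   blue (myelin) and light blue staining in the top-attention tiles, slide
   medians, Welch group tests, and 2-D kernel density contrasts.
6. **Association statistics** — Spearman correlations with pathoclinical
   traits, permutation-based differential correlation (Fisher z, empirical
   p), and chi-square conditional independence tests via contingency mutual
   information (G = 2N·MI).

Because real cohorts of this kind are not publicly deposited, the package
ships a **synthetic slide generator** (`sim_config()`, `generate_cohort()`,
`generate_slide()`) that plants a known myelin-loss effect — reduced
dark-blue fibre density in white matter of impaired donors, optionally in
scattered patches — plus label noise, missingness and per-slide stain gain,
with per-tile ground truth for recovery testing.

## Worked example

```r
library(lfbmil)

res <- run_pipeline(pipeline_config(sim = sim_config(seed = 42)))
str(res$report[c("mean_auc", "auc_wilcoxon_p",
                 "wm_attention_median_z", "gm_attention_median_z")])
```

On the default demo conditions (120 synthetic slides, planted effect 0.3,
label noise 0.1, 10 folds; about 3 minutes on one CPU) this prints:

```
List of 4
 $ mean_auc             : num 0.797
 $ auc_wilcoxon_p       : num 0.00592
 $ wm_attention_median_z: num -0.0238
 $ gm_attention_median_z: num -0.662
```

Read: the classifier separates CI from NCI slides well above chance
(mean test AUC 0.80 across the 10 folds, Wilcoxon p = 0.006 against AUC
0.5), and the best-fold model's attention concentrates on white matter
(median per-slide WM z-attention above GM; the paired t-test in
`res$region_attention` is strongly significant). `res$stain$tests` then
shows the top-attention-tile dark-blue counts are lower in slides predicted
CI — the planted myelin-loss direction — and `res$assoc` carries the
correlation table, differential correlation by label group, and the
conditional-independence G tests.

Individual stages are exported too: `segment_tissue()`, `tile()`,
`extract_features()`, `mil_train()`, `attention_map()`, `top_k_tiles()`,
`tile_counts()`, `summarize_slide()`, `differential_correlation()`,
`conditional_independence()`, and friends. See `vignette("myelin-mil")` for
the methods account and every numerical convention.

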