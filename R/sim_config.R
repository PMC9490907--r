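#' Simulation configuration for synthetic LFB-like cohorts and slides
#'
#' Bundles every parameter of the synthetic-data generator: cohort size and
#' composition, the planted myelin-loss effect, label corruption, stain
#' variation, and slide geometry. Identical configurations (including `seed`)
#' produce bit-identical cohorts and pixel-identical slides.
#'
#' @param n_donors Number of brain donors (one slide each).
#' @param p_impaired Marginal probability that a donor is truly cognitively
#'   impaired (CI).
#' @param effect_size Fractional reduction of white-matter dark-blue pixel
#'   density in truly impaired donors, in `[0, 1)`. 0 plants no effect.
#' @param patchiness Fraction of the white-matter area affected by the myelin
#'   reduction (1 = uniform across WM; smaller values confine the loss to
#'   scattered patches).
#' @param label_noise Probability that a donor's recorded cognitive measures
#'   contradict the true impairment state.
#' @param missingness Per-measure probability that CDR, MMSE or the clinical
#'   diagnosis is missing.
#' @param age_mean,age_sd Age distribution (years).
#' @param age_ci_slope Logistic slope of true impairment on centred age
#'   (per year).
#' @param stain_gain_sd Standard deviation of the per-slide multiplicative RGB
#'   intensity factor, modelling systemic staining variation across slides.
#' @param slide_px Side length of the square slide image in pixels (>= 512).
#' @param wm_fraction Fraction of the tissue area that is white matter.
#' @param base_density Target dark-blue pixel fraction in unaffected white
#'   matter.
#' @param n_pieces Number of tissue pieces per slide (1 or 2).
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_donors = 10, slide_px = 512)
#' cfg$effect_size
#' @export
sim_config <- function(n_donors = 120,
                       p_impaired = 0.49,
                       effect_size = 0.3,
                       patchiness = 1,
                       label_noise = 0.1,
                       missingness = 0.15,
                       age_mean = 85,
                       age_sd = 10,
                       age_ci_slope = 0.08,
                       stain_gain_sd = 0.05,
                       slide_px = 1024,
                       wm_fraction = 0.4,
                       base_density = 0.10,
                       n_pieces = 1,
                       seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
  }
  chk_prob(p_impaired, "p_impaired")
  chk_prob(patchiness, "patchiness")
  chk_prob(label_noise, "label_noise")
  chk_prob(missingness, "missingness")
  chk_prob(wm_fraction, "wm_fraction")
  chk_prob(base_density, "base_density")
  if (!is.numeric(effect_size) || effect_size < 0 || effect_size >= 1)
    stop("`effect_size` must be in [0, 1)", call. = FALSE)
  if (n_donors < 1) stop("`n_donors` must be >= 1", call. = FALSE)
  if (slide_px < 512) stop("`slide_px` must be >= 512", call. = FALSE)
  if (age_sd <= 0) stop("`age_sd` must be positive", call. = FALSE)
  if (stain_gain_sd < 0) stop("`stain_gain_sd` must be >= 0", call. = FALSE)
  if (!n_pieces %in% c(1L, 2L)) stop("`n_pieces` must be 1 or 2", call. = FALSE)
  structure(list(
    n_donors = as.integer(n_donors), p_impaired = p_impaired,
    effect_size = effect_size, patchiness = patchiness,
    label_noise = label_noise, missingness = missingness,
    age_mean = age_mean, age_sd = age_sd, age_ci_slope = age_ci_slope,
    stain_gain_sd = stain_gain_sd, slide_px = as.integer(slide_px),
    wm_fraction = wm_fraction, base_density = base_density,
    n_pieces = as.integer(n_pieces), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic LFB cohort configuration\n")
  cat(sprintf("  donors: %d  (P(CI) = %.2f)\n", x$n_donors, x$p_impaired))
  cat(sprintf("  planted effect: %.2f over %.0f%% of WM\n",
              x$effect_size, 100 * x$patchiness))
  cat(sprintf("  label noise: %.2f  missingness: %.2f\n",
              x$label_noise, x$missingness))
  cat(sprintf("  slide: %d px, WM fraction %.2f, gain sd %.2f, seed %d\n",
              x$slide_px, x$wm_fraction, x$stain_gain_sd, x$seed))
  invisible(x)
}
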