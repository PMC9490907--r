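#' Generate a synthetic brain-donor cohort
#'
#' Draws donor covariates and cognitive measures with the statistical structure
#' the downstream analysis assumes: true impairment has a logistic dependence
#' on age; Braak stage, CERAD positivity, ARTAG and cerebrovascular disease are
#' positively associated with true impairment; the recorded cognitive measures
#' (CDR, MMSE, clinical diagnosis) are generated from the true state, then
#' contradicted at rate `label_noise` and masked at rate `missingness`.
#'
#' The true state is retained in column `true_state` for recovery testing only;
#' the analysis label is derived from the recorded measures via
#' [label_cohort()]. A small fraction of impaired donors receive raw dementia
#' severity scores above 3 so that CDR capping is exercised.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per donor: `donor_id`, `age`, `sex`,
#'   `cdr`, `mmse`, `clinical_dx`, `braak`, `cerad`, `artag`, `cvd`,
#'   `region`, `slide_path`, `true_state`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_donors = 20, slide_px = 512))
#' table(cohort$true_state)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_donors
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 55), 105), 1)
  p_ci <- stats::plogis(stats::qlogis(config$p_impaired) +
                          config$age_ci_slope * (age - config$age_mean))
  true_ci <- stats::rbinom(n, 1L, p_ci)
  sex <- ifelse(stats::runif(n) < 0.54, "F", "M")
  braak <- stats::rbinom(n, 6L, 0.38 + 0.04 * true_ci)
  cerad <- stats::rbinom(n, 1L, 0.15 + 0.05 * true_ci)
  artag <- stats::rbinom(n, 1L, 0.22 + 0.09 * true_ci)
  cvd <- stats::rbinom(n, 1L, 0.18 + 0.12 * true_ci)

  # recorded measures reflect an observed state that contradicts the true
  # state with probability label_noise
  flip <- stats::runif(n) < config$label_noise
  obs_ci <- ifelse(flip, 1L - true_ci, true_ci)
  cdr <- ifelse(obs_ci == 1L,
                sample(c(0.5, 1, 2, 3, 4, 5), n, replace = TRUE,
                       prob = c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03)),
                0)
  mmse <- ifelse(obs_ci == 1L,
                 sample(5:24, n, replace = TRUE),
                 sample(25:30, n, replace = TRUE))
  clinical_dx <- ifelse(obs_ci == 1L, "impaired", "not_impaired")
  miss <- matrix(stats::runif(3 * n) < config$missingness, ncol = 3)
  cdr[miss[, 1]] <- NA_real_
  clinical_dx[miss[, 2]] <- NA_character_
  mmse[miss[, 3]] <- NA_integer_

  donor_id <- sprintf("D%04d", seq_len(n))
  data.frame(
    donor_id = donor_id, age = age, sex = sex, cdr = cdr, mmse = mmse,
    clinical_dx = clinical_dx, braak = braak, cerad = cerad,
    artag = artag, cvd = cvd, region = "hippocampus",
    slide_path = paste0(donor_id, ".png"),
    true_state = ifelse(true_ci == 1L, "CI", "NCI"),
    stringsAsFactors = FALSE
  )
}

#' Write / read the cohort CSV
#'
#' Column order follows the pipeline's external contract: `donor_id`, `age`,
#' `sex`, `cdr`, `mmse`, `clinical_dx`, `braak`, `cerad`, `artag`, `cvd`,
#' `region`, `slide_path`, plus any derived columns (`label`, `p_ci`, ...).
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  lead <- c("donor_id", "age", "sex", "cdr", "mmse", "clinical_dx", "braak",
            "cerad", "artag", "cvd", "region", "slide_path")
  lead <- lead[lead %in% names(cohort)]
  cohort <- cohort[, c(lead, setdiff(names(cohort), lead)), drop = FALSE]
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so that generator functions are pure in
# the calling session apart from their declared seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
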