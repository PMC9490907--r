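#' Labeling policy for cognitive impairment
#'
#' Defines how the binary cognitive-impairment (CI) label is derived from the
#' three available clinical measures: the Clinical Dementia Rating (CDR), the
#' clinical diagnosis, and the Mini-Mental State Examination (MMSE).
#'
#' Two modes are supported. In `"any_evidence"` (the default) a donor is CI if
#' any available measure is positive (CDR >= `cdr_threshold`, diagnosis of
#' impairment, or MMSE <= `mmse_threshold`), NCI if at least one measure is
#' available and all available measures are negative, and `excluded` when no
#' measure is available. In `"hierarchical"` mode the first available measure
#' in the order CDR, diagnosis, MMSE decides alone.
#'
#' @param mode `"any_evidence"` or `"hierarchical"`.
#' @param cdr_threshold CDR at or above which a donor counts as impaired.
#' @param mmse_threshold MMSE at or below which a donor counts as impaired.
#' @param cdr_cap Maximum CDR; larger recorded values are truncated for
#'   consistency across contributing centres.
#' @return An object of class `label_policy`.
#' @export
label_policy <- function(mode = c("any_evidence", "hierarchical"),
                         cdr_threshold = 0.5, mmse_threshold = 24,
                         cdr_cap = 3) {
  mode <- match.arg(mode)
  structure(list(mode = mode, cdr_threshold = cdr_threshold,
                 mmse_threshold = mmse_threshold, cdr_cap = cdr_cap),
            class = "label_policy")
}

#' Cap CDR scores at a maximum severity
#'
#' Recorded dementia severity scores above the cap (default 3, the standard CDR
#' maximum) are truncated; missing values pass through unchanged.
#'
#' @param cdr Numeric vector of CDR scores (may contain `NA`).
#' @param cap Maximum allowed value.
#' @return `pmin(cdr, cap)` with `NA` preserved.
#' @examples
#' cap_cdr(c(0, 0.5, 4, NA))
#' @export
cap_cdr <- function(cdr, cap = 3) {
  if (any(!is.na(cdr) & cdr < 0))
    stop("CDR scores must be non-negative", call. = FALSE)
  pmin(cdr, cap)
}

#' Assign the cognitive-impairment label to donors
#'
#' Vectorised over donors. CDR values are assumed already capped (see
#' [cap_cdr()]); [label_cohort()] applies both steps to a cohort table.
#'
#' @param cdr,mmse Numeric vectors (may contain `NA`).
#' @param clinical_dx Character vector with values `"impaired"`,
#'   `"not_impaired"` or `NA`.
#' @param policy A [label_policy()].
#' @return Character vector with values `"CI"`, `"NCI"` or `"excluded"`.
#' @examples
#' assign_label(cdr = 0.5, mmse = 30, clinical_dx = NA, policy = label_policy())
#' assign_label(cdr = NA, mmse = 24, clinical_dx = NA, policy = label_policy())
#' @export
assign_label <- function(cdr, mmse, clinical_dx, policy = label_policy()) {
  n <- max(length(cdr), length(mmse), length(clinical_dx))
  cdr <- rep_len(cdr, n); mmse <- rep_len(mmse, n)
  clinical_dx <- rep_len(as.character(clinical_dx), n)
  bad <- !is.na(clinical_dx) & !clinical_dx %in% c("impaired", "not_impaired")
  if (any(bad))
    stop("unknown clinical_dx code: ", paste(unique(clinical_dx[bad]), collapse = ", "),
         call. = FALSE)
  cdr_pos <- !is.na(cdr) & cdr >= policy$cdr_threshold
  dx_pos <- !is.na(clinical_dx) & clinical_dx == "impaired"
  mmse_pos <- !is.na(mmse) & mmse <= policy$mmse_threshold
  avail <- cbind(!is.na(cdr), !is.na(clinical_dx), !is.na(mmse))
  pos <- cbind(cdr_pos, dx_pos, mmse_pos)
  out <- rep("excluded", n)
  if (policy$mode == "any_evidence") {
    any_avail <- rowSums(avail) > 0
    any_pos <- rowSums(pos) > 0
    out[any_avail & any_pos] <- "CI"
    out[any_avail & !any_pos] <- "NCI"
  } else {
    # first available measure in the order CDR -> diagnosis -> MMSE decides
    first <- apply(avail, 1L, function(a) if (any(a)) which(a)[1] else NA_integer_)
    has <- !is.na(first)
    decided <- pos[cbind(which(has), first[has])]
    out[has] <- ifelse(decided, "CI", "NCI")
  }
  out
}

#' Label a cohort table
#'
#' Caps CDR scores and appends a `label` column derived from the policy.
#'
#' @param cohort Data frame with columns `cdr`, `mmse`, `clinical_dx`.
#' @param policy A [label_policy()].
#' @return The cohort with `cdr` capped and a `label` column added.
#' @export
label_cohort <- function(cohort, policy = label_policy()) {
  stopifnot(all(c("cdr", "mmse", "clinical_dx") %in% names(cohort)))
  cohort$cdr <- cap_cdr(cohort$cdr, policy$cdr_cap)
  cohort$label <- assign_label(cohort$cdr, cohort$mmse, cohort$clinical_dx, policy)
  cohort
}
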