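#' Baseline-referenced Z-score change
#'
#' Both timepoints are standardized against the baseline cohort mean and
#' SD, so the difference z(followup) - z(baseline) is a change score in
#' baseline-SD units, invariant to shifting both timepoints by a constant
#' or rescaling both by a positive factor. For scales where a lower raw
#' score is better (timed tests, symptom inventories), declare
#' `higher_is_better = FALSE` and the sign is flipped so that a positive
#' change always means clinical improvement.
#'
#' @param baseline,followup numeric vectors of equal length (>= 3); pairs
#'   with a missing value propagate `NA`.
#' @param higher_is_better does a higher raw score mean a better outcome?
#' @return Numeric vector of oriented Z-score changes with attribute
#'   `"orientation"` (`"improvement_positive"`) recording the convention.
#' @export
zscore_change <- function(baseline, followup, higher_is_better = TRUE) {
  if (length(baseline) != length(followup))
    stop("'baseline' and 'followup' must have the same length", call. = FALSE)
  if (length(baseline) < 3L)
    stop("need at least 3 patients", call. = FALSE)
  m <- mean(baseline, na.rm = TRUE)
  s <- stats::sd(baseline, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("baseline has zero variance: scale is uninformative", call. = FALSE)
  dz <- (followup - m) / s - (baseline - m) / s
  if (!higher_is_better) dz <- -dz
  structure(dz, orientation = "improvement_positive")
}

#' Scales with a significant baseline-to-follow-up change
#'
#' Runs a two-sided paired t test per scale and keeps the scales whose
#' p value is less than or equal to `alpha` (change in either direction
#' counts). Only these scales proceed to voxel-wise mapping.
#'
#' @param patients a patient data frame (see [load_patient_table()]).
#' @param scales scale names to test; default all detected scales.
#' @param alpha selection threshold (ties at exactly `alpha` are selected).
#' @param min_pairs minimum complete baseline/follow-up pairs per scale.
#' @return Character vector of selected scale names, with the per-scale
#'   p values in attribute `"p_values"` (named, all tested scales).
#' @export
select_significant_scales <- function(patients, scales = NULL, alpha = 0.05,
                                      min_pairs = 3L) {
  if (is.null(scales)) scales <- scale_names(patients)
  p <- stats::setNames(rep(NA_real_, length(scales)), scales)
  for (sc in scales) {
    b <- patients[[paste0(sc, "_baseline")]]
    f <- patients[[paste0(sc, "_followup")]]
    ok <- stats::complete.cases(b, f)
    if (sum(ok) < min_pairs) next
    if (stats::sd(f[ok] - b[ok]) == 0) {
      p[sc] <- if (any(f[ok] != b[ok])) 0 else 1
      next
    }
    p[sc] <- stats::t.test(f[ok], b[ok], paired = TRUE)$p.value
  }
  structure(scales[!is.na(p) & p <= alpha], p_values = p)
}

#' Cohort summary of baseline and follow-up scores
#'
#' Mean (SD) at each timepoint, two-sided paired t test and effect sizes
#' per scale. Because the effect-size convention behind published tables
#' is often ambiguous, both the paired Cohen's d (mean difference / SD of
#' the differences) and the pooled-SD d are reported, labelled.
#'
#' @inheritParams select_significant_scales
#' @return A data frame with one row per scale: `scale`, `n`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`,
#'   `p_paired_t`, `cohens_d_paired`, `cohens_d_pooled`, `note`. Scales
#'   with constant differences get `NA` tests and an explanatory note.
#' @export
cohort_summary <- function(patients, scales = NULL) {
  if (is.null(scales)) scales <- scale_names(patients)
  rows <- lapply(scales, function(sc) {
    b <- patients[[paste0(sc, "_baseline")]]
    f <- patients[[paste0(sc, "_followup")]]
    ok <- stats::complete.cases(b, f)
    b <- b[ok]; f <- f[ok]
    out <- data.frame(scale = sc, n = sum(ok),
                      baseline_mean = mean(b), baseline_sd = stats::sd(b),
                      followup_mean = mean(f), followup_sd = stats::sd(f),
                      p_paired_t = NA_real_,
                      cohens_d_paired = NA_real_,
                      cohens_d_pooled = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (sum(ok) < 2L) {
      out$note <- "fewer than 2 complete pairs"
      return(out)
    }
    d <- b - f  # positive = raw score decreased
    if (stats::sd(d) == 0) {
      out$note <- "constant difference: no test computed"
      return(out)
    }
    out$p_paired_t <- stats::t.test(b, f, paired = TRUE)$p.value
    out$cohens_d_paired <- mean(d) / stats::sd(d)
    sp <- sqrt((stats::sd(b)^2 + stats::sd(f)^2) / 2)
    out$cohens_d_pooled <- if (sp > 0) mean(d) / sp else NA_real_
    out
  })
  do.call(rbind, rows)
}

#' Percentage outcome change, improvement-positive
#'
#' For scales where a lower raw score is better (e.g. symptom counts,
#' timed tests) the change is 100 (baseline - followup) / baseline;
#' otherwise 100 (followup - baseline) / baseline. Positive values always
#' mean improvement; magnitudes above 100% are legitimate for large
#' worsenings. Patients with a zero baseline are excluded (`NA`) with a
#' warning.
#'
#' @param baseline,followup numeric vectors (recycled to common length).
#' @param higher_is_better does a higher raw score mean a better outcome?
#' @return Numeric vector of percentage changes.
#' @export
percent_change <- function(baseline, followup, higher_is_better = TRUE) {
  n <- max(length(baseline), length(followup))
  baseline <- rep_len(baseline, n); followup <- rep_len(followup, n)
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero))
    warning(sprintf("%d patient(s) with zero baseline excluded from percent change",
                    sum(zero)), call. = FALSE)
  pc <- if (higher_is_better) 100 * (followup - baseline) / baseline
        else 100 * (baseline - followup) / baseline
  pc[zero] <- NA_real_
  pc
}
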