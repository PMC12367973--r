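#' Median-split of VTA-to-cluster distances
#'
#' Patients whose distance is less than or equal to the median form the
#' `"closer"` stimulated group, the rest the `"farther"` group. Ties at
#' the median go to the closer group (deterministic cutoff semantics);
#' with an even patient count and no ties both groups have equal size.
#'
#' @param distances numeric vector of distances in mm (>= 2 patients).
#' @return A list with `group` (factor `closer`/`farther`) and
#'   `cutoff_mm` (the median).
#' @export
assign_groups <- function(distances) {
  if (length(distances) < 2L)
    stop("need at least 2 patients to split", call. = FALSE)
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  med <- stats::median(distances)
  grp <- factor(ifelse(distances <= med, "closer", "farther"),
                levels = c("closer", "farther"))
  if (all(grp == "closer"))
    warning("all distances at or below the median: everyone in the closer group",
            call. = FALSE)
  list(group = grp, cutoff_mm = med)
}

# closer/farther comparison for one cluster on one scale
.concordance_one <- function(center_mm, hemisphere, direction, vtas,
                             baseline, followup, higher_is_better,
                             flip_mask = NULL) {
  stopifnot(length(vtas) == length(baseline),
            length(baseline) == length(followup))
  if (!is.null(flip_mask))
    vtas[flip_mask] <- lapply(vtas[flip_mask], flip_lr)
  hemi <- if (hemisphere %in% c("left", "right")) hemisphere else "bilateral"
  centers <- t(vapply(vtas, vta_center, numeric(3), hemisphere = hemi))
  dist_mm <- sqrt(rowSums(sweep(centers, 2L, center_mm, "-")^2))
  split <- assign_groups(dist_mm)
  pct <- percent_change(baseline, followup, higher_is_better)
  closer <- split$group == "closer" & !is.na(pct)
  farther <- split$group == "farther" & !is.na(pct)
  cm <- if (sum(closer)) mean(pct[closer]) else NA_real_
  fm <- if (sum(farther)) mean(pct[farther]) else NA_real_
  concordant <- if (sum(closer) < 2L || sum(farther) < 2L) NA
    else if (direction == "improvement") cm > fm else cm < fm
  list(distance_mm = dist_mm, group = split$group,
       median_cutoff_mm = split$cutoff_mm, percent_change = pct,
       closer_mean_pct = cm, farther_mean_pct = fm, concordant = concordant)
}

#' Distance-based outcome prediction for new patients
#'
#' The proof-of-concept single-subject rule: for each significant cluster
#' of the fitted map, compute the Euclidean distance from each new
#' patient's VTA center (restricted to the cluster's hemisphere) to the
#' cluster center, split the new cohort at the median distance into a
#' closer and a farther stimulated group, and compare the groups' mean
#' percentage outcome changes. The prediction is concordant when the
#' closer group's mean change is strictly more in the cluster's direction
#' (larger improvement for improvement clusters, larger worsening for
#' worsening clusters) than the farther group's.
#'
#' @param object a fitted [vlsm()] model with at least one significant
#'   cluster.
#' @param vtas list of [vta_mask()] objects for the new patients.
#' @param baseline,followup raw scores of the new patients on the mapped
#'   scale.
#' @param higher_is_better orientation of the raw scale (see
#'   [percent_change()]).
#' @param flip logical vector marking new patients whose masks must be
#'   mirrored before distance computation (motor analyses where the most
#'   affected body side is the right), or `NULL` for none.
#' @param clusters `"significant"` (default) or `"all"`.
#' @param ... unused.
#' @return A data frame of class `"vlsm_prediction"`, one row per patient
#'   and cluster: `cluster`, `direction`, `patient`, `distance_mm`,
#'   `median_cutoff_mm`, `group`, `percent_change`; per-cluster summary
#'   (group means and concordance) in attribute `"summary"`.
#' @export
predict.vlsm <- function(object, vtas, baseline, followup,
                         higher_is_better = TRUE, flip = NULL,
                         clusters = c("significant", "all"), ...) {
  clusters <- match.arg(clusters)
  tab <- object$clusters
  if (clusters == "significant")
    tab <- tab[tab$significant, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("the fitted map has no ", clusters, " clusters to predict from",
         call. = FALSE)
  ids <- vapply(vtas, `[[`, character(1), "patient_id")
  detail <- NULL
  summ <- NULL
  for (i in seq_len(nrow(tab))) {
    cl <- tab[i, ]
    res <- .concordance_one(c(cl$x, cl$y, cl$z), cl$hemisphere,
                            cl$direction, vtas, baseline, followup,
                            higher_is_better, flip_mask = flip)
    detail <- rbind(detail, data.frame(
      cluster = cl$cluster, direction = cl$direction, patient = ids,
      distance_mm = res$distance_mm,
      median_cutoff_mm = res$median_cutoff_mm,
      group = as.character(res$group),
      percent_change = res$percent_change, stringsAsFactors = FALSE))
    summ <- rbind(summ, data.frame(
      cluster = cl$cluster, direction = cl$direction,
      n_closer = sum(res$group == "closer"),
      n_farther = sum(res$group == "farther"),
      closer_mean_pct = res$closer_mean_pct,
      farther_mean_pct = res$farther_mean_pct,
      concordant = res$concordant, stringsAsFactors = FALSE))
  }
  structure(detail, summary = summ, class = c("vlsm_prediction",
                                              "data.frame"))
}

#' @export
print.vlsm_prediction <- function(x, ...) {
  cat("Distance-based outcome prediction\n\nPer-cluster summary:\n")
  print(attr(x, "summary"), row.names = FALSE)
  cat("\nPer-patient assignments:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Concordance of a new cohort with mapped clusters across scales
#'
#' Applies the distance/median-split rule of [predict.vlsm()] to every
#' cluster in a results table (e.g. from [run_vlsm_analysis()]), using
#' each cluster's own scale to pick the raw scores, the scale metadata to
#' orient percentage changes, and mirroring motor-scale masks of patients
#' whose most affected side is the right.
#'
#' @param clusters data frame with columns `scale`, `cluster`,
#'   `direction`, `hemisphere`, `x`, `y`, `z`.
#' @param patients new-cohort patient table with `<scale>_baseline` /
#'   `<scale>_followup` columns and `most_affected_side`.
#' @param vtas list of [vta_mask()] objects aligned with `patients`.
#' @param scale_info data frame with columns `scale`, `domain`,
#'   `higher_is_better`.
#' @param flip_motor mirror masks of right-most-affected patients for
#'   motor-domain scales (default `TRUE`).
#' @return A list with `summary` (per-cluster concordance table including
#'   `concordant_fraction` attribute) and `detail` (per-patient rows).
#' @export
evaluate_concordance <- function(clusters, patients, vtas, scale_info,
                                 flip_motor = TRUE) {
  stopifnot(nrow(patients) == length(vtas))
  summ <- NULL; detail <- NULL
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    meta <- scale_info[scale_info$scale == cl$scale, ]
    if (nrow(meta) != 1L)
      stop("no (unique) metadata for scale '", cl$scale, "'", call. = FALSE)
    b <- patients[[paste0(cl$scale, "_baseline")]]
    f <- patients[[paste0(cl$scale, "_followup")]]
    ok <- stats::complete.cases(b, f)
    flip <- if (flip_motor && meta$domain == "motor")
      patients$most_affected_side[ok] == "right" else NULL
    res <- .concordance_one(c(cl$x, cl$y, cl$z), cl$hemisphere,
                            cl$direction, vtas[ok], b[ok], f[ok],
                            meta$higher_is_better, flip_mask = flip)
    summ <- rbind(summ, data.frame(
      scale = cl$scale, cluster = cl$cluster, direction = cl$direction,
      n_closer = sum(res$group == "closer"),
      n_farther = sum(res$group == "farther"),
      closer_mean_pct = res$closer_mean_pct,
      farther_mean_pct = res$farther_mean_pct,
      concordant = res$concordant, stringsAsFactors = FALSE))
    detail <- rbind(detail, data.frame(
      scale = cl$scale, cluster = cl$cluster,
      patient = patients$id[ok], distance_mm = res$distance_mm,
      median_cutoff_mm = res$median_cutoff_mm,
      group = as.character(res$group),
      percent_change = res$percent_change, stringsAsFactors = FALSE))
  }
  frac <- mean(summ$concordant, na.rm = TRUE)
  attr(summ, "concordant_fraction") <- frac
  list(summary = summ, detail = detail)
}
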