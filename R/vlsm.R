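#' Voxel-wise stimulated-vs-non-stimulated mapping with permutation
#' cluster correction
#'
#' `vlsm()` fits, at every voxel covered by at least one patient's VTA, a
#' linear model of the outcome change on a stimulated/non-stimulated group
#' indicator (patients whose VTA contains the voxel vs those whose VTA
#' does not) plus nuisance covariates, and reports the t statistic of the
#' group term. Voxels where either group has fewer than `min_group_n`
#' patients are discarded to maintain statistical power. Supra-threshold
#' clusters are corrected for family-wise error by permuting the outcome
#' vector across patients (VTAs and covariates fixed), recomputing the
#' full map each time, and comparing each observed cluster against the
#' permutation distribution of the maximum cluster statistic.
#'
#' The outcome (the formula's left-hand side) is expected to be
#' improvement-oriented, as produced by [zscore_change()]: a positive
#' group effect is labelled `"improvement"`, a negative one
#' `"worsening"`.
#'
#' With `tail = "both"` (default) each observed cluster of either sign is
#' compared against the null maximum over both signs, so the chance of
#' reporting any spurious cluster in either direction is controlled at
#' `alpha`. `tail = "separate"` corrects each direction against its own
#' one-sided null at `alpha`.
#'
#' @param formula model formula; left-hand side is the per-patient outcome
#'   change, right-hand side the nuisance covariates (use `~ 1` for none).
#' @param data data frame holding the formula's variables, one row per
#'   patient, aligned with `vtas`.
#' @param vtas list of [vta_mask()] objects, one per row of `data`, all on
#'   the same grid.
#' @param min_group_n minimum patients per group at a voxel (default 4).
#' @param n_permutations number of outcome permutations (>= 100).
#' @param alpha cluster-level significance threshold.
#' @param cluster_forming_p two-sided voxel-level p defining the
#'   cluster-forming t threshold (default 0.01).
#' @param connectivity neighbourhood for cluster formation: 6, 18 or 26.
#' @param tail `"both"` or `"separate"`; see Details.
#' @param permutation `"manly"` (permute the raw outcome) or
#'   `"freedman_lane"` (permute covariate-adjusted residuals).
#' @param null_statistic `"size"` (cluster extent) or `"mass"` (sum of
#'   |t| over members).
#' @param scale optional name of the clinical scale being mapped (label
#'   only).
#' @param seed integer seed for the permutation stream; drawn from the
#'   session RNG if omitted, and always recorded in the result.
#' @param perm_block permutations processed per matrix block (memory
#'   knob; no effect on results).
#' @return An object of class `"vlsm"`; see [summary.vlsm()]. Key fields:
#'   `tmap`, `beta`, `eligible`, `n_stim` (3-D arrays), `df`, `clusters`
#'   (data frame with `cluster`, `direction`, `hemisphere`, `size`,
#'   `mass`, `peak_t`, `x`, `y`, `z`, `p`, `significant`),
#'   `cluster_voxels`, `null_max`, `config`.
#' @examples
#' sim <- simulate_cohort(simulation_spec(seed = 7))
#' dz <- zscore_change(sim$patients$memory_baseline,
#'                     sim$patients$memory_followup)
#' fit <- vlsm(dz ~ age + sex + duration_years,
#'             data = cbind(sim$patients, dz = dz), vtas = sim$vtas,
#'             n_permutations = 200, seed = 1)
#' summary(fit)
#' @export
vlsm <- function(formula, data, vtas, min_group_n = 4L,
                 n_permutations = 1000L, alpha = 0.05,
                 cluster_forming_p = 0.01, connectivity = 26L,
                 tail = c("both", "separate"),
                 permutation = c("manly", "freedman_lane"),
                 null_statistic = c("size", "mass"),
                 scale = NULL, seed = NULL, perm_block = 250L) {
  tail <- match.arg(tail)
  permutation <- match.arg(permutation)
  null_statistic <- match.arg(null_statistic)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  if (n_permutations < 100L)
    stop("'n_permutations' must be at least 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || cluster_forming_p <= 0 ||
      cluster_forming_p >= 1)
    stop("'alpha' and 'cluster_forming_p' must lie in (0, 1)", call. = FALSE)
  if (min_group_n < 2L) stop("'min_group_n' must be >= 2", call. = FALSE)
  if (length(vtas) != nrow(data))
    stop("need exactly one VTA mask per row of 'data'", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  formula <- .drop_constant_terms(formula, data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  if (!all(keep))
    message(sprintf("dropping %d patient(s) with missing outcome or covariates",
                    sum(!keep)))
  mf <- mf[keep, , drop = FALSE]
  vtas <- vtas[keep]
  n <- nrow(mf)
  if (n < min_group_n)
    stop("fewer patients than 'min_group_n': refusing to run", call. = FALSE)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X))
    stop("covariate design matrix is rank deficient", call. = FALSE)
  df <- n - ncol(X) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)

  grid <- vtas[[1L]]$grid
  .stopifnot_grid(grid)
  for (m in vtas)
    if (!grids_compatible(grid, m$grid))
      stop("all VTA masks must share one grid", call. = FALSE)

  prep <- .vlsm_prepare(vtas, X, min_group_n, grid)
  cfg <- list(min_group_n = as.integer(min_group_n),
              n_permutations = as.integer(n_permutations), alpha = alpha,
              cluster_forming_p = cluster_forming_p,
              connectivity = connectivity, tail = tail,
              permutation = permutation, null_statistic = null_statistic,
              seed = as.integer(seed))
  out <- list(call = match.call(), formula = formula, scale = scale,
              n = n, df = df, grid = grid, config = cfg, X = X, y = y)
  class(out) <- "vlsm"

  dims <- as.integer(grid$shape)
  out$covered <- array(FALSE, dims); out$covered[prep$lin_cov] <- TRUE
  out$eligible <- array(FALSE, dims); out$eligible[prep$lin_elig] <- TRUE
  out$n_stim <- array(NA_integer_, dims)
  out$n_stim[prep$lin_cov] <- prep$n_stim
  out$ineligible_reason <- prep$reason

  tmap <- array(NA_real_, dims)
  beta <- array(NA_real_, dims)
  if (length(prep$lin_elig) == 0L) {
    warning("no voxel passed the minimum-group-size rule: empty map",
            call. = FALSE)
    out$tmap <- tmap; out$beta <- beta
    out$clusters <- .empty_cluster_table()
    out$cluster_voxels <- list()
    out$null_max <- matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("positive", "negative")))
    out$t_threshold <- stats::qt(1 - cluster_forming_p / 2, df)
    return(out)
  }

  Q <- qr(X)
  Ry <- qr.resid(Q, y)
  y_ss <- sum((y - mean(y))^2)
  tv <- .t_stats(crossprod(prep$Gr, Ry), prep$d, sum(Ry^2), df, y_ss)
  tmap[prep$lin_elig] <- tv
  beta[prep$lin_elig] <- crossprod(prep$Gr, Ry)[, 1] / prep$d
  out$tmap <- tmap; out$beta <- beta
  out$residuals_covariates <- Ry

  t_crit <- stats::qt(1 - cluster_forming_p / 2, df)
  out$t_threshold <- t_crit
  pos <- form_clusters(tmap, out$eligible, grid, t_crit, "positive",
                       connectivity)
  neg <- form_clusters(tmap, out$eligible, grid, t_crit, "negative",
                       connectivity)

  null_max <- .permutation_null(prep, Q, y, Ry, df, t_crit, dims,
                                connectivity, null_statistic, permutation,
                                n_permutations, seed, perm_block, y_ss)
  out$null_max <- null_max

  out$clusters <- .score_clusters(pos, neg, null_max, tail, alpha,
                                  null_statistic, n_permutations)
  out$cluster_voxels <- c(pos$voxels, neg$voxels)[out$clusters$.order]
  out$clusters$.order <- NULL
  out
}

# drop covariate terms that are constant in the analyzed rows (e.g. a
# single-sex cohort): they carry no information and break factor coding
.drop_constant_terms <- function(formula, data) {
  tl <- attr(stats::terms(formula, data = data), "term.labels")
  if (!length(tl)) return(formula)
  keep <- vapply(tl, function(tm) {
    v <- tryCatch(eval(str2lang(tm), data), error = function(e) NULL)
    if (is.null(v)) return(TRUE)
    length(unique(v[!is.na(v)])) >= 2L
  }, logical(1))
  if (all(keep)) return(formula)
  message("dropping constant covariate term(s): ",
          paste(tl[!keep], collapse = ", "))
  stats::reformulate(if (any(keep)) tl[keep] else "1",
                     response = formula[[2L]])
}

# coverage matrix and eligibility bookkeeping shared with voxelwise_t()
.vlsm_prepare <- function(vtas, X, min_group_n, grid) {
  n <- length(vtas)
  covered <- Reduce(`|`, lapply(vtas, `[[`, "voxels"))
  lin_cov <- which(covered)
  G <- vapply(vtas, function(m) as.numeric(m$voxels[lin_cov]),
              numeric(length(lin_cov)))
  if (length(lin_cov) == 1L) G <- matrix(G, nrow = 1L)
  n_stim <- as.integer(rowSums(G))
  elig <- n_stim >= min_group_n & (n - n_stim) >= min_group_n
  reason <- array(NA_integer_, dim(covered))
  reason[lin_cov] <- ifelse(elig, 0L, 1L)  # 1 = min-group rule
  Gr <- NULL; d <- NULL
  if (any(elig)) {
    Q <- qr(X)
    Gr <- qr.resid(Q, t(G[elig, , drop = FALSE]))  # n x Ve
    d <- colSums(Gr^2)
    collinear <- d <= 1e-8
    if (any(collinear)) {
      reason[lin_cov[elig][collinear]] <- 2L  # 2 = collinear with covariates
      keep <- !collinear
      Gr <- Gr[, keep, drop = FALSE]; d <- d[keep]
      elig[elig] <- keep
    }
  }
  list(lin_cov = lin_cov, lin_elig = lin_cov[elig], n_stim = n_stim,
       Gr = Gr, d = d, reason = reason)
}

# t statistics of the group term from residualized cross-products.
# C: Ve x B matrix (or vector) of crossprod(Gr, Ry); d: Ve sums of squares;
# yy: per-permutation residual sum of squares of the outcome (length B);
# y_ss: outcome sum of squares before residualization, used to recognize
# outcomes that are numerically constant after covariate adjustment
# (catastrophic cancellation would otherwise turn 1e-30-scale residuals
# into O(1) t values).
.t_stats <- function(C, d, yy, df, y_ss = NULL) {
  C <- cbind(C)
  if (is.null(y_ss)) y_ss <- max(yy)
  degen <- if (y_ss == 0) rep(TRUE, length(yy)) else yy <= y_ss * 1e-14
  RSS <- pmax(rep(yy, each = nrow(C)) - C^2 / d, 0)
  tt <- C * sqrt(df) / sqrt(d * RSS)
  bad <- !is.finite(tt)
  if (any(bad)) tt[bad] <- ifelse(C[bad] == 0, 0, sign(C[bad]) * Inf)
  if (any(degen)) tt[, degen] <- 0
  if (ncol(tt) == 1L) tt[, 1L] else tt
}

.permutation_null <- function(prep, Q, y, Ry, df, t_crit, dims, connectivity,
                              null_statistic, permutation, B, seed,
                              perm_block, y_ss = NULL) {
  n <- length(y)
  null_max <- matrix(0, B, 2,
                     dimnames = list(NULL, c("positive", "negative")))
  base <- if (permutation == "manly") y else Ry
  set.seed(seed)
  done <- 0L
  while (done < B) {
    nb <- min(perm_block, B - done)
    P <- replicate(nb, sample.int(n))
    RYp <- qr.resid(Q, matrix(base[P], n, nb))
    C <- crossprod(prep$Gr, RYp)
    Tm <- .t_stats(C, prep$d, colSums(RYp^2), df, y_ss)
    Tm <- cbind(Tm)
    for (b in seq_len(nb)) {
      tb <- Tm[, b]
      up <- tb > t_crit
      dn <- tb < -t_crit
      null_max[done + b, 1L] <- .max_cluster_stat(
        prep$lin_elig[up], dims, connectivity, null_statistic, tb[up])
      null_max[done + b, 2L] <- .max_cluster_stat(
        prep$lin_elig[dn], dims, connectivity, null_statistic, tb[dn])
    }
    done <- done + nb
  }
  null_max
}

.empty_cluster_table <- function() {
  data.frame(cluster = integer(), direction = character(),
             hemisphere = character(), size = integer(), mass = numeric(),
             peak_t = numeric(), x = numeric(), y = numeric(), z = numeric(),
             p = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

.score_clusters <- function(pos, neg, null_max, tail, alpha, null_statistic,
                            B) {
  tab <- rbind(pos$table, neg$table)
  if (nrow(tab) == 0L) {
    out <- .empty_cluster_table()
    out$.order <- integer()
    return(out)
  }
  stat_obs <- if (null_statistic == "size") tab$size else tab$mass
  null_pos <- null_max[, "positive"]; null_neg <- null_max[, "negative"]
  p <- vapply(seq_len(nrow(tab)), function(i) {
    nd <- switch(tail,
                 both = pmax(null_pos, null_neg),
                 separate = if (tab$sign[i] == "positive") null_pos
                            else null_neg)
    (1 + sum(nd >= stat_obs[i])) / (B + 1)
  }, numeric(1))
  out <- data.frame(
    cluster = seq_len(nrow(tab)),
    direction = ifelse(tab$sign == "positive", "improvement", "worsening"),
    hemisphere = ifelse(tab$x > 0, "right",
                        ifelse(tab$x < 0, "left", "midline")),
    size = tab$size, mass = tab$mass, peak_t = tab$peak_t,
    x = tab$x, y = tab$y, z = tab$z, p = p, significant = p < alpha,
    stringsAsFactors = FALSE)
  ord <- order(out$p, -out$size)
  out <- out[ord, , drop = FALSE]
  out$.order <- ord
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Voxel-wise group t statistics without cluster inference
#'
#' The mass-univariate stage of [vlsm()] on its own: per-voxel t of the
#' stimulated-vs-non-stimulated indicator after adjusting for covariates,
#' plus the eligibility bookkeeping, without permutation correction.
#'
#' @inheritParams vlsm
#' @return A list with `tmap`, `beta`, `eligible`, `covered`, `n_stim`,
#'   `ineligible_reason` (3-D arrays), scalar `df` and the `grid`.
#' @export
voxelwise_t <- function(formula, data, vtas, min_group_n = 4L) {
  formula <- .drop_constant_terms(formula, data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  vtas <- vtas[keep]
  n <- nrow(mf)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X))
    stop("covariate design matrix is rank deficient", call. = FALSE)
  df <- n - ncol(X) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  grid <- vtas[[1L]]$grid
  prep <- .vlsm_prepare(vtas, X, min_group_n, grid)
  dims <- as.integer(grid$shape)
  tmap <- array(NA_real_, dims); beta <- array(NA_real_, dims)
  eligible <- array(FALSE, dims); eligible[prep$lin_elig] <- TRUE
  covered <- array(FALSE, dims); covered[prep$lin_cov] <- TRUE
  n_stim <- array(NA_integer_, dims); n_stim[prep$lin_cov] <- prep$n_stim
  if (length(prep$lin_elig)) {
    Q <- qr(X)
    Ry <- qr.resid(Q, y)
    cv <- crossprod(prep$Gr, Ry)[, 1]
    tmap[prep$lin_elig] <- .t_stats(cv, prep$d, sum(Ry^2), df,
                                    sum((y - mean(y))^2))
    beta[prep$lin_elig] <- cv / prep$d
  }
  list(tmap = tmap, beta = beta, eligible = eligible, covered = covered,
       n_stim = n_stim, ineligible_reason = prep$reason, df = df,
       grid = grid)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.vlsm <- function(x, ...) {
  cat("Voxel-wise stimulation-outcome mapping (VLSM)\n")
  if (!is.null(x$scale)) cat(sprintf("  scale        : %s\n", x$scale))
  cat(sprintf("  patients     : %d (residual df %d)\n", x$n, x$df))
  cat(sprintf("  eligible     : %d of %d covered voxels\n",
              sum(x$eligible), sum(x$covered)))
  cat(sprintf("  permutations : %d (seed %d, %s null, tail '%s')\n",
              x$config$n_permutations, x$config$seed,
              x$config$null_statistic, x$config$tail))
  ns <- sum(x$clusters$significant)
  cat(sprintf("  clusters     : %d significant of %d candidate(s) at alpha %g\n",
              ns, nrow(x$clusters), x$config$alpha))
  invisible(x)
}

#' Summarize a fitted VLSM map
#'
#' @param object a [vlsm()] fit.
#' @param all report all candidate clusters (default) or significant only.
#' @param ... unused.
#' @return The cluster table, invisibly, after printing.
#' @export
summary.vlsm <- function(object, all = TRUE, ...) {
  print(object)
  tab <- object$clusters
  if (!all) tab <- tab[tab$significant, , drop = FALSE]
  if (nrow(tab)) {
    cat(sprintf("\nCluster-forming |t| > %.3f (voxel p < %g two-sided):\n",
                object$t_threshold, object$config$cluster_forming_p))
    print(cbind(tab[, c("cluster", "direction", "hemisphere", "size")],
                round(tab[, c("peak_t", "x", "y", "z")], 2),
                p = signif(tab$p, 3), significant = tab$significant),
          row.names = FALSE)
  } else cat("\nNo supra-threshold clusters.\n")
  invisible(tab)
}

#' @export
coef.vlsm <- function(object, ...) object$beta

#' @export
residuals.vlsm <- function(object, ...) {
  if (!is.null(object$residuals_covariates)) object$residuals_covariates
  else qr.resid(qr(object$X), object$y)
}

#' Simulate outcome vectors from the fitted covariate-only null model
#'
#' Draws `nsim` outcome vectors from the covariate model with no voxel
#' effect: fitted covariate means plus Gaussian noise at the residual
#' standard deviation. Useful for parametric null checks of the
#' permutation machinery.
#'
#' @param object a [vlsm()] fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of length `object$n`.
#' @export
simulate.vlsm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr(object$X)
  mu <- qr.fitted(Q, object$y)
  sigma <- sqrt(sum(qr.resid(Q, object$y)^2) / (object$n - ncol(object$X)))
  out <- as.data.frame(mu + matrix(stats::rnorm(object$n * nsim, 0, sigma),
                                   object$n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot an axial slice of the t map
#'
#' @param x a [vlsm()] fit.
#' @param z_mm mm height of the axial slice; default the slice holding the
#'   peak |t| voxel.
#' @param ... passed to [graphics::image()].
#' @export
plot.vlsm <- function(x, z_mm = NULL, ...) {
  tm <- x$tmap
  if (all(is.na(tm))) stop("empty map: nothing to plot", call. = FALSE)
  if (is.null(z_mm)) {
    pk <- arrayInd(which.max(abs(tm)), dim(tm))
    zi <- pk[3]
  } else {
    zi <- mm_to_voxel(x$grid, c(0, x$grid$origin_mm[2], z_mm))[3]
  }
  xs <- grid_axis(x$grid, 1); ys <- grid_axis(x$grid, 2)
  sl <- tm[, , zi]
  rng <- max(abs(sl), na.rm = TRUE)
  graphics::image(xs, ys, sl, zlim = c(-rng, rng),
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("group t, axial slice z = %g mm",
                                 grid_axis(x$grid, 3)[zi]), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
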