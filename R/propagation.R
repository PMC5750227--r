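#' Connectivity-weighted disease exposure
#'
#' The core statistic of the network-spread model. For every cortical parcel
#' i, exposure(i) = sum over reservoir parcels j of Conn_ij * Atrophy(j):
#' the atrophy burden of the subcortical disease reservoir, weighted by the
#' connectivity of each cortical parcel to it. The reservoir always spans
#' both hemispheres; hemispheric restriction applies only to the cortical
#' scope of downstream association tests.
#'
#' @param conn a functional or structural [connectome] covering all parcels
#'   (passing a distance connectome is an error; use [distance_exposure]).
#' @param atrophy an [atrophy_map]; parcels with nonzero `z` form the
#'   default reservoir.
#' @param reservoir optional integer vector of parcel_ids restricting the
#'   reservoir (see [subset_reservoir] for named subsets).
#' @param atlas optional [parcel_atlas] supplying hemisphere/tissue columns
#'   when the atrophy map lacks them.
#' @return An `exposure_vector`: data.frame `parcel_id`, `hemisphere`,
#'   `exposure` over cortical parcels, with the modality and reservoir as
#'   attributes.
#' @export
disease_exposure <- function(conn, atrophy, reservoir = NULL, atlas = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(atrophy, "atrophy_map"))
  if (conn$modality == "distance")
    stop("distance connectome passed to disease_exposure(); ",
         "use distance_exposure() for the geometric comparator")
  exposure_core(conn, atrophy, reservoir, atlas)
}

#' Distance-weighted exposure comparator
#'
#' The geometric null model: the same weighted sum as [disease_exposure] but
#' with the Euclidean distance matrix in place of connectivity. Under a
#' propagation mechanism the hypothesized association with thinning is
#' negative (parcels *nearer* the reservoir thin more).
#'
#' @inheritParams disease_exposure
#' @param conn a distance [connectome].
#' @return An `exposure_vector` with modality "distance".
#' @export
distance_exposure <- function(conn, atrophy, reservoir = NULL, atlas = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(atrophy, "atrophy_map"))
  if (conn$modality != "distance")
    stop("distance_exposure() requires a distance connectome")
  exposure_core(conn, atrophy, reservoir, atlas)
}

exposure_core <- function(conn, atrophy, reservoir, atlas) {
  info <- if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "parcel_atlas"))
    atlas[, c("parcel_id", "hemisphere", "tissue")]
  } else {
    if (is.null(atrophy$hemisphere) || all(is.na(atrophy$tissue)))
      stop("need tissue/hemisphere info: supply `atlas` or an atrophy map ",
           "with tissue and hemisphere columns")
    atrophy[, c("parcel_id", "hemisphere", "tissue")]
  }
  if (is.null(reservoir)) reservoir <- atrophy$parcel_id[atrophy$z != 0]
  if (!all(reservoir %in% conn$parcel_ids))
    stop("connectome does not cover reservoir parcel(s): ",
         paste(setdiff(reservoir, conn$parcel_ids), collapse = ", "))
  ctx <- info$parcel_id[info$tissue == "cortical"]
  if (!all(ctx %in% conn$parcel_ids))
    stop("connectome does not cover all cortical parcels")
  z <- atrophy$z[match(reservoir, atrophy$parcel_id)]
  W <- conn$weights[match(ctx, conn$parcel_ids),
                    match(reservoir, conn$parcel_ids), drop = FALSE]
  out <- data.frame(parcel_id = ctx,
                    hemisphere = info$hemisphere[match(ctx, info$parcel_id)],
                    exposure = as.vector(W %*% z))
  structure(out, class = c("exposure_vector", "data.frame"),
            modality = conn$modality, reservoir = reservoir)
}

#' Restrict the atrophy reservoir to a named subset
#'
#' Zeroes atrophy outside the subset and recomputes the reservoir. The
#' "basal_ganglia" subset keeps caudate, putamen, pallidum and accumbens
#' bilaterally (by the atrophy map's `structure` labels).
#'
#' @param atrophy an [atrophy_map].
#' @param subset "all", "basal_ganglia", or an integer vector of parcel_ids.
#' @return An [atrophy_map] with the restricted reservoir.
#' @export
subset_reservoir <- function(atrophy, subset = "all") {
  stopifnot(inherits(atrophy, "atrophy_map"))
  if (identical(subset, "all")) return(atrophy)
  keep <- if (identical(subset, "basal_ganglia")) {
    atrophy$parcel_id[!is.na(atrophy$structure) &
                        atrophy$structure %in% BASAL_GANGLIA]
  } else if (is.numeric(subset)) {
    as.integer(subset)
  } else stop("subset must be 'all', 'basal_ganglia', or parcel_ids")
  out <- atrophy
  out$z[!out$parcel_id %in% keep] <- 0
  if (all(out$z == 0))
    stop("reservoir subset leaves no parcel with nonzero atrophy")
  out
}

scope_filter <- function(df, scope) {
  scope <- match.arg(scope, c("whole", "left", "right"))
  if (scope == "whole") df
  else df[df$hemisphere == c(left = "L", right = "R")[scope], , drop = FALSE]
}

#' Spearman association of cortical thinning with disease exposure
#'
#' Spearman rank correlation (average ranks for ties) between per-parcel
#' thinning and exposure, over the cortical parcels in scope. Significance
#' comes from a permutation test that keeps the connectivity structure (and
#' hence the exposure) intact and permutes the thinning values across parcels
#' within scope; the 95% confidence interval is a percentile bootstrap
#' resampling parcels with replacement. p-values use the add-one estimator
#' (k + 1) / (n_perm + 1).
#'
#' @param exposure an `exposure_vector` (see [disease_exposure]).
#' @param thinning numeric vector of per-parcel thinning values, either named
#'   by parcel_id or aligned with `exposure$parcel_id`. Parcels with missing
#'   thinning are dropped.
#' @param scope "whole", "left" or "right" cortical scope.
#' @param n_perm,n_boot permutation and bootstrap draw counts.
#' @param seed integer seed for both resampling schemes.
#' @param alternative "two.sided" (default), "greater" or "less" for the
#'   permutation test direction.
#' @return An `association_result` with fields `rho`, `p_perm`, `ci`,
#'   `n_perm`, `n_boot`, `seed`, `scope`, `n`, `modality`, `alternative`.
#' @export
associate <- function(exposure, thinning, scope = "whole", n_perm = 10000,
                      n_boot = 10000, seed = 1,
                      alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(exposure, "exposure_vector"))
  alternative <- match.arg(alternative)
  stop_if_not_scalar_count(n_perm, "n_perm")
  stop_if_not_scalar_count(n_boot, "n_boot")
  if (!is.null(names(thinning))) {
    thinning <- thinning[as.character(exposure$parcel_id)]
  } else if (length(thinning) != nrow(exposure)) {
    stop("thinning must be named by parcel_id or aligned with exposure")
  }
  df <- data.frame(parcel_id = exposure$parcel_id,
                   hemisphere = exposure$hemisphere,
                   x = exposure$exposure, y = as.numeric(thinning))
  df <- scope_filter(df, scope)
  df <- df[is.finite(df$y), , drop = FALSE]
  n <- nrow(df)
  if (n < 5) stop("fewer than 5 parcels in scope")
  if (stats::sd(df$x) == 0 || stats::sd(df$y) == 0)
    stop("zero-variance input (constant exposure or thinning)")
  rx <- rank(df$x); ry <- rank(df$y)
  rho <- stats::cor(rx, ry)  # Spearman = Pearson on average ranks
  with_seed(seed, {
    ## permutation: permute thinning ranks over parcels in scope
    rxc <- rx - mean(rx)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    R <- matrix(0, n, n_perm)
    for (k in seq_len(n_perm)) R[, k] <- sample(ry)
    rho_null <- as.vector(crossprod(rxc, R - mean(ry))) / denom
    exceed <- switch(alternative,
                     two.sided = sum(abs(rho_null) >= abs(rho)),
                     greater = sum(rho_null >= rho),
                     less = sum(rho_null <= rho))
    p_perm <- perm_pvalue(exceed, n_perm)
    ## percentile bootstrap over parcels
    rho_boot <- vapply(seq_len(n_boot), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(df$x[idx]) == 0 || stats::sd(df$y[idx]) == 0)
        return(NA_real_)
      stats::cor(df$x[idx], df$y[idx], method = "spearman")
    }, numeric(1))
    ci <- unname(stats::quantile(rho_boot, c(0.025, 0.975), na.rm = TRUE))
  })
  structure(list(rho = rho, p_perm = p_perm, ci = ci, n_perm = n_perm,
                 n_boot = n_boot, seed = seed, scope = scope, n = n,
                 modality = attr(exposure, "modality"),
                 reservoir = attr(exposure, "reservoir"),
                 alternative = alternative),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "association (%s, scope %s, n = %d): rho = %.3f, 95%% CI [%.3f, %.3f], p_perm = %.4g (%s, n_perm = %d)\n",
    x$modality, x$scope, x$n, x$rho, x$ci[1], x$ci[2], x$p_perm,
    x$alternative, x$n_perm))
  invisible(x)
}

#' Association of thinning with the distance comparator
#'
#' Computes the distance-weighted exposure ([distance_exposure]) and runs the
#' same Spearman/permutation/bootstrap machinery as [associate]. The
#' hypothesized direction is negative (smaller weighted distance to the
#' reservoir means more thinning), so directional tests should use
#' `alternative = "less"`; the default remains two-sided.
#'
#' @param distance a distance [connectome].
#' @param atrophy an [atrophy_map].
#' @param thinning per-parcel thinning values (see [associate]).
#' @param atlas optional [parcel_atlas] (see [disease_exposure]).
#' @inheritParams associate
#' @return An `association_result`.
#' @export
associate_distance <- function(distance, atrophy, thinning, scope = "whole",
                               n_perm = 10000, n_boot = 10000, seed = 1,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               atlas = NULL) {
  ex <- distance_exposure(distance, atrophy, atlas = atlas)
  associate(ex, thinning, scope = scope, n_perm = n_perm, n_boot = n_boot,
            seed = seed, alternative = match.arg(alternative))
}

#' Multivariate functional + structural exposure model
#'
#' OLS of per-parcel thinning on the functional and structural exposures
#' plus an intercept, assessing the relative contribution of the two
#' connectivity modalities to the spatial pattern of thinning.
#'
#' @param thinning per-parcel thinning (named by parcel_id or aligned).
#' @param exposure_func,exposure_struct `exposure_vector`s over the same
#'   parcels.
#' @param scope "whole", "left" or "right".
#' @param standardize if TRUE, z-score predictors before fitting.
#' @param cor_limit absolute predictor correlation above which the fit
#'   aborts with a collinearity error.
#' @return A `multivariate_fit`: data.frame of per-term `beta`, `se`, `t`,
#'   `p`, plus `df`, `r2`, `n`, `scope` attributes.
#' @export
multivariate_fit <- function(thinning, exposure_func, exposure_struct,
                             scope = "whole", standardize = FALSE,
                             cor_limit = 0.99) {
  stopifnot(inherits(exposure_func, "exposure_vector"),
            inherits(exposure_struct, "exposure_vector"))
  if (!identical(exposure_func$parcel_id, exposure_struct$parcel_id))
    stop("exposure vectors cover different parcels")
  if (!is.null(names(thinning)))
    thinning <- thinning[as.character(exposure_func$parcel_id)]
  df <- data.frame(parcel_id = exposure_func$parcel_id,
                   hemisphere = exposure_func$hemisphere,
                   y = as.numeric(thinning),
                   functional = exposure_func$exposure,
                   structural = exposure_struct$exposure)
  df <- scope_filter(df, scope)
  df <- df[is.finite(df$y), , drop = FALSE]
  if (nrow(df) < 5) stop("fewer than 5 parcels in scope")
  r_pred <- stats::cor(df$functional, df$structural)
  if (abs(r_pred) > cor_limit)
    stop(sprintf(paste0("functional and structural exposures are collinear",
                        " (|r| = %.3f); run single-predictor models"),
                 abs(r_pred)))
  if (standardize) {
    df$functional <- as.vector(scale(df$functional))
    df$structural <- as.vector(scale(df$structural))
  }
  fit <- stats::lm(y ~ functional + structural, data = df)
  s <- summary(fit)
  coefs <- data.frame(term = rownames(s$coefficients),
                      beta = s$coefficients[, 1], se = s$coefficients[, 2],
                      t = s$coefficients[, 3], p = s$coefficients[, 4],
                      row.names = NULL)
  structure(list(coefficients = coefs, df = fit$df.residual,
                 r2 = s$r.squared, n = nrow(df), scope = scope),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf("multivariate exposure model (scope %s, n = %d, df = %d, r2 = %.3f)\n",
              x$scope, x$n, x$df, x$r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}
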