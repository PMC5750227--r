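#' Longitudinal group-by-time thinning contrast
#'
#' Per-vertex ordinary least squares of the thickness change
#' delta-t = t1 - t2 (positive = thinning) on a PD-group indicator plus
#' covariates, i.e. the (PD1-PD2) - (HC1-HC2) contrast. Returns the group
#' coefficient's t-statistic with the convention positive = more thinning in
#' PD.
#'
#' @param panel a `thickness_panel` (see [gen_thickness]).
#' @param covariates character vector of covariate names among
#'   `site`, `age`, `sex` (site enters as a factor). Default `"site"`.
#' @return A `thinning_map`: data.frame `vertex_id`, `t`, `effect` (mm),
#'   with residual `df` and the covariate list as attributes.
#' @export
longitudinal_contrast <- function(panel, covariates = "site") {
  stopifnot(inherits(panel, "thickness_panel"))
  subj <- panel$subjects
  if (length(setdiff(covariates, names(subj))))
    stop("covariates not in panel: ",
         paste(setdiff(covariates, names(subj)), collapse = ", "))
  if (min(table(subj$group)) < 2)
    stop("need at least 2 subjects per group")
  X <- contrast_design(subj, covariates)
  D <- panel$t1 - panel$t2
  res <- contrast_t(D, X)
  structure(data.frame(vertex_id = panel$vertex_ids, t = res$t,
                       effect = res$beta),
            class = c("thinning_map", "data.frame"),
            df = res$df, covariates = covariates)
}

# Design matrix: intercept, PD indicator first, then covariates.
contrast_design <- function(subj, covariates) {
  df <- data.frame(group_pd = as.integer(subj$group == "PD"))
  for (cv in covariates) {
    if (cv == "site") {
      f <- factor(subj$site)
      if (nlevels(f) < 2) next  # single site: absorbed by the intercept
      df[[cv]] <- f
    } else df[[cv]] <- subj[[cv]]
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  X
}

# Vectorized per-vertex OLS t for the group_pd coefficient (column 2).
contrast_t <- function(D, X) {
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, D)
  beta <- fit$coefficients["group_pd", ]
  resid <- D - X %*% fit$coefficients
  sigma2 <- colSums(resid^2) / (n - p)
  # zero residual variance (up to FP noise relative to the data scale)
  # means a perfectly fit vertex: t is 0 for a null effect, +/-Inf otherwise
  scale2 <- colMeans(D^2)
  zero_var <- sigma2 <= 1e-20 + 1e-16 * scale2
  xtx_inv_g <- chol2inv(chol(crossprod(X)))[2, 2]
  se <- sqrt(xtx_inv_g * sigma2)
  t <- beta / se
  null_beta <- abs(beta) <= 1e-8 * sqrt(scale2 + 1e-12)
  t[zero_var] <- ifelse(null_beta[zero_var], 0,
                        sign(beta[zero_var]) * Inf)
  list(t = unname(t), beta = unname(beta), df = n - p)
}

#' Extract supra-threshold clusters on the surface
#'
#' Connected components (via the surface adjacency) of vertices whose
#' thinning t-statistic meets the cluster-forming threshold.
#'
#' @param map a `thinning_map`.
#' @param surface the [vertex_surface] the map lives on.
#' @param t_threshold positive cluster-forming threshold on t.
#' @return A `cluster_table`: data.frame `cluster_id`, `nverts`,
#'   `peak_vertex`, `peak_t`, `p` (NA until corrected), ordered by
#'   decreasing size, with the member vertex ids in `attr(, "members")`.
#' @export
find_clusters <- function(map, surface, t_threshold) {
  stopifnot(inherits(map, "thinning_map"), inherits(surface, "vertex_surface"))
  if (t_threshold <= 0) stop("t_threshold must be positive")
  comp <- threshold_components(map$t, map$vertex_id, surface$edges,
                               t_threshold)
  cluster_table(comp, map)
}

# Union-find connected components over the supra-threshold subgraph.
# Returns a list of integer vectors of vertex_ids (possibly empty).
threshold_components <- function(t, vertex_id, edges, thr) {
  keep <- which(t >= thr)
  if (length(keep) == 0) return(list())
  pos <- integer(max(vertex_id))
  pos[vertex_id[keep]] <- seq_along(keep)
  e1 <- pos[edges$v1]; e2 <- pos[edges$v2]
  ok <- edges$v1 <= length(pos) & edges$v2 <= length(pos) & e1 > 0 & e2 > 0
  parent <- seq_along(keep)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in which(ok)) {
    a <- find(e1[k]); b <- find(e2[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(keep), find, integer(1))
  unname(split(vertex_id[keep], roots))
}

cluster_table <- function(members, map) {
  if (length(members) == 0) {
    out <- data.frame(cluster_id = integer(), nverts = integer(),
                      peak_vertex = integer(), peak_t = numeric(),
                      p = numeric())
    return(structure(out, class = c("cluster_table", "data.frame"),
                     members = list()))
  }
  sizes <- lengths(members)
  ord <- order(sizes, decreasing = TRUE)
  members <- members[ord]
  tv <- stats::setNames(map$t, map$vertex_id)
  peaks <- vapply(members, function(v) v[which.max(tv[as.character(v)])],
                  numeric(1))
  out <- data.frame(cluster_id = seq_along(members),
                    nverts = lengths(members),
                    peak_vertex = as.integer(peaks),
                    peak_t = vapply(members, function(v)
                      max(tv[as.character(v)]), numeric(1)),
                    p = NA_real_)
  structure(out, class = c("cluster_table", "data.frame"), members = members)
}

#' Permutation cluster-extent correction
#'
#' Familywise-corrected cluster p-values by permuting group labels within
#' acquisition-site strata: the null distribution of the maximum
#' supra-threshold cluster size is built over `n_perm` relabelings and each
#' observed cluster gets p = (1 + #\{null max >= observed size\}) /
#' (n_perm + 1). Sites containing only one group are excluded from
#' relabeling with a warning.
#'
#' @inheritParams longitudinal_contrast
#' @param surface the [vertex_surface].
#' @param t_threshold cluster-forming threshold on t.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return A `cluster_table` with the permutation `p` column filled and the
#'   null maximum sizes in `attr(, "null_max")`.
#' @export
cluster_correction_permutation <- function(panel, surface,
                                           covariates = "site",
                                           t_threshold = 3, n_perm = 1000,
                                           seed = 1) {
  stopifnot(inherits(panel, "thickness_panel"))
  stop_if_not_scalar_count(n_perm, "n_perm")
  subj <- panel$subjects
  X <- contrast_design(subj, covariates)
  D <- panel$t1 - panel$t2
  obs_map <- longitudinal_contrast(panel, covariates)
  obs <- find_clusters(obs_map, surface, t_threshold)
  strata <- split(seq_len(nrow(subj)), subj$site)
  fixed <- vapply(strata, function(i) length(unique(subj$group[i])) < 2,
                  logical(1))
  if (any(fixed)) {
    warning("site stratum/strata with a single group excluded from ",
            "permutation: ", paste(names(strata)[fixed], collapse = ", "))
    strata <- strata[!fixed]
  }
  g <- as.integer(subj$group == "PD")
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    gp <- g
    for (s in strata) gp[s] <- g[sample(s)]
    Xp <- X
    Xp[, "group_pd"] <- gp
    tt <- contrast_t(D, Xp)$t
    comp <- threshold_components(tt, panel$vertex_ids, surface$edges,
                                 t_threshold)
    if (length(comp)) max(lengths(comp)) else 0L
  }, numeric(1)))
  if (nrow(obs) > 0)
    obs$p <- vapply(obs$nverts, function(sz)
      perm_pvalue(sum(null_max >= sz), n_perm), numeric(1))
  attr(obs, "null_max") <- null_max
  obs
}

#' Whole-brain mean thickness change within a group
#'
#' Subject-level whole-brain mean thickness at each timepoint and the paired
#' t-test across subjects. A zero-variance difference is flagged as
#' degenerate rather than reported as an infinite t.
#'
#' @param panel a `thickness_panel`.
#' @param group "PD" or "HC".
#' @return list `mean_t1`, `mean_t2` (mm), `t`, `df`, `p`, `n`,
#'   `degenerate`.
#' @export
whole_brain_change <- function(panel, group) {
  stopifnot(inherits(panel, "thickness_panel"))
  idx <- which(panel$subjects$group == group)
  if (length(idx) < 2) stop("fewer than 2 subjects in group ", group)
  m1 <- rowMeans(panel$t1[idx, , drop = FALSE])
  m2 <- rowMeans(panel$t2[idx, , drop = FALSE])
  d <- m1 - m2
  n <- length(d)
  if (stats::sd(d) == 0) {
    # zero-variance change: t is 0/0 when there is no change at all,
    # otherwise unbounded; both are flagged rather than reported as +/-Inf
    no_change <- isTRUE(all.equal(mean(d), 0))
    return(list(mean_t1 = mean(m1), mean_t2 = mean(m2),
                t = if (no_change) 0 else NA_real_,
                df = n - 1, p = if (no_change) 1 else NA_real_, n = n,
                degenerate = !no_change))
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(mean_t1 = mean(m1), mean_t2 = mean(m2), t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), n - 1), n = n, degenerate = FALSE)
}

#' Intrinsic-network summaries of a thinning map
#'
#' Mean vertex t-statistic within each of the seven intrinsic networks, with
#' a permutation p (shuffling network labels over vertices; one-sided for
#' greater-than-chance thinning) and a percentile bootstrap 95% CI over
#' vertices. Networks without vertices get NA rows.
#'
#' @param map a `thinning_map`.
#' @param atlas a [parcel_atlas] with networks assigned.
#' @param vertex_map vertex-to-parcel map (see [map_vertices_to_parcels]).
#' @param n_perm,n_boot resampling draw counts.
#' @param seed integer RNG seed.
#' @return data.frame `network`, `mu`, `ci_low`, `ci_high`, `p_perm`,
#'   `n_vertices`, `n_perm`.
#' @export
network_summary <- function(map, atlas, vertex_map, n_perm = 10000,
                            n_boot = 10000, seed = 1) {
  stopifnot(inherits(map, "thinning_map"), inherits(atlas, "parcel_atlas"))
  if (all(is.na(atlas$network))) stop("atlas has no network labels")
  stop_if_not_scalar_count(n_perm, "n_perm")
  pid <- vertex_map$parcel_id[match(map$vertex_id, vertex_map$vertex_id)]
  lab <- atlas$network[match(pid, atlas$parcel_id)]
  keep <- !is.na(lab)
  t <- map$t[keep]
  lab <- factor(lab[keep], levels = NETWORKS_7)
  lab <- droplevels(lab)
  present <- levels(lab)
  counts_p <- as.vector(table(lab))
  mu_p_obs <- as.vector(tapply(t, lab, mean))
  with_seed(seed, {
    exceed <- numeric(length(present))
    for (k in seq_len(n_perm)) {
      mu_k <- rowsum(t[sample(length(t))], lab) / counts_p
      exceed <- exceed + (mu_k[present, 1] >= mu_p_obs - 1e-12)
    }
    p_present <- perm_pvalue(exceed, n_perm)
    ci_p <- t(vapply(present, function(nw) {
      tv <- t[lab == nw]
      bm <- vapply(seq_len(n_boot), function(k)
        mean(tv[sample.int(length(tv), replace = TRUE)]), numeric(1))
      unname(stats::quantile(bm, c(0.025, 0.975)))
    }, numeric(2)))
  })
  out <- data.frame(network = NETWORKS_7, mu = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_perm = NA_real_, n_vertices = 0L,
                    n_perm = n_perm, row.names = NULL)
  idx <- match(present, NETWORKS_7)
  out$mu[idx] <- mu_p_obs
  out$ci_low[idx] <- ci_p[, 1]
  out$ci_high[idx] <- ci_p[, 2]
  out$p_perm[idx] <- p_present
  out$n_vertices[idx] <- counts_p
  out
}
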