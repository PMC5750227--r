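#' Synthetic-study configuration
#'
#' Bundles every tunable of the synthetic data generators. Defaults emulate
#' the cohort and effect scale of a two-group (105 PD, 57 control),
#' two-timepoint, multi-site cortical thickness study: a 448 + 15 parcel
#' brain, mean baseline thickness 3.055 mm, aging-related thinning of
#' 0.019 mm over the follow-up interval, and a PD-specific extra thinning of
#' `b` mm (on average) proportional to network disease exposure.
#'
#' @param n_cortical number of cortical parcels (must be even; split L/R).
#' @param n_subcortical number of subcortical reservoir parcels.
#' @param vertices_per_parcel surface vertices simulated per cortical parcel.
#' @param n_pd,n_hc subjects per group.
#' @param baseline_mean mean baseline cortical thickness, mm.
#' @param aging_thinning thinning over the follow-up interval common to both
#'   groups, mm.
#' @param b spread coefficient: mean PD-specific extra thinning, mm, applied
#'   in proportion to the (mean-normalized) disease exposure of the parcel.
#' @param noise_sd vertex-level measurement noise sd, mm.
#' @param subject_sd between-subject sd of mean baseline thickness, mm.
#' @param n_sites number of acquisition sites.
#' @param site_sd sd of additive per-site offsets on the follow-up scan, mm.
#' @param interhemi_attenuation multiplier in \[0, 1\] on cross-hemisphere
#'   structural weights (tractography under-recovers interhemispheric
#'   connections).
#' @param distance_decay connectivity decay length lambda, mm.
#' @param conn_noise_sd sd of symmetric noise added to functional weights.
#' @param seed integer RNG seed; all generators are pure in (config, seed).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cortical = 448, n_subcortical = 15,
                         vertices_per_parcel = 10, n_pd = 105, n_hc = 57,
                         baseline_mean = 3.055, aging_thinning = 0.019,
                         b = 0.009, noise_sd = 0.03, subject_sd = 0.13,
                         n_sites = 3, site_sd = 0.005,
                         interhemi_attenuation = 0.2, distance_decay = 30,
                         conn_noise_sd = 0.05, seed = 1) {
  cfg <- list(n_cortical = as.integer(n_cortical),
              n_subcortical = as.integer(n_subcortical),
              vertices_per_parcel = as.integer(vertices_per_parcel),
              n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
              baseline_mean = baseline_mean,
              aging_thinning = aging_thinning, b = b, noise_sd = noise_sd,
              subject_sd = subject_sd, n_sites = as.integer(n_sites),
              site_sd = site_sd,
              interhemi_attenuation = interhemi_attenuation,
              distance_decay = distance_decay,
              conn_noise_sd = conn_noise_sd, seed = as.integer(seed))
  for (nm in c("n_cortical", "n_subcortical", "vertices_per_parcel",
               "n_pd", "n_hc", "n_sites"))
    stop_if_not_scalar_count(cfg[[nm]], nm)
  for (nm in c("noise_sd", "subject_sd", "site_sd", "conn_noise_sd"))
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (cfg$interhemi_attenuation < 0 || cfg$interhemi_attenuation > 1)
    stop("interhemi_attenuation must lie in [0, 1]")
  if (cfg$b < 0) stop("spread coefficient b must be non-negative")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic parcel atlas and vertex surface
#'
#' Two mirrored hemispheric shells of cortical parcel centroids plus a
#' medial/inferior subcortical block (bilateral structure pairs, with a
#' midline brainstem when `n_subcortical` is odd). Vertices are jittered
#' around cortical centroids with a symmetric k-nearest-neighbour adjacency
#' within hemisphere.
#'
#' @param config a [synth_config].
#' @param k_adjacency neighbours per vertex in the surface graph.
#' @return list with elements `atlas` ([parcel_atlas]) and `surface`
#'   ([vertex_surface]).
#' @export
gen_atlas <- function(config, k_adjacency = 6) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_cortical %% 2 != 0)
    stop("n_cortical must be even (hemispheric balance required)")
  with_seed(config$seed + 101L, {
    nh <- config$n_cortical / 2
    # right-hemisphere shell: unit directions folded to x > 0, radius ~65 mm
    u <- matrix(stats::rnorm(3 * nh), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 1] <- abs(u[, 1]) + 0.1
    u <- u / sqrt(rowSums(u^2))
    r <- 65 + stats::rnorm(nh, 0, 2)
    right <- u * r
    left <- right; left[, 1] <- -left[, 1]
    n_pairs <- config$n_subcortical %/% 2
    midline <- config$n_subcortical %% 2 == 1
    strs <- rep_len(SUBCORTICAL_STRUCTURES, max(n_pairs, 1))[seq_len(n_pairs)]
    sub_r <- cbind(x = 15 + stats::rnorm(n_pairs, 0, 3),
                   y = stats::runif(n_pairs, -30, 10),
                   z = stats::runif(n_pairs, -20, 0))
    sub_l <- sub_r; sub_l[, 1] <- -sub_l[, 1]
    # intrinsic-network labels: random per right-hemisphere parcel, mirrored
    nets_r <- sample(rep_len(NETWORKS_7, nh))
    parcels <- data.frame(
      parcel_id = seq_len(config$n_cortical + config$n_subcortical),
      hemisphere = c(rep("L", nh), rep("R", nh),
                     rep(c("L", "R"), each = n_pairs),
                     if (midline) "M"),
      tissue = c(rep("cortical", config$n_cortical),
                 rep("subcortical", config$n_subcortical)),
      rbind(left, right, sub_l, sub_r,
            if (midline) cbind(0, -25, -40)) |>
        as.data.frame() |> stats::setNames(c("x", "y", "z")),
      network = c(nets_r, nets_r,
                  rep(NA_character_, config$n_subcortical)),
      structure = c(rep(NA_character_, config$n_cortical),
                    rep(strs, 2), if (midline) "brainstem"))
    atlas <- parcel_atlas(parcels)
    ctx <- atlas[atlas$tissue == "cortical", ]
    vpp <- config$vertices_per_parcel
    vx <- ctx[rep(seq_len(nrow(ctx)), each = vpp), c("x", "y", "z")]
    vx <- as.matrix(vx) + matrix(stats::rnorm(3 * nrow(vx), 0, 3), ncol = 3)
    vertices <- data.frame(
      vertex_id = seq_len(nrow(vx)), x = vx[, 1], y = vx[, 2], z = vx[, 3],
      hemisphere = rep(ctx$hemisphere, each = vpp))
    edges <- knn_edges(vertices, k_adjacency)
    list(atlas = atlas,
         surface = vertex_surface(vertices, edges))
  })
}

# Symmetric within-hemisphere k-nearest-neighbour edge list.
knn_edges <- function(vertices, k) {
  out <- list()
  for (h in unique(vertices$hemisphere)) {
    idx <- which(vertices$hemisphere == h)
    p <- as.matrix(vertices[idx, c("x", "y", "z")])
    d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
    diag(d2) <- Inf
    kk <- min(k, length(idx) - 1)
    nn <- apply(d2, 1L, function(row) order(row)[seq_len(kk)])
    e <- cbind(v1 = rep(vertices$vertex_id[idx], each = kk),
               v2 = vertices$vertex_id[idx][as.vector(nn)])
    out[[h]] <- e
  }
  e <- do.call(rbind, out)
  e <- cbind(v1 = pmin(e[, 1], e[, 2]), v2 = pmax(e[, 1], e[, 2]))
  as.data.frame(unique(e))
}

#' Generate synthetic functional, structural, and distance connectomes
#'
#' Distance is the pairwise Euclidean centroid distance. Functional weights
#' decay as exp(-d / lambda) with symmetric additive noise, clipped to
#' \[-1, 1\] with unit diagonal. Structural weights are sparse, non-negative
#' and distance-decaying, with cross-hemisphere entries multiplied by
#' `interhemi_attenuation`.
#'
#' @param atlas a [parcel_atlas].
#' @param config a [synth_config].
#' @param sparsity fraction of strongest off-diagonal structural weights kept.
#' @return named list of three [connectome] objects:
#'   `functional`, `structural`, `distance`.
#' @export
gen_connectomes <- function(atlas, config, sparsity = 0.3) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(config, "synth_config"))
  if (config$distance_decay <= 0)
    stop("distance_decay (lambda) must be positive")
  dist_conn <- distance_connectome(atlas)
  D <- dist_conn$weights
  P <- nrow(D)
  with_seed(config$seed + 202L, {
    ## functional: smooth decay + symmetric noise
    Wf <- exp(-D / config$distance_decay)
    if (config$conn_noise_sd > 0) {
      N <- matrix(stats::rnorm(P * P, 0, config$conn_noise_sd), P, P)
      Wf <- Wf + (N + t(N)) / 2
    }
    Wf <- pmin(pmax(Wf, -1), 1)
    diag(Wf) <- 1
    ## structural: multiplicative lognormal noise, sparsified, attenuated
    logn <- matrix(stats::rnorm(P * P, 0, 0.5), P, P)
    Ws <- exp(-D / config$distance_decay) * exp((logn + t(logn)) / 2)
    diag(Ws) <- 0
    off <- Ws[upper.tri(Ws)]
    thr <- stats::quantile(off, 1 - sparsity)
    Ws[Ws < thr] <- 0
    hemi <- atlas$hemisphere
    cross <- outer(hemi == "L", hemi == "R") | outer(hemi == "R", hemi == "L")
    Ws[cross] <- Ws[cross] * config$interhemi_attenuation
    list(functional = connectome(Wf, "functional", atlas$parcel_id),
         structural = connectome(Ws, "structural", atlas$parcel_id),
         distance = dist_conn)
  })
}

#' Generate a synthetic reservoir atrophy map
#'
#' Positive atrophy z-values on a configurable subset of the subcortical
#' parcels (default: all of them); zero on every cortical parcel, mirroring
#' a baseline deformation-based morphometry component in which only the
#' subcortical reservoir shows significant atrophy.
#'
#' @param atlas a [parcel_atlas].
#' @param config a [synth_config].
#' @param reservoir optional integer vector of subcortical parcel_ids to
#'   receive nonzero atrophy; requesting a non-subcortical parcel is an error.
#' @param z_mean,z_sd distribution of the (positive) z-values.
#' @return An `atrophy_map`: data.frame `parcel_id`, `z`, `structure`,
#'   `tissue` over all parcels.
#' @export
gen_atrophy <- function(atlas, config, reservoir = NULL, z_mean = 3,
                        z_sd = 0.8) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(config, "synth_config"))
  sub_ids <- atlas$parcel_id[atlas$tissue == "subcortical"]
  if (length(sub_ids) == 0) stop("atlas has no subcortical parcels")
  if (is.null(reservoir)) reservoir <- sub_ids
  bad <- setdiff(reservoir, sub_ids)
  if (length(bad))
    stop("requested reservoir parcel(s) not subcortical: ",
         paste(bad, collapse = ", "))
  z <- numeric(nrow(atlas))
  with_seed(config$seed + 303L, {
    z[match(reservoir, atlas$parcel_id)] <-
      abs(stats::rnorm(length(reservoir), z_mean, z_sd)) + 0.1
  })
  atrophy_map(data.frame(parcel_id = atlas$parcel_id, z = z,
                         structure = atlas$structure,
                         tissue = atlas$tissue,
                         hemisphere = atlas$hemisphere))
}

#' Construct and validate an atrophy map
#'
#' @param df data.frame with `parcel_id`, `z` and (for reservoir subsetting)
#'   `structure`, `tissue`. Nonzero z is only allowed on subcortical parcels.
#' @return An `atrophy_map` data.frame; parcels with nonzero z form the
#'   disease reservoir.
#' @export
atrophy_map <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("parcel_id", "z") %in% names(df)))
    stop("atrophy map needs columns parcel_id, z")
  if (!all(is.finite(df$z))) stop("atrophy z-values must be finite")
  if (is.null(df$tissue)) df$tissue <- NA_character_
  if (is.null(df$structure)) df$structure <- NA_character_
  nz <- df$z != 0
  if (any(nz & !is.na(df$tissue) & df$tissue != "subcortical"))
    stop("nonzero atrophy on non-subcortical parcel(s): ",
         paste(df$parcel_id[nz & df$tissue != "subcortical"], collapse = ", "))
  class(df) <- c("atrophy_map", "data.frame")
  df
}

#' Generate a synthetic longitudinal thickness panel
#'
#' Baseline vertex thickness is normal around `baseline_mean` with a
#' between-subject component; follow-up subtracts the common aging effect, an
#' additive site offset, and (PD group only) `b` times the mean-normalized
#' disease exposure of the vertex's parcel, plus vertex-level measurement
#' noise. Thickness is floored at 0.5 mm.
#'
#' When `conn` has distance modality the injected spatial pattern is
#' *decreasing* in the distance-weighted exposure (parcels nearer the
#' reservoir thin more), emulating a purely geometric spread mechanism.
#'
#' @param atlas,surface,map atlas, surface, and vertex-to-parcel map.
#' @param conn [connectome] driving the spatial pattern of PD thinning.
#' @param atrophy an `atrophy_map` (see [gen_atrophy]).
#' @param config a [synth_config]; `config$b` must be non-negative.
#' @return A `thickness_panel`: list with `subjects` (data.frame
#'   `subject_id`, `group`, `site`, `age`, `sex`), matrices `t1`, `t2`
#'   (subjects x vertices, mm), and `vertex_ids`. The normalized per-parcel
#'   exposure actually injected is stored in `attr(, "exposure")`.
#' @export
gen_thickness <- function(atlas, surface, map, conn, atrophy, config) {
  stopifnot(inherits(config, "synth_config"), inherits(conn, "connectome"))
  if (config$b < 0) stop("spread coefficient b must be non-negative")
  if (conn$modality == "distance") {
    ex <- distance_exposure(conn, atrophy)
    e <- ex$exposure
    e <- max(e) - e  # nearer reservoir (smaller weighted distance) thins more
  } else {
    ex <- disease_exposure(conn, atrophy, atlas = atlas)
    e <- ex$exposure
  }
  if (mean(e) > 0) e <- e / mean(e)  # b is mm per unit mean-normalized exposure
  names(e) <- ex$parcel_id
  v_exposure <- e[as.character(map$parcel_id)]
  n <- config$n_pd + config$n_hc
  V <- nrow(map)
  with_seed(config$seed + 404L, {
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = c(rep("PD", config$n_pd), rep("HC", config$n_hc)),
      site = rep_len(seq_len(config$n_sites), n),
      age = round(stats::rnorm(n, 61, 9.5), 1),
      sex = stats::rbinom(n, 1, 0.35))
    site_offsets <- stats::rnorm(config$n_sites, 0, config$site_sd)
    u <- stats::rnorm(n, 0, config$subject_sd)
    t1 <- config$baseline_mean + u +
      matrix(stats::rnorm(n * V, 0, config$noise_sd), n, V)
    pd_term <- (subjects$group == "PD") %o% (config$b * v_exposure)
    t2 <- t1 - config$aging_thinning - site_offsets[subjects$site] -
      pd_term + matrix(stats::rnorm(n * V, 0, config$noise_sd), n, V)
    t1 <- pmax(t1, 0.5); t2 <- pmax(t2, 0.5)
    structure(list(subjects = subjects, t1 = t1, t2 = t2,
                   vertex_ids = map$vertex_id),
              class = "thickness_panel", exposure = e)
  })
}

#' @export
print.thickness_panel <- function(x, ...) {
  cat(sprintf("thickness_panel: %d subjects (%d PD, %d HC), %d vertices\n",
              nrow(x$subjects), sum(x$subjects$group == "PD"),
              sum(x$subjects$group == "HC"), length(x$vertex_ids)))
  invisible(x)
}

#' Generate a synthetic clinical and CSF table
#'
#' Group-specific normal draws for age, MoCA (two timepoints), UPDRS-III and
#' CSF measures, with defaults near a de novo PD cohort. CSF values are
#' truncated positive. Optionally plants a linear dependence of the MoCA
#' change on supplied cluster-thinning columns, for regression recovery
#' tests.
#'
#' @param config a [synth_config] (supplies group sizes and seed).
#' @param means named list overriding any of the default group means/sds;
#'   see the function body for names.
#' @param planted optional list(`slopes` = numeric vector, `thinning` =
#'   matrix with `n_pd` rows and `length(slopes)` columns, `noise_sd`):
#'   delta-MoCA for PD subjects becomes `thinning %*% slopes` + noise.
#' @return A `clinical_table` data.frame, one row per subject.
#' @export
gen_clinical <- function(config, means = list(), planted = NULL) {
  stopifnot(inherits(config, "synth_config"))
  p <- utils::modifyList(list(
    age_pd = 61.06, age_pd_sd = 9.37, age_hc = 59.05, age_hc_sd = 10.96,
    moca_pd = 27.49, moca_pd_sd = 2.11, moca_hc = 28.30, moca_hc_sd = 1.13,
    moca_decline_pd = 0.8, moca_decline_hc = 0.1, moca_t2_sd = 1.5,
    updrs_pd = 21.67, updrs_pd_sd = 9.61, updrs_gain_pd = 1.4,
    asyn = 1870, asyn_sd = 740, abeta42 = 371, abeta42_sd = 95,
    ttau = 45.4, ttau_sd = 19, ptau181 = 16.4, ptau181_sd = 9.8), means)
  n <- config$n_pd + config$n_hc
  grp <- c(rep("PD", config$n_pd), rep("HC", config$n_hc))
  with_seed(config$seed + 505L, {
    pd <- grp == "PD"
    age <- ifelse(pd, stats::rnorm(n, p$age_pd, p$age_pd_sd),
                  stats::rnorm(n, p$age_hc, p$age_hc_sd))
    moca1 <- ifelse(pd, stats::rnorm(n, p$moca_pd, p$moca_pd_sd),
                    stats::rnorm(n, p$moca_hc, p$moca_hc_sd))
    decline <- ifelse(pd, p$moca_decline_pd, p$moca_decline_hc)
    if (!is.null(planted)) {
      stopifnot(nrow(planted$thinning) == config$n_pd)
      delta <- as.vector(planted$thinning %*% planted$slopes) +
        stats::rnorm(config$n_pd, 0, planted$noise_sd)
      moca2 <- moca1
      moca2[pd] <- moca1[pd] - delta
      moca2[!pd] <- moca1[!pd] - p$moca_decline_hc +
        stats::rnorm(sum(!pd), 0, p$moca_t2_sd)
    } else {
      moca2 <- moca1 - decline + stats::rnorm(n, 0, p$moca_t2_sd)
    }
    updrs1 <- ifelse(pd, stats::rnorm(n, p$updrs_pd, p$updrs_pd_sd), NA)
    updrs2 <- updrs1 + ifelse(pd, p$updrs_gain_pd +
                                stats::rnorm(n, 0, 4), NA)
    csf <- function(m, s) pmax(stats::rnorm(n, m, s), 1)
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)), group = grp,
      site = rep_len(seq_len(config$n_sites), n),
      age = age, sex = stats::rbinom(n, 1, 0.35),
      moca_t1 = moca1, moca_t2 = moca2,
      updrs_t1 = updrs1, updrs_t2 = updrs2,
      asyn = csf(p$asyn, p$asyn_sd), abeta42 = csf(p$abeta42, p$abeta42_sd),
      ttau = csf(p$ttau, p$ttau_sd), ptau181 = csf(p$ptau181, p$ptau181_sd))
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [gen_atlas], [gen_connectomes], [gen_atrophy],
#' [map_vertices_to_parcels], [gen_thickness] (driven by the functional
#' connectome) and [gen_clinical] in sequence.
#'
#' @param config a [synth_config].
#' @return list with `atlas`, `surface`, `map`, `connectomes`, `atrophy`,
#'   `panel`, `clinical`, `config`.
#' @export
gen_dataset <- function(config) {
  as_ <- gen_atlas(config)
  conns <- gen_connectomes(as_$atlas, config)
  atr <- gen_atrophy(as_$atlas, config)
  vmap <- map_vertices_to_parcels(as_$surface, as_$atlas)
  panel <- gen_thickness(as_$atlas, as_$surface, vmap, conns$functional,
                         atr, config)
  list(atlas = as_$atlas, surface = as_$surface, map = vmap,
       connectomes = conns, atrophy = atr, panel = panel,
       clinical = gen_clinical(config), config = config)
}
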