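# Shared fixtures for the test suite; everything is generated in code.

# Reduced desk-scale configuration: 40 + 6 parcel atlas, small surface.
small_config <- function(seed = 1, ...) {
  defaults <- list(n_cortical = 40, n_subcortical = 6,
                   vertices_per_parcel = 3, n_pd = 20, n_hc = 20,
                   n_sites = 2, seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# A tiny hand-built atlas: nc cortical parcels per hemisphere on two
# shells, ns subcortical pairs near the midline.
tiny_atlas <- function(nc = 3, ns = 1) {
  ctx <- data.frame(
    parcel_id = seq_len(2 * nc),
    hemisphere = rep(c("L", "R"), each = nc),
    tissue = "cortical",
    x = rep(c(-50, 50), each = nc),
    y = rep(seq(-40, 40, length.out = nc), 2),
    z = 10)
  sub <- data.frame(
    parcel_id = 2 * nc + seq_len(2 * ns),
    hemisphere = rep(c("L", "R"), each = ns),
    tissue = "subcortical",
    x = rep(c(-10, 10), each = ns),
    y = rep(seq(-15, 5, length.out = ns), 2),
    z = -10)
  sub$structure <- rep(rep_len(c("putamen", "caudate", "thalamus"), ns), 2)
  ctx$structure <- NA_character_
  parcel_atlas(rbind(ctx, sub))
}

# Uniform atrophy on all subcortical parcels of an atlas.
uniform_atrophy <- function(atlas, z = 1) {
  atrophy_map(data.frame(parcel_id = atlas$parcel_id,
                         z = ifelse(atlas$tissue == "subcortical", z, 0),
                         structure = atlas$structure,
                         tissue = atlas$tissue,
                         hemisphere = atlas$hemisphere))
}

# Bare exposure_vector for association tests that need iid pairs.
as_exposure <- function(x, hemisphere = "L", modality = "functional") {
  structure(data.frame(parcel_id = seq_along(x), hemisphere = hemisphere,
                       exposure = x),
            class = c("exposure_vector", "data.frame"),
            modality = modality, reservoir = integer())
}

# Build a thickness_panel directly from a matrix of changes: t1 constant,
# t2 = t1 - delta.
panel_from_delta <- function(delta, group, site = rep(1, nrow(delta)),
                             age = rep(60, nrow(delta)),
                             sex = rep(0, nrow(delta)), baseline = 3) {
  n <- nrow(delta)
  structure(list(
    subjects = data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                          group = group, site = site, age = age, sex = sex),
    t1 = matrix(baseline, n, ncol(delta)),
    t2 = baseline - delta,
    vertex_ids = seq_len(ncol(delta))),
    class = "thickness_panel")
}

# Chain surface: vertices 1..n in a line per hemisphere, edges between
# consecutive vertices (simple known topology for cluster tests).
chain_surface <- function(n, hemisphere = "L") {
  vertex_surface(
    data.frame(vertex_id = seq_len(n), x = seq_len(n), y = 0, z = 0,
               hemisphere = hemisphere),
    data.frame(v1 = seq_len(n - 1), v2 = 2:n))
}
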