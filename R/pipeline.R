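#' Validate a pipeline run configuration
#'
#' A run configuration is a flat list (or a YAML file with the same keys)
#' with either a `synth` block of [synth_config] arguments or an `inputs`
#' block of file paths (`atlas`, `surface_vertices`, `surface_edges`,
#' `connectome_functional`, `connectome_structural`, `atrophy`, `panel`,
#' optionally `clinical` and `vertex_map`), plus analysis settings:
#' `scopes`, `n_perm`, `n_boot`, `t_threshold`, `seed`.
#'
#' @param config list or path to a YAML file.
#' @return A validated `run_config` list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  has_synth <- !is.null(config$synth)
  has_inputs <- !is.null(config$inputs)
  if (!has_synth && !has_inputs)
    stop("config needs either a 'synth' block or an 'inputs' block")
  if (has_inputs) {
    req <- c("atlas", "surface_vertices", "surface_edges",
             "connectome_functional", "connectome_structural", "atrophy",
             "panel")
    miss <- setdiff(req, names(config$inputs))
    if (length(miss))
      stop("config inputs missing field(s): ", paste(miss, collapse = ", "))
  }
  defaults <- list(scopes = c("whole", "left", "right"), n_perm = 1000,
                   n_boot = 1000, t_threshold = 3, seed = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stop("config missing field: seed")
  structure(config, class = "run_config")
}

# Rolling polynomial hash of the serialized config, for the run log.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full network-spread analysis pipeline
#'
#' Sequences the whole analysis: data generation (or loading), vertex-parcel
#' mapping, the longitudinal thinning contrast, permutation cluster
#' correction, intrinsic-network summaries, disease-exposure associations
#' (functional, structural and distance modalities; whole-brain and
#' per-hemisphere scopes; full and basal-ganglia reservoirs), the
#' multivariate functional + structural model, and clinical statistics.
#' Writes delimited reports, a JSON summary and a run log to `out_dir`.
#' Identical config + seed gives identical outputs.
#'
#' @param config a [run_config] (or list / YAML path accepted by it).
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @return list of all results (invisibly the same content as the reports).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- run_config(config)
  seed <- as.integer(config$seed)
  ## --- data ---
  if (!is.null(config$synth)) {
    scfg <- do.call(synth_config,
                    utils::modifyList(config$synth, list(seed = seed)))
    data <- gen_dataset(scfg)
  } else {
    inp <- config$inputs
    atlas <- read_atlas(inp$atlas)
    surface <- read_surface(inp$surface_vertices, inp$surface_edges)
    vmap <- if (!is.null(inp$vertex_map)) read_vertex_map(inp$vertex_map)
            else map_vertices_to_parcels(surface, atlas)
    data <- list(
      atlas = atlas, surface = surface, map = vmap,
      connectomes = list(
        functional = read_connectome(inp$connectome_functional,
                                     "functional", atlas),
        structural = read_connectome(inp$connectome_structural,
                                     "structural", atlas),
        distance = distance_connectome(atlas)),
      atrophy = read_atrophy(inp$atrophy),
      panel = read_thickness_panel(inp$panel),
      clinical = if (!is.null(inp$clinical)) read_clinical(inp$clinical))
  }
  ## --- vertex-wise contrast and clusters ---
  covars <- if (!is.null(config$covariates)) config$covariates else "site"
  tmap <- longitudinal_contrast(data$panel, covars)
  clusters <- cluster_correction_permutation(
    data$panel, data$surface, covars, config$t_threshold, config$n_perm,
    seed = seed + 1L)
  networks <- if (any(!is.na(data$atlas$network)))
    network_summary(tmap, data$atlas, data$map, config$n_perm,
                    config$n_boot, seed = seed + 2L)
  wb <- list(PD = whole_brain_change(data$panel, "PD"),
             HC = whole_brain_change(data$panel, "HC"))
  ## --- parcel thinning and exposure associations ---
  parcel_t <- aggregate_to_parcels(
    data$map, tmap$t,
    parcel_ids = data$atlas$parcel_id[data$atlas$tissue == "cortical"])
  reservoirs <- list(all = data$atrophy)
  bg <- try(subset_reservoir(data$atrophy, "basal_ganglia"), silent = TRUE)
  if (!inherits(bg, "try-error")) reservoirs$basal_ganglia <- bg
  assoc <- list()
  for (rn in names(reservoirs)) {
    atr <- reservoirs[[rn]]
    ef <- disease_exposure(data$connectomes$functional, atr,
                           atlas = data$atlas)
    es <- disease_exposure(data$connectomes$structural, atr,
                           atlas = data$atlas)
    for (sc in config$scopes) {
      assoc[[paste("functional", rn, sc, sep = ".")]] <-
        associate(ef, parcel_t, sc, config$n_perm, config$n_boot,
                  seed = seed + 3L)
      assoc[[paste("structural", rn, sc, sep = ".")]] <-
        associate(es, parcel_t, sc, config$n_perm, config$n_boot,
                  seed = seed + 4L)
      assoc[[paste("distance", rn, sc, sep = ".")]] <-
        associate_distance(data$connectomes$distance, atr, parcel_t, sc,
                           config$n_perm, config$n_boot, seed = seed + 5L,
                           atlas = data$atlas)
    }
  }
  mv <- lapply(stats::setNames(nm = intersect(config$scopes,
                                              c("left", "right"))),
               function(sc) multivariate_fit(
                 parcel_t,
                 disease_exposure(data$connectomes$functional, data$atrophy,
                                  atlas = data$atlas),
                 disease_exposure(data$connectomes$structural, data$atrophy,
                                  atlas = data$atlas),
                 scope = sc))
  ## --- clinical statistics ---
  clin <- NULL
  if (!is.null(data$clinical)) {
    clin <- list(group_table = clinical_group_table(data$clinical))
    pd <- data$clinical[data$clinical$group == "PD", ]
    if (nrow(clusters) >= 1 &&
        nrow(pd) == sum(data$panel$subjects$group == "PD")) {
      mem <- attr(clusters, "members")
      pdi <- which(data$panel$subjects$group == "PD")
      dmat <- data$panel$t1[pdi, , drop = FALSE] -
        data$panel$t2[pdi, , drop = FALSE]
      ct <- vapply(mem, function(v)
        rowMeans(dmat[, match(v, data$panel$vertex_ids), drop = FALSE]),
        numeric(length(pdi)))
      clin$moca_regression <- try(
        delta_moca_regression(pd$moca_t1 - pd$moca_t2, ct, pd$age, pd$sex),
        silent = TRUE)
      if (inherits(clin$moca_regression, "try-error"))
        clin$moca_regression <- NULL
    }
  }
  results <- list(config = unclass(config), seed = seed,
                  thinning_map = tmap, clusters = clusters,
                  networks = networks, whole_brain = wb,
                  parcel_thinning = parcel_t, associations = assoc,
                  multivariate = mv, clinical = clin)
  if (!is.null(out_dir)) write_run_report(results, out_dir)
  invisible(results)
}

# Delimited reports + JSON summary + log.
write_run_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(as.data.frame(results$thinning_map), "thinning_map.tsv")
  wt(as.data.frame(results$clusters), "clusters.tsv")
  if (!is.null(results$networks)) wt(results$networks, "networks.tsv")
  assoc_df <- do.call(rbind, lapply(names(results$associations), function(k) {
    a <- results$associations[[k]]
    data.frame(analysis = k, modality = a$modality, scope = a$scope,
               n = a$n, rho = a$rho, ci_low = a$ci[1], ci_high = a$ci[2],
               p_perm = a$p_perm, n_perm = a$n_perm, n_boot = a$n_boot)
  }))
  wt(assoc_df, "associations.tsv")
  if (!is.null(results$clinical))
    wt(results$clinical$group_table, "clinical_group_table.tsv")
  summary <- list(
    seed = results$seed,
    whole_brain = results$whole_brain,
    n_clusters = nrow(results$clusters),
    min_cluster_p = if (nrow(results$clusters)) min(results$clusters$p)
                    else NA,
    associations = lapply(results$associations, function(a)
      list(rho = a$rho, p_perm = a$p_perm, ci = a$ci)),
    multivariate = lapply(results$multivariate, function(m)
      list(r2 = m$r2, beta = stats::setNames(m$coefficients$beta,
                                             m$coefficients$term))),
    moca_r2 = if (!is.null(results$clinical$moca_regression))
      results$clinical$moca_regression$r2 else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(c(sprintf("config_hash: %s", config_hash(results$config)),
               sprintf("seed: %d", results$seed),
               sprintf("n_perm: %d", results$config$n_perm),
               sprintf("n_boot: %d", results$config$n_boot)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
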