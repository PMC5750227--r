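#' Intrinsic-network vocabulary
#'
#' The canonical seven resting-state networks used to label cortical parcels.
#' @export
NETWORKS_7 <- c("visual", "somatomotor", "dorsal_attention",
                "ventral_attention", "limbic", "frontoparietal", "default")

#' Subcortical structures of the disease reservoir
#'
#' The 15 subcortical parcels: seven bilateral structures plus brainstem.
#' @export
SUBCORTICAL_STRUCTURES <- c("thalamus", "caudate", "putamen", "pallidum",
                            "accumbens", "hippocampus", "amygdala")

#' Basal ganglia structure names
#' @export
BASAL_GANGLIA <- c("caudate", "putamen", "pallidum", "accumbens")

#' Construct and validate a parcel atlas
#'
#' A parcel atlas is the brain model: `P` parcels, each with a hemisphere,
#' tissue class, a centroid in mm, and (for cortical parcels) an optional
#' intrinsic-network label. Subcortical parcels may carry a `structure` name
#' (e.g. "putamen") used for reservoir subsetting.
#'
#' @param parcels data.frame with columns `parcel_id` (integer, unique,
#'   contiguous from 1), `hemisphere` ("L", "R" or "M"), `tissue`
#'   ("cortical" or "subcortical"), `x`, `y`, `z` (mm), and optionally
#'   `network` (one of [NETWORKS_7], cortical only) and `structure`
#'   (subcortical only).
#' @return A `parcel_atlas` (a validated data.frame).
#' @export
parcel_atlas <- function(parcels) {
  parcels <- as.data.frame(parcels)
  req <- c("parcel_id", "hemisphere", "tissue", "x", "y", "z")
  miss <- setdiff(req, names(parcels))
  if (length(miss))
    stop("atlas table missing columns: ", paste(miss, collapse = ", "))
  parcels$parcel_id <- as.integer(parcels$parcel_id)
  if (anyDuplicated(parcels$parcel_id))
    stop("parcel_ids must be unique")
  parcels <- parcels[order(parcels$parcel_id), , drop = FALSE]
  rownames(parcels) <- NULL
  if (!identical(parcels$parcel_id, seq_len(nrow(parcels))))
    stop("parcel_ids must be contiguous 1..P")
  if (!all(parcels$hemisphere %in% c("L", "R", "M")))
    stop("hemisphere must be one of L, R, M")
  if (!all(parcels$tissue %in% c("cortical", "subcortical")))
    stop("tissue must be 'cortical' or 'subcortical'")
  ctx <- parcels$tissue == "cortical"
  if (any(!parcels$hemisphere[ctx] %in% c("L", "R")))
    stop("every cortical parcel must have hemisphere L or R")
  xyz <- as.matrix(parcels[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("parcel centroids must be finite")
  if (is.null(parcels$network)) parcels$network <- NA_character_
  lab <- !is.na(parcels$network)
  if (any(lab & !ctx))
    stop("network labels are only allowed on cortical parcels")
  if (any(lab) && !all(parcels$network[lab] %in% NETWORKS_7))
    stop("unknown network label(s): ",
         paste(setdiff(parcels$network[lab], NETWORKS_7), collapse = ", "))
  if (is.null(parcels$structure)) parcels$structure <- NA_character_
  class(parcels) <- c("parcel_atlas", "data.frame")
  parcels
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("parcel_atlas: %d parcels (%d cortical, %d subcortical)\n",
              nrow(x), sum(x$tissue == "cortical"),
              sum(x$tissue == "subcortical")))
  if (any(!is.na(x$network)))
    cat("  networks assigned:", sum(!is.na(x$network)), "parcels\n")
  invisible(x)
}

#' Construct and validate a vertex surface
#'
#' A triangulation-derived cortical surface reduced to what the pipeline
#' needs: vertex positions and an undirected adjacency edge list. Edges never
#' cross hemispheres.
#'
#' @param vertices data.frame with `vertex_id`, `x`, `y`, `z` (mm),
#'   `hemisphere` ("L"/"R").
#' @param edges data.frame with two columns of vertex ids (undirected edges).
#' @return A `vertex_surface` object (list of `vertices` and `edges`).
#' @export
vertex_surface <- function(vertices, edges) {
  vertices <- as.data.frame(vertices)
  req <- c("vertex_id", "x", "y", "z", "hemisphere")
  miss <- setdiff(req, names(vertices))
  if (length(miss))
    stop("vertex table missing columns: ", paste(miss, collapse = ", "))
  vertices$vertex_id <- as.integer(vertices$vertex_id)
  if (anyDuplicated(vertices$vertex_id)) stop("vertex_ids must be unique")
  if (!all(vertices$hemisphere %in% c("L", "R")))
    stop("vertex hemisphere must be L or R")
  if (!all(is.finite(as.matrix(vertices[, c("x", "y", "z")]))))
    stop("vertex positions must be finite")
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("edge list needs two vertex_id columns")
  names(edges)[1:2] <- c("v1", "v2")
  edges$v1 <- as.integer(edges$v1); edges$v2 <- as.integer(edges$v2)
  if (!all(c(edges$v1, edges$v2) %in% vertices$vertex_id))
    stop("edge refers to unknown vertex_id")
  hemi <- vertices$hemisphere[match(edges$v1, vertices$vertex_id)]
  hemi2 <- vertices$hemisphere[match(edges$v2, vertices$vertex_id)]
  if (any(hemi != hemi2))
    stop("cross-hemisphere edges are not allowed")
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges),
            class = "vertex_surface")
}

#' @export
print.vertex_surface <- function(x, ...) {
  cat(sprintf("vertex_surface: %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Map surface vertices to their nearest cortical parcel
#'
#' Assigns each vertex to the cortical parcel with the nearest centroid
#' (Euclidean distance in mm), restricted to the vertex's own hemisphere.
#' Exact ties are broken by the lower `parcel_id`, making the assignment
#' deterministic.
#'
#' @param surface a [vertex_surface].
#' @param atlas a [parcel_atlas].
#' @return data.frame `vertex_id`, `parcel_id` (one row per vertex).
#' @export
map_vertices_to_parcels <- function(surface, atlas) {
  stopifnot(inherits(surface, "vertex_surface"),
            inherits(atlas, "parcel_atlas"))
  v <- surface$vertices
  out <- integer(nrow(v))
  for (h in unique(v$hemisphere)) {
    vi <- which(v$hemisphere == h)
    pk <- atlas[atlas$tissue == "cortical" & atlas$hemisphere == h, ,
                drop = FALSE]
    if (nrow(pk) == 0)
      stop("no cortical parcels in hemisphere ", h,
           " but surface has vertices there")
    pk <- pk[order(pk$parcel_id), , drop = FALSE]  # ties -> lowest id
    vp <- as.matrix(v[vi, c("x", "y", "z")])
    cp <- as.matrix(pk[, c("x", "y", "z")])
    # squared distances via the expansion |v|^2 - 2 v.c + |c|^2
    d2 <- outer(rowSums(vp^2), rowSums(cp^2), "+") - 2 * tcrossprod(vp, cp)
    out[vi] <- pk$parcel_id[apply(d2, 1L, which.min)]
  }
  data.frame(vertex_id = v$vertex_id, parcel_id = out)
}

#' Aggregate per-vertex values to parcel means
#'
#' Unweighted mean of member-vertex values per cortical parcel. Parcels with
#' no mapped vertices get `NA`.
#'
#' @param map vertex-to-parcel map as returned by [map_vertices_to_parcels].
#' @param vertex_values numeric vector named by (or ordered as) the map's
#'   `vertex_id`.
#' @param parcel_ids optional integer vector of parcels to report (defaults
#'   to the parcels present in the map).
#' @return named numeric vector of parcel means.
#' @export
aggregate_to_parcels <- function(map, vertex_values, parcel_ids = NULL) {
  if (length(vertex_values) != nrow(map))
    stop("vertex_values length must equal map size")
  bad <- which(!is.finite(vertex_values))
  if (length(bad))
    stop("non-finite vertex value at vertex_id ",
         map$vertex_id[bad[1]])
  if (is.null(parcel_ids)) parcel_ids <- sort(unique(map$parcel_id))
  sums <- tapply(vertex_values, map$parcel_id, mean)
  out <- rep(NA_real_, length(parcel_ids))
  names(out) <- parcel_ids
  hit <- intersect(names(sums), names(out))
  out[hit] <- sums[hit]
  out
}

#' Assign intrinsic-network labels to cortical parcels
#'
#' @param atlas a [parcel_atlas].
#' @param labels data.frame `parcel_id`, `network`; must cover every cortical
#'   parcel with labels from [NETWORKS_7]; labeling a subcortical parcel is an
#'   error.
#' @return the atlas with its `network` column populated.
#' @export
assign_networks <- function(atlas, labels) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  labels <- as.data.frame(labels)
  if (!all(c("parcel_id", "network") %in% names(labels)))
    stop("labels need columns parcel_id, network")
  unknown <- setdiff(labels$network, NETWORKS_7)
  if (length(unknown))
    stop("unknown network label(s): ", paste(unknown, collapse = ", "))
  sub_ids <- atlas$parcel_id[atlas$tissue == "subcortical"]
  if (any(labels$parcel_id %in% sub_ids))
    stop("network label given for subcortical parcel(s): ",
         paste(intersect(labels$parcel_id, sub_ids), collapse = ", "))
  ctx_ids <- atlas$parcel_id[atlas$tissue == "cortical"]
  uncovered <- setdiff(ctx_ids, labels$parcel_id)
  if (length(uncovered))
    stop("labels must cover all cortical parcels; missing ",
         length(uncovered), " parcel(s)")
  atlas$network <- NA_character_
  idx <- match(labels$parcel_id, atlas$parcel_id)
  atlas$network[idx] <- labels$network
  parcel_atlas(atlas)
}
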