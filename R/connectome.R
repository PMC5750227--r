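#' Construct and validate a connectome
#'
#' A connectome is a symmetric parcel-by-parcel weight matrix tagged by
#' modality. Modality-specific invariants are enforced on construction:
#' functional weights lie in \[-1, 1\] with unit diagonal; structural weights
#' are non-negative; distance weights are non-negative with zero diagonal.
#'
#' @param weights square numeric matrix.
#' @param modality "functional", "structural" or "distance".
#' @param parcel_ids integer vector giving the parcel order of the rows.
#' @param tol tolerance for symmetry and range checks.
#' @return A `connectome` object.
#' @export
connectome <- function(weights, modality, parcel_ids = NULL, tol = 1e-8) {
  modality <- match.arg(modality, c("functional", "structural", "distance"))
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (anyNA(weights) || !all(is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite weight at (%d, %d)", bad[1], bad[2]))
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max |w - t(w)| = %g)",
                 asym))
  weights <- (weights + t(weights)) / 2
  if (is.null(parcel_ids)) parcel_ids <- seq_len(nrow(weights))
  parcel_ids <- as.integer(parcel_ids)
  if (length(parcel_ids) != nrow(weights) || anyDuplicated(parcel_ids))
    stop("parcel_ids must be unique and match matrix dimension")
  if (modality == "functional") {
    if (any(weights > 1 + tol) || any(weights < -1 - tol))
      stop("functional weights must lie in [-1, 1]")
    if (max(abs(diag(weights) - 1)) > tol)
      stop("functional connectome must have unit diagonal")
    weights <- pmin(pmax(weights, -1), 1)
    diag(weights) <- 1
  } else {
    if (any(weights < -tol))
      stop(modality, " weights must be non-negative")
    weights[weights < 0] <- 0
    if (modality == "distance") {
      if (max(abs(diag(weights))) > tol)
        stop("distance connectome must have zero diagonal")
      diag(weights) <- 0
    }
  }
  dimnames(weights) <- list(parcel_ids, parcel_ids)
  structure(list(weights = weights, modality = modality,
                 parcel_ids = parcel_ids),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %s, %d x %d\n", x$modality,
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Functional connectome from parcel time series
#'
#' Pairwise Pearson correlation of parcel time series, the conventional
#' resting-state functional connectivity estimate.
#'
#' @param series numeric matrix, parcels in rows, time points in columns.
#' @param parcel_ids parcel order of the rows.
#' @return A functional [connectome].
#' @export
functional_from_timeseries <- function(series, parcel_ids = NULL) {
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("need at least 3 time points")
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    if (is.null(parcel_ids)) parcel_ids <- seq_len(nrow(series))
    stop("constant time series for parcel ", parcel_ids[which(sds == 0)[1]])
  }
  w <- stats::cor(t(series))
  connectome(w, "functional", parcel_ids)
}

#' Euclidean distance connectome from atlas centroids
#'
#' @param atlas a [parcel_atlas].
#' @return A distance [connectome] over all parcels, in mm.
#' @export
distance_connectome <- function(atlas) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  d <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  connectome(d, "distance", atlas$parcel_id)
}

#' Write a connectome to a delimited text file
#'
#' Tab-delimited square matrix with parcel ids as the first row and first
#' column; symmetric storage (no triangular shorthand).
#'
#' @param conn a [connectome].
#' @param path output file path.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  df <- data.frame(parcel_id = conn$parcel_ids, conn$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectome from a delimited text file
#'
#' Validates the modality invariants on read; an id mismatch with the given
#' atlas, NaN entries, or asymmetry beyond tolerance are errors.
#'
#' @param path file written by [write_connectome] (or equivalent).
#' @param modality connectome modality to validate against.
#' @param atlas optional [parcel_atlas]; if given, the file's parcel ids must
#'   all be known to the atlas.
#' @param tol symmetry tolerance.
#' @return A [connectome].
#' @export
read_connectome <- function(path, modality, atlas = NULL, tol = 1e-8) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  ids_row <- as.integer(df[[1]])
  ids_col <- as.integer(names(df)[-1])
  if (!identical(ids_row, ids_col))
    stop("header parcel_ids do not match first-column parcel_ids")
  w <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(w)) {
    bad <- which(is.na(w), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN entry at parcel_ids (%d, %d)",
                 ids_row[bad[1]], ids_col[bad[2]]))
  }
  if (!is.null(atlas)) {
    extra <- setdiff(ids_row, atlas$parcel_id)
    if (length(extra))
      stop("parcel_ids not in atlas: ", paste(extra, collapse = ", "))
  }
  connectome(w, modality, ids_row, tol = tol)
}
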