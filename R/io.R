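# Delimited-text I/O for the pipeline's data objects. All files are
# tab-delimited with headers; see the individual writers for schemas.

#' Read / write a parcel atlas table
#'
#' Schema: `parcel_id, hemisphere, tissue, x, y, z, network, structure`
#' (network/structure may be empty).
#'
#' @param path file path.
#' @return [parcel_atlas] (reader) or `path` invisibly (writer).
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""))
  parcel_atlas(df)
}

#' @rdname read_atlas
#' @param atlas a [parcel_atlas].
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a vertex surface
#'
#' Two files: a vertex table (`vertex_id, x, y, z, hemisphere`) and an edge
#' list (`v1, v2`).
#'
#' @param vertex_path,edge_path file paths.
#' @return [vertex_surface] (reader) or invisible NULL (writer).
#' @export
read_surface <- function(vertex_path, edge_path) {
  vertex_surface(
    utils::read.table(vertex_path, header = TRUE, sep = "\t"),
    utils::read.table(edge_path, header = TRUE, sep = "\t"))
}

#' @rdname read_surface
#' @param surface a [vertex_surface].
#' @export
write_surface <- function(surface, vertex_path, edge_path) {
  utils::write.table(surface$vertices, vertex_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(surface$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read / write an atrophy map
#'
#' Schema: `parcel_id, z, structure, tissue`.
#' @param path file path.
#' @return [atrophy_map] (reader).
#' @export
read_atrophy <- function(path) {
  atrophy_map(utils::read.table(path, header = TRUE, sep = "\t",
                                na.strings = c("NA", "")))
}

#' @rdname read_atrophy
#' @param atrophy an [atrophy_map].
#' @export
write_atrophy <- function(atrophy, path) {
  utils::write.table(as.data.frame(atrophy), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a longitudinal thickness panel
#'
#' Long format, one row per subject x timepoint x vertex:
#' `subject,group,site,age,sex,timepoint,vertex_id,thickness_mm`
#' (timepoint is "t1" or "t2").
#'
#' @param path file path.
#' @return `thickness_panel` (reader).
#' @export
read_thickness_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  req <- c("subject", "group", "site", "age", "sex", "timepoint",
           "vertex_id", "thickness_mm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("panel file missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$timepoint %in% c("t1", "t2")))
    stop("timepoint must be 't1' or 't2'")
  if (any(df$thickness_mm <= 0)) stop("thickness values must be positive")
  subs <- unique(df[, c("subject", "group", "site", "age", "sex")])
  names(subs)[1] <- "subject_id"
  rownames(subs) <- NULL
  vids <- sort(unique(df$vertex_id))
  grab <- function(tp) {
    d <- df[df$timepoint == tp, ]
    m <- matrix(NA_real_, nrow(subs), length(vids),
                dimnames = list(subs$subject_id, vids))
    m[cbind(match(d$subject, subs$subject_id), match(d$vertex_id, vids))] <-
      d$thickness_mm
    if (anyNA(m)) stop("panel incomplete at timepoint ", tp)
    m
  }
  structure(list(subjects = subs, t1 = grab("t1"), t2 = grab("t2"),
                 vertex_ids = vids),
            class = "thickness_panel")
}

#' @rdname read_thickness_panel
#' @param panel a `thickness_panel`.
#' @export
write_thickness_panel <- function(panel, path) {
  subs <- panel$subjects
  long <- do.call(rbind, lapply(c("t1", "t2"), function(tp) {
    m <- panel[[tp]]
    data.frame(subject = rep(subs$subject_id, times = ncol(m)),
               group = rep(subs$group, times = ncol(m)),
               site = rep(subs$site, times = ncol(m)),
               age = rep(subs$age, times = ncol(m)),
               sex = rep(subs$sex, times = ncol(m)),
               timepoint = tp,
               vertex_id = rep(panel$vertex_ids, each = nrow(m)),
               thickness_mm = as.vector(m))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a vertex-to-parcel map
#' @param path file path.
#' @return data.frame `vertex_id`, `parcel_id` (reader).
#' @export
read_vertex_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("vertex_id", "parcel_id") %in% names(df)))
    stop("map file needs columns vertex_id, parcel_id")
  df
}

#' @rdname read_vertex_map
#' @param map the two-column map data.frame.
#' @export
write_vertex_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Schema: `subject,group,site,age,sex,moca_t1,moca_t2,updrs_t1,updrs_t2,`
#' `asyn,abeta42,ttau,ptau181`.
#' @param path file path.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  names(df)[names(df) == "subject"] <- "subject_id"
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @rdname read_clinical
#' @param clinical a `clinical_table`.
#' @export
write_clinical <- function(clinical, path) {
  out <- as.data.frame(clinical)
  names(out)[names(out) == "subject_id"] <- "subject"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
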