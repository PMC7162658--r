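#' Distribution-based assignment quotient
#'
#' The mean probability of an atlas area over the voxels of a cluster,
#' divided by the area's mean probability over all voxels where the area is
#' observed (probability above `min_prob`). A quotient above 1 indicates the
#' cluster sits centrally within the area; below 1, peripherally; 0, fully
#' outside its support. Invariant to rescaling the area's probability volume
#' by a positive constant.
#'
#' @param cluster_mask logical 3D array (or integer voxel indices) selecting
#'   the cluster.
#' @param atlas a `prob_atlas`.
#' @param area area label or index.
#' @param min_prob observation floor defining the area's support (default 0,
#'   i.e. strictly positive probability; thresholded atlases may need more).
#' @return A single number, or `NA` (undefined) when the area is observed
#'   nowhere.
#' @export
assignment_quotient <- function(cluster_mask, atlas, area, min_prob = 0) {
  stopifnot(inherits(atlas, "prob_atlas"))
  a <- if (is.character(area)) match(area, atlas$area_labels) else as.integer(area)
  if (is.na(a) || a < 1L || a > length(atlas$area_labels))
    stop_invalid("area", "not present in atlas")
  p <- atlas$prob[, , , a]
  idx <- if (is.logical(cluster_mask)) which(cluster_mask) else
    as.integer(cluster_mask)
  if (length(idx) == 0L) stop_invalid("cluster_mask", "empty cluster")
  support <- p > min_prob
  if (!any(support)) return(NA_real_)
  mean(p[idx]) / mean(p[support])
}

#' Quotient report for a cluster against every atlas area
#'
#' @inheritParams assignment_quotient
#' @return data.frame with `area`, `quotient`, `cluster_size`.
#' @export
quotient_report <- function(cluster_mask, atlas, min_prob = 0) {
  idx <- if (is.logical(cluster_mask)) which(cluster_mask) else
    as.integer(cluster_mask)
  data.frame(
    area = atlas$area_labels,
    quotient = vapply(atlas$area_labels, function(a)
      assignment_quotient(idx, atlas, a, min_prob), numeric(1)),
    cluster_size = length(idx), row.names = NULL)
}

#' Volume fractions of labels within structures
#'
#' For every structure mask and every label set, the percentage of the
#' structure's voxels carrying that label:
#' `100 * |label n structure| / |structure|`. When the labels partition a
#' structure its row sums to 100.
#'
#' @param labels named list of logical vectors/arrays (e.g. per-template
#'   assignment masks plus the unassigned mask), all on one grid.
#' @param structure_masks named list of logical vectors/arrays on the same
#'   grid.
#' @return data.frame, one row per structure, one column per label, values
#'   in percent.
#' @export
volume_fractions <- function(labels, structure_masks) {
  lab <- lapply(labels, as.logical)
  stru <- lapply(structure_masks, as.logical)
  nvox <- length(lab[[1]])
  for (l in lab) if (length(l) != nvox)
    stop("label masks are on different grids", call. = FALSE)
  out <- matrix(NA_real_, length(stru), length(lab),
                dimnames = list(names(stru), names(lab)))
  for (s in seq_along(stru)) {
    m <- stru[[s]]
    if (length(m) != nvox)
      stop("structure masks are on a different grid", call. = FALSE)
    if (!any(m))
      stop(sprintf("empty structure mask: %s", names(stru)[s]), call. = FALSE)
    for (l in seq_along(lab))
      out[s, l] <- 100 * sum(lab[[l]] & m) / sum(m)
  }
  data.frame(structure = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}
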