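#' Region timeseries container
#'
#' A time-by-unit matrix of signal values with its sampling interval. Units
#' are voxels or regions; every correlation in the pipeline is computed from
#' objects of this class.
#'
#' @param values numeric matrix, rows = timepoints, columns = units.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param unit_labels optional character vector naming the columns.
#' @return A `region_ts` object (list with `values`, `tr_seconds`,
#'   `unit_labels`).
#' @export
region_ts <- function(values, tr_seconds, unit_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_invalid("values", "must be numeric")
  if (nrow(values) < 2L) stop_invalid("values", "need n_time >= 2")
  if (any(!is.finite(values))) stop_invalid("values", "non-finite entries")
  tr_seconds <- check_pos(tr_seconds, "tr_seconds")
  if (is.null(unit_labels)) {
    unit_labels <- colnames(values)
    if (is.null(unit_labels)) unit_labels <- paste0("u", seq_len(ncol(values)))
  }
  if (length(unit_labels) != ncol(values))
    stop_invalid("unit_labels", "one label per column required")
  colnames(values) <- unit_labels
  structure(list(values = values, tr_seconds = tr_seconds,
                 unit_labels = unit_labels),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d timepoints x %d units, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$values)

as_region_ts <- function(x, tr_seconds) {
  if (inherits(x, "region_ts")) return(x)
  region_ts(x, tr_seconds)
}
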