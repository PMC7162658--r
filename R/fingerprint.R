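#' Construct a connectivity fingerprint
#'
#' @param values numeric vector, one connectivity value per target.
#' @param target_labels character vector, same length.
#' @param scale `"r"` or `"fisher_z"`.
#' @param subject_id optional identifier.
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(values, target_labels, scale = c("r", "fisher_z"),
                        subject_id = NA_character_) {
  scale <- match.arg(scale)
  if (length(values) != length(target_labels))
    stop_invalid("values", "one value per target required")
  if (scale == "r" && any(abs(values) >= 1))
    stop_invalid("values", "r-scale values must lie in (-1, 1)")
  structure(list(values = as.numeric(values),
                 target_labels = as.character(target_labels),
                 scale = scale, subject_id = subject_id),
            class = "fingerprint")
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, odd and strictly increasing. Values at or beyond |r| = 1
#' (degenerate correlations) are clipped to +/-(1 - 1e-7) with a warning so
#' the transform stays finite.
#'
#' @param r numeric vector of correlations.
#' @return The transformed vector.
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-7
  if (any(abs(r) >= 1)) {
    warning("correlation(s) at |r| >= 1 clipped to +/-(1 - 1e-7) before atanh")
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

#' Seed-to-target connectivity fingerprint from timeseries
#'
#' Pearson correlation of the seed series with each target series, optionally
#' Fisher r-to-z transformed.
#'
#' @param seed_series numeric vector, an `eigenvariate`, or a single-column
#'   [region_ts()].
#' @param target_ts a [region_ts()] (or time-by-target matrix) of target
#'   series, same length.
#' @param scale `"r"` (default) or `"fisher_z"`.
#' @param subject_id carried into the result.
#' @return A [fingerprint()].
#' @export
compute_fingerprint <- function(seed_series, target_ts,
                                scale = c("r", "fisher_z"),
                                subject_id = NA_character_) {
  scale <- match.arg(scale)
  if (inherits(seed_series, "eigenvariate")) seed_series <- seed_series$series
  if (inherits(seed_series, "region_ts")) seed_series <- seed_series$values[, 1]
  X <- if (inherits(target_ts, "region_ts")) target_ts$values else
    as.matrix(target_ts)
  labels <- colnames(X) %||% paste0("t", seq_len(ncol(X)))
  if (length(seed_series) != nrow(X))
    stop_invalid("seed_series", "length differs from target series")
  if (length(seed_series) < 3L) stop_invalid("seed_series", "need length >= 3")
  if (sd(seed_series) == 0) stop("constant series for region: seed",
                                 call. = FALSE)
  csd <- apply(X, 2, sd)
  if (any(csd == 0))
    stop(sprintf("constant series for region: %s",
                 paste(labels[csd == 0], collapse = ", ")), call. = FALSE)
  r <- as.vector(cor(seed_series, X))
  v <- if (scale == "fisher_z") fisher_z(r) else r
  if (scale == "r") v <- pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)
  fingerprint(v, labels, scale, subject_id)
}

fp_matrix <- function(fps) {
  labs <- fps[[1]]$target_labels
  scl <- fps[[1]]$scale
  for (fp in fps) {
    if (!identical(fp$target_labels, labs))
      stop("fingerprint target order mismatch", call. = FALSE)
    if (!identical(fp$scale, scl))
      stop("fingerprint scale mismatch", call. = FALSE)
  }
  do.call(rbind, lapply(fps, `[[`, "values"))
}

#' Robust-mean template fingerprint across subjects
#'
#' Per-target 20%-trimmed mean over subject fingerprints; dispersion is the
#' standard error of the mean of the retained (untrimmed) values.
#'
#' @param fps list of [fingerprint()]s with identical target order and scale.
#' @param trim trim fraction per tail (default 0.2); 0 gives the plain mean.
#' @param estimator `"trimmed"` (default), `"mean"`, or `"median"`.
#' @return A `template_fingerprint`: list with `values`, `dispersion`,
#'   `n_subjects`, `target_labels`, `scale`.
#' @export
robust_mean_template <- function(fps, trim = 0.2,
                                 estimator = c("trimmed", "mean", "median")) {
  estimator <- match.arg(estimator)
  if (length(fps) < 1L) stop_invalid("fps", "need >= 1 fingerprint")
  M <- fp_matrix(fps)
  n <- nrow(M)
  g <- if (estimator == "trimmed") floor(n * trim) else 0L
  stat <- function(x) switch(estimator,
    trimmed = mean(x, trim = trim),
    mean = mean(x),
    median = median(x))
  disp <- function(x) {
    if (n == 1L) return(0)
    if (estimator == "median") return(sd(x) / sqrt(n))
    kept <- sort(x)[seq(g + 1L, n - g)]
    sd(kept) / sqrt(length(kept))
  }
  structure(list(values = apply(M, 2, stat),
                 dispersion = apply(M, 2, disp),
                 n_subjects = n,
                 target_labels = fps[[1]]$target_labels,
                 scale = fps[[1]]$scale,
                 trim = if (estimator == "trimmed") trim else 0),
            class = "template_fingerprint")
}

#' Manhattan distance between two fingerprints
#'
#' `D = sum_t |a_t - b_t|` over matched targets.
#'
#' @param fpA,fpB [fingerprint()] or `template_fingerprint` objects with
#'   identical target order and scale.
#' @return A single non-negative number.
#' @export
manhattan_distance <- function(fpA, fpB) {
  if (!identical(fpA$target_labels, fpB$target_labels))
    stop("fingerprint target order mismatch", call. = FALSE)
  if (!identical(fpA$scale, fpB$scale))
    stop("fingerprint scale mismatch", call. = FALSE)
  sum(abs(fpA$values - fpB$values))
}

#' Permutation test for a difference between two seeds' fingerprints
#'
#' The observed statistic is the Manhattan distance between the two groups'
#' robust-mean templates. The null exchanges each subject's pair of
#' fingerprints between the two seeds with probability 1/2 (label exchange
#' within subject — the natural exchangeability for "these two seeds have
#' the same fingerprint"), recomputing the template distance each time. The
#' p-value uses the add-one estimator `(1 + #{null >= obs}) / (n_perm + 1)`
#' and so is never zero.
#'
#' @param fpsA,fpsB per-subject fingerprint lists, paired by position.
#' @param n_perm number of permutations (>= 1; 10,000 for publication use).
#' @param rng_seed integer seed.
#' @param trim template trim fraction.
#' @return A `distance_test`: list with `observed_distance`, `p_value`,
#'   `n_permutations`, `null_distances`.
#' @export
fingerprint_distance_test <- function(fpsA, fpsB, n_perm = 10000L,
                                      rng_seed = 1L, trim = 0.2) {
  n_perm <- check_count(n_perm, "n_perm")
  if (length(fpsA) < 2L || length(fpsB) < 2L)
    stop_invalid("fpsA", "need >= 2 subjects per group")
  if (length(fpsA) != length(fpsB))
    stop_invalid("fpsB", "groups must be paired (equal size)")
  A <- fp_matrix(fpsA)
  B <- fp_matrix(fpsB)
  if (!identical(fpsA[[1]]$target_labels, fpsB[[1]]$target_labels))
    stop("fingerprint target order mismatch", call. = FALSE)
  observed <- manhattan_distance(robust_mean_template(fpsA, trim),
                                 robust_mean_template(fpsB, trim))
  set.seed(rng_seed)
  null <- .dist_perm_null_cpp(A, B, n_perm, trim)
  structure(list(observed_distance = observed,
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_permutations = n_perm,
                 null_distances = null),
            class = "distance_test")
}

#' @export
print.distance_test <- function(x, ...) {
  cat(sprintf("Manhattan distance = %.3f, p %s (%d permutations)\n",
              x$observed_distance,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.4f", x$p_value),
              x$n_permutations))
  invisible(x)
}

#' Long-format export of fingerprints
#'
#' @param fps list of [fingerprint()]s.
#' @param seed seed label recorded per row.
#' @return data.frame with columns subject, seed, target, value, scale.
#' @export
fingerprints_to_df <- function(fps, seed = NA_character_) {
  do.call(rbind, lapply(fps, function(fp)
    data.frame(subject = fp$subject_id, seed = seed,
               target = fp$target_labels, value = fp$values,
               scale = fp$scale)))
}
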