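#' Specification for a synthetic tracer connectome
#'
#' Describes a planted-cluster injection-by-voxel tracer matrix: `k_clusters`
#' groups of voxels share a cluster-mean injection profile, profiles are drawn
#' i.i.d. Gaussian with standard deviation `separation` (so the expected
#' per-injection difference between two cluster profiles has sd
#' `sqrt(2) * separation`), and i.i.d. Gaussian noise of sd `noise_sd` is
#' added per voxel. The `separation / noise_sd` ratio is the knob governing
#' recoverability of the planted parcellation.
#'
#' @param n_injections number of injection sites (rows).
#' @param n_voxels number of voxels (columns).
#' @param k_clusters number of planted clusters.
#' @param separation non-negative; sd of cluster-mean profiles.
#' @param noise_sd non-negative; per-entry noise sd.
#' @param rng_seed integer seed; all generation is deterministic given it.
#' @return A `tracer_sim_spec` object.
#' @export
tracer_sim_spec <- function(n_injections, n_voxels, k_clusters,
                            separation = 5, noise_sd = 1, rng_seed = 1L) {
  spec <- list(
    n_injections = check_count(n_injections, "n_injections"),
    n_voxels = check_count(n_voxels, "n_voxels"),
    k_clusters = check_count(k_clusters, "k_clusters"),
    separation = check_nonneg(separation, "separation"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L))
  if (spec$n_voxels < spec$k_clusters)
    stop_invalid("n_voxels", "need n_voxels >= k_clusters")
  structure(spec, class = "tracer_sim_spec")
}

# Lay labelled voxels out as contiguous axis-aligned boxes stacked along x,
# one box per label level in order of first appearance. Returns integer
# 1-based voxel coordinates and the bounding grid dimension.
layout_blocks <- function(labels) {
  lev <- unique(labels)
  counts <- table(factor(labels, levels = lev))
  side <- max(2L, ceiling(max(counts)^(1 / 3)))
  coords <- matrix(0L, length(labels), 3)
  x0 <- 0L
  for (l in lev) {
    idx <- which(labels == l)
    m <- length(idx)
    bx <- ceiling(m / (side * side))
    g <- as.matrix(expand.grid(x = seq_len(bx), y = seq_len(side),
                               z = seq_len(side)))[seq_len(m), , drop = FALSE]
    g[, 1] <- g[, 1] + x0
    coords[idx, ] <- g
    x0 <- x0 + bx + 1L  # one-voxel gap keeps blocks disconnected
  }
  list(coords = coords,
       dim = c(max(coords[, 1]), max(coords[, 2]), max(coords[, 3])))
}

#' Generate a synthetic tracer connectome with planted clusters
#'
#' @param spec a [tracer_sim_spec()].
#' @return A list with `connectome` (a `tracer_connectome` holding the raw,
#'   not yet z-scored strengths, injection labels, and 3D voxel coordinates
#'   laid out as contiguous per-cluster blocks) and `truth` (per-voxel planted
#'   cluster labels and the cluster-mean profiles).
#' @export
generate_tracer_matrix <- function(spec) {
  if (!inherits(spec, "tracer_sim_spec")) spec <- do.call(tracer_sim_spec, spec)
  set.seed(spec$rng_seed)
  k <- spec$k_clusters
  sizes <- rep(spec$n_voxels %/% k, k) +
    c(rep(1L, spec$n_voxels %% k), rep(0L, k - spec$n_voxels %% k))
  labels <- rep(seq_len(k), times = sizes)
  profiles <- matrix(rnorm(spec$n_injections * k, sd = spec$separation),
                     spec$n_injections, k)
  strengths <- profiles[, labels, drop = FALSE] +
    matrix(rnorm(spec$n_injections * spec$n_voxels, sd = spec$noise_sd),
           spec$n_injections, spec$n_voxels)
  lay <- layout_blocks(labels)
  conn <- structure(list(
    strengths = strengths,
    injection_labels = paste0("inj", seq_len(spec$n_injections)),
    voxel_coordinates = lay$coords,
    grid_dim = lay$dim,
    zscored = FALSE), class = "tracer_connectome")
  truth <- list(cluster_labels = labels, profiles = profiles)
  list(connectome = conn, truth = truth)
}

#' Specification for a synthetic two-compartment rsfMRI dataset
#'
#' Describes one synthetic "species": independent unit-variance Gaussian
#' target signals, and seed/voxel signals built as fixed linear mixtures of
#' the targets plus i.i.d. Gaussian noise, so every seed-to-target
#' correlation has the closed form `w_t / sqrt(sum(w^2) + noise_sd^2)`.
#' Voxels labelled with a seed name inherit that seed's loading vector;
#' voxels labelled `"unique"` get a loading vector orthogonal (in target
#' space) to every seed's, guaranteeing low fingerprint similarity with all
#' templates.
#'
#' @param n_subjects,n_timepoints,tr_seconds sampling layout.
#' @param target_labels character vector of target region names.
#' @param seed_defs named list (or matrix, seeds x targets) of loading
#'   vectors, one entry per target each.
#' @param voxel_labels character vector over striatal voxels; each entry a
#'   seed name or `"unique"`.
#' @param brain_labels optional character vector over whole-brain voxels,
#'   same convention (`"none"` allowed for pure-noise voxels).
#' @param noise_sd non-negative noise sd added to every seed/voxel series.
#' @param ar_coef optional AR(1) coefficient for target signals (default 0 =
#'   i.i.d. white, keeping correlations closed-form; a nonzero value is only
#'   for filter tests).
#' @param rng_seed integer seed.
#' @return A `species_sim_spec` object.
#' @export
species_sim_spec <- function(n_subjects, n_timepoints, tr_seconds,
                             target_labels, seed_defs, voxel_labels,
                             brain_labels = NULL, noise_sd = 1,
                             ar_coef = 0, rng_seed = 1L) {
  if (is.matrix(seed_defs)) {
    seed_defs <- stats::setNames(
      lapply(seq_len(nrow(seed_defs)), function(i) seed_defs[i, ]),
      rownames(seed_defs) %||% paste0("seed", seq_len(nrow(seed_defs))))
  }
  nt <- length(target_labels)
  for (s in names(seed_defs))
    if (length(seed_defs[[s]]) != nt)
      stop_invalid("seed_defs", sprintf(
        "loading vector for seed '%s' has length %d, expected %d (one per target)",
        s, length(seed_defs[[s]]), nt))
  bad <- setdiff(unique(voxel_labels), c(names(seed_defs), "unique"))
  if (length(bad))
    stop_invalid("voxel_labels",
                 paste("labels not a seed name or 'unique':",
                       paste(bad, collapse = ", ")))
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 11L),
    tr_seconds = check_pos(tr_seconds, "tr_seconds"),
    target_labels = as.character(target_labels),
    seed_defs = seed_defs,
    voxel_labels = as.character(voxel_labels),
    brain_labels = if (!is.null(brain_labels)) as.character(brain_labels),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    ar_coef = as.numeric(ar_coef),
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L))
  structure(spec, class = "species_sim_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vector in target space orthogonal to every seed loading AND to the
# constant vector, scaled to the mean seed norm. Orthogonality to the
# constant matters: fingerprint matching uses Pearson correlation, which
# centres the vectors, so a complement vector with nonzero mean would still
# correlate with every (centred) template pattern.
unique_loading <- function(seed_defs) {
  W <- rbind(do.call(rbind, seed_defs), 1)
  nt <- ncol(W)
  if (nrow(W) >= nt)
    stop("cannot build a unique circuit: seed loadings span target space")
  q <- qr.Q(qr(t(W)), complete = TRUE)
  u <- q[, nrow(W) + 1L]
  u * mean(sqrt(rowSums(W[-nrow(W), , drop = FALSE]^2)))
}

mix_series <- function(targets, w, noise_sd, n_time) {
  as.vector(targets %*% w) + rnorm(n_time, sd = noise_sd)
}

#' Generate a synthetic multi-subject species dataset
#'
#' @param spec a [species_sim_spec()].
#' @return A list with `subjects` (per subject: `targets`, `seeds`, `voxels`,
#'   and optionally `brain` as [region_ts()] objects), `grid` (striatal voxel
#'   grid: `dim` and integer `coords`, contiguous per-circuit blocks), and
#'   `truth` (voxel labels, seed loadings, the orthogonal unique loading, and
#'   per-seed expected fingerprints).
#' @export
generate_species_dataset <- function(spec) {
  if (!inherits(spec, "species_sim_spec")) stop("need a species_sim_spec")
  set.seed(spec$rng_seed)
  nt <- length(spec$target_labels)
  n_time <- spec$n_timepoints
  has_unique <- any(spec$voxel_labels == "unique") ||
    any(spec$brain_labels == "unique")
  u <- if (has_unique) unique_loading(spec$seed_defs)
  loading_for <- function(lbl) {
    if (lbl == "unique") u
    else if (lbl == "none") rep(0, nt)
    else spec$seed_defs[[lbl]]
  }
  gen_unit <- function(targets, labels) {
    vapply(labels, function(l)
      mix_series(targets, loading_for(l), spec$noise_sd, n_time),
      numeric(n_time))
  }
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    tg <- matrix(rnorm(n_time * nt), n_time, nt)
    if (spec$ar_coef != 0)
      tg <- apply(tg, 2, function(x)
        as.vector(stats::filter(x, spec$ar_coef, method = "recursive")))
    colnames(tg) <- spec$target_labels
    seeds <- gen_unit(tg, names(spec$seed_defs))
    colnames(seeds) <- names(spec$seed_defs)
    voxels <- gen_unit(tg, spec$voxel_labels)
    colnames(voxels) <- paste0("v", seq_along(spec$voxel_labels))
    out <- list(
      targets = region_ts(tg, spec$tr_seconds),
      seeds = region_ts(seeds, spec$tr_seconds),
      voxels = region_ts(voxels, spec$tr_seconds))
    if (!is.null(spec$brain_labels)) {
      br <- gen_unit(tg, spec$brain_labels)
      colnames(br) <- paste0("b", seq_along(spec$brain_labels))
      out$brain <- region_ts(br, spec$tr_seconds)
    }
    out
  })
  lay <- layout_blocks(spec$voxel_labels)
  expected_fp <- lapply(spec$seed_defs, function(w)
    w / sqrt(sum(w^2) + spec$noise_sd^2))
  list(subjects = subjects,
       grid = list(dim = lay$dim, coords = lay$coords),
       truth = list(voxel_labels = spec$voxel_labels,
                    seed_loadings = spec$seed_defs,
                    unique_loading = u,
                    expected_fingerprints = expected_fp),
       spec = spec)
}

#' Generate a probabilistic atlas of smooth unimodal areas
#'
#' Each area's probability volume is an isotropic Gaussian bump,
#' `exp(-d^2 / (2 spread^2))`, maximal (1) at its peak voxel; with
#' `uniform = TRUE` every area is a constant 0.5 everywhere.
#'
#' @param n_areas number of areas (>= 1).
#' @param grid_shape integer 3-vector.
#' @param peak_locations optional n_areas x 3 matrix of 1-based peak voxel
#'   coordinates; drawn uniformly inside the grid when omitted.
#' @param spread bump standard deviation in voxels.
#' @param rng_seed integer seed (used only when peaks are drawn).
#' @param uniform logical; constant-probability atlas.
#' @return A `prob_atlas`: list with `prob` (4D array x,y,z,area) and
#'   `area_labels`.
#' @export
generate_prob_atlas <- function(n_areas, grid_shape, peak_locations = NULL,
                                spread = 2, rng_seed = 1L, uniform = FALSE) {
  n_areas <- check_count(n_areas, "n_areas")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_invalid("grid_shape", "must be a positive integer 3-vector")
  prob <- array(0, dim = c(grid_shape, n_areas))
  if (uniform) {
    prob[] <- 0.5
    peak_locations <- NULL
  } else {
    if (is.null(peak_locations)) {
      set.seed(rng_seed)
      peak_locations <- cbind(sample.int(grid_shape[1], n_areas, TRUE),
                              sample.int(grid_shape[2], n_areas, TRUE),
                              sample.int(grid_shape[3], n_areas, TRUE))
    }
    peak_locations <- matrix(as.numeric(peak_locations), ncol = 3)
    if (nrow(peak_locations) != n_areas)
      stop_invalid("peak_locations", "need one row per area")
    if (any(peak_locations < 1) ||
        any(sweep(peak_locations, 2, grid_shape, `>`)))
      stop_invalid("peak_locations", "peaks must lie inside the grid")
    g <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
    for (a in seq_len(n_areas)) {
      d2 <- rowSums(sweep(g, 2, peak_locations[a, ])^2)
      prob[, , , a] <- array(exp(-d2 / (2 * spread^2)), grid_shape)
    }
  }
  structure(list(prob = prob,
                 area_labels = paste0("area", seq_len(n_areas)),
                 peaks = peak_locations),
            class = "prob_atlas")
}
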