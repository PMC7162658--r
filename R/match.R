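#' Threshold-free cluster enhancement of a 3D statistic map
#'
#' For each voxel, integrates `extent^E * height^H` over suprathreshold
#' heights in steps of `dh`: `TFCE(v) = sum_h extent(v, h)^E h^H dh`, where
#' `extent(v, h)` is the size of the connected suprathreshold component
#' containing `v` at threshold `h`. Negative lobes are enhanced on the
#' negated map separately and subtracted. Defaults E = 0.5, H = 2,
#' 6-connectivity are the standard published TFCE parameters.
#'
#' @param stat_volume numeric 3D array.
#' @param E extent exponent (> 0 required by the interface; 0.5 default).
#' @param H height exponent (2 default).
#' @param dh integration step; `NULL` (default) uses `max(|stat|)/100`.
#' @param connectivity 6, 18, or 26.
#' @return A 3D array of enhanced values, same shape.
#' @export
tfce_enhance <- function(stat_volume, E = 0.5, H = 2, dh = NULL,
                         connectivity = 6L) {
  if (length(dim(stat_volume)) != 3L)
    stop_invalid("stat_volume", "must be a 3D array")
  check_pos(E, "E"); check_pos(H, "H")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_invalid("connectivity", "must be 6, 18 or 26")
  vmax <- max(abs(stat_volume))
  if (vmax == 0) return(stat_volume * 0)
  if (is.null(dh)) dh <- vmax / 100
  check_pos(dh, "dh")
  out <- .tfce_cpp(as.numeric(stat_volume), dim(stat_volume), E, H, dh,
                   as.integer(connectivity))
  array(out, dim(stat_volume))
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 6L) {
  stopifnot(length(dim(mask)) == 3L)
  array(.label_components_cpp(as.logical(mask), dim(mask),
                              as.integer(connectivity)), dim(mask))
}

#' Per-subject voxelwise fingerprint-similarity map
#'
#' Correlates each voxel's fingerprint with a template fingerprint from the
#' other species and stores the Fisher r-to-z value at the voxel. Constant
#' (degenerate) voxel fingerprints get similarity 0 with a warning.
#'
#' @param voxel_fps per-subject list; each element a voxel-by-target matrix
#'   of fingerprint values (target order matching the template) or a list of
#'   [fingerprint()]s.
#' @param template a `template_fingerprint`.
#' @param grid grid reference: list with `dim` and voxel `coords` (or
#'   `mask_idx`); carried through to inference.
#' @return A `similarity_map`: list with `z` (subject-by-voxel matrix of
#'   Fisher-z similarities), `template_id`, `grid`.
#' @export
voxelwise_similarity_map <- function(voxel_fps, template, grid = NULL) {
  tv <- template$values
  if (length(tv) < 3L) stop_invalid("template", "need >= 3 targets")
  rows <- lapply(voxel_fps, function(subj) {
    M <- if (is.matrix(subj)) subj else fp_matrix(subj)
    if (ncol(M) != length(tv))
      stop("voxel fingerprints and template differ in target count",
           call. = FALSE)
    sds <- apply(M, 1, sd)
    r <- rep(0, nrow(M))
    if (any(sds == 0))
      warning(sprintf("%d constant voxel fingerprint(s) set to similarity 0",
                      sum(sds == 0)))
    ok <- sds > 0
    if (any(ok)) r[ok] <- as.vector(cor(t(M[ok, , drop = FALSE]), tv))
    suppressWarnings(fisher_z(r))
  })
  structure(list(z = do.call(rbind, rows),
                 template_id = attr(template, "id") %||% NA_character_,
                 grid = grid),
            class = "similarity_map")
}

# One-sample t statistics per column of an n x V matrix; zero-variance
# columns with nonzero mean are capped at +/- t_cap.
col_tstat <- function(X, t_cap = 50) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / n)
  tt[v == 0 & m == 0] <- 0
  pmin(pmax(tt, -t_cap), t_cap)
}

vol_from_vox <- function(values, grid) {
  vol <- array(0, grid$dim)
  vol[grid_index(grid)] <- values
  vol
}

grid_index <- function(grid) {
  if (!is.null(grid$mask_idx)) return(grid$mask_idx)
  grid$coords[, 1] + grid$dim[1] * (grid$coords[, 2] - 1) +
    grid$dim[1] * grid$dim[2] * (grid$coords[, 3] - 1)
}

#' One-sample group inference with sign-flip TFCE permutation testing
#'
#' One-sample t statistics per voxel; the null is built by randomly negating
#' whole subject maps (valid under a symmetric null), each permuted t map is
#' TFCE-enhanced, and family-wise corrected p-values come from the null
#' distribution of the maximum TFCE statistic. With `n <= 12` subjects the
#' full set of `2^n` sign patterns is enumerated (exact test); otherwise
#' `n_perm` random flips are drawn and the add-one p estimator used, so the
#' corrected p can never fall below `1/(n_perm + 1)`.
#'
#' @param maps a `similarity_map`, or an n-subject-by-voxel matrix.
#' @param grid grid reference (required when `maps` is a bare matrix).
#' @param n_perm Monte-Carlo permutations (10,000 for publication use).
#' @param alpha significance level recorded in the result.
#' @param rng_seed integer seed.
#' @param tfce_params list with `E`, `H`, `dh` (NULL = max/100),
#'   `connectivity`.
#' @param exact_max_n enumerate all sign patterns when `n <= exact_max_n`.
#' @param alternative `"greater"` (default; similarity is a one-sided
#'   question) or `"two.sided"`.
#' @return A `stat_map`: list with `t` (voxel vector), `tfce`,
#'   `p_corrected`, `n_subjects`, `n_permutations`, `tfce_params`, `grid`,
#'   `alpha`, `exact`.
#' @export
group_onesample_tfce <- function(maps, grid = NULL, n_perm = 1000L,
                                 alpha = 0.05, rng_seed = 1L,
                                 tfce_params = list(E = 0.5, H = 2, dh = NULL,
                                                    connectivity = 6L),
                                 exact_max_n = 12L,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(maps, "similarity_map")) {
    grid <- grid %||% maps$grid
    maps <- maps$z
  }
  maps <- as.matrix(maps)
  if (is.null(grid)) stop_invalid("grid", "grid reference required")
  n <- nrow(maps)
  if (n < 2L) stop_invalid("maps", "need >= 2 subjects")
  if (any(!is.finite(maps))) stop_invalid("maps", "non-finite map values")
  idx <- grid_index(grid)
  E <- tfce_params$E %||% 0.5; H <- tfce_params$H %||% 2
  conn <- as.integer(tfce_params$connectivity %||% 6L)
  t_obs <- col_tstat(maps)
  t_signed <- if (alternative == "greater") pmax(t_obs, 0) else t_obs
  dh <- tfce_params$dh %||% (max(abs(t_signed)) / 100)
  enhance <- function(tv) {
    if (max(abs(tv)) == 0 || dh <= 0) return(rep(0, length(tv)))
    vol <- vol_from_vox(tv, grid)
    .tfce_cpp(as.numeric(vol), dim(vol), E, H, dh, conn)[idx]
  }
  tfce_obs <- enhance(t_signed)
  exact <- n <= exact_max_n
  set.seed(rng_seed)
  signs <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  null_max <- if (dh > 0)
    .signflip_max_tfce_cpp(maps, signs, as.integer(idx),
                           as.integer(grid$dim), E, H, dh, conn, 50,
                           alternative == "greater")
  else rep(0, nrow(signs))
  if (exact) {
    p_corr <- vapply(tfce_obs, function(v) mean(null_max >= v), numeric(1))
    n_eff <- nrow(signs)
  } else {
    p_corr <- vapply(tfce_obs, function(v)
      (1 + sum(null_max >= v)) / (n_perm + 1), numeric(1))
    n_eff <- n_perm
  }
  structure(list(t = t_obs, tfce = tfce_obs, p_corrected = p_corr,
                 n_subjects = n, n_permutations = n_eff,
                 tfce_params = list(E = E, H = H, dh = dh,
                                    connectivity = conn),
                 grid = grid, alpha = alpha, exact = exact,
                 null_max = null_max),
            class = "stat_map")
}

#' Assign voxels to templates from corrected significance maps
#'
#' A voxel is matched to every template whose corrected p falls below
#' `alpha`; multi-membership is preserved (overlapping assignments are a
#' real phenomenon, not an error). Voxels significant for no template are
#' unassigned.
#'
#' @param stat_maps named list of `stat_map`s, one per template, same grid.
#' @param alpha significance level (default 0.05).
#' @return An `assignment_map`: list with `assigned` (voxel-by-template
#'   logical matrix), `unassigned` (logical vector), `templates`, `grid`,
#'   and `argmax` (index of the most significant template per assigned
#'   voxel, for summary reporting).
#' @export
classify_voxels <- function(stat_maps, alpha = 0.05) {
  if (length(stat_maps) < 1L) stop_invalid("stat_maps", "need >= 1 map")
  g1 <- stat_maps[[1]]$grid
  for (smap in stat_maps)
    if (!identical(smap$grid$dim, g1$dim) ||
        length(smap$p_corrected) != length(stat_maps[[1]]$p_corrected))
      stop("stat maps are on different grids", call. = FALSE)
  P <- do.call(cbind, lapply(stat_maps, `[[`, "p_corrected"))
  colnames(P) <- names(stat_maps) %||% paste0("template", seq_along(stat_maps))
  assigned <- P < alpha
  argmax <- apply(P, 1, which.min)
  argmax[!apply(assigned, 1, any)] <- NA_integer_
  structure(list(assigned = assigned,
                 unassigned = !apply(assigned, 1, any),
                 templates = colnames(P), grid = g1, argmax = argmax,
                 alpha = alpha),
            class = "assignment_map")
}

#' Conjunction test: unassigned evidence exceeds every template's
#'
#' For each template `k`, a paired difference map (unassigned evidence minus
#' template-`k` similarity) per subject enters a one-sample sign-flip TFCE
#' test; the conjunction (minimum-statistic logic) keeps only voxels
#' significant in all contrasts simultaneously, i.e. voxels whose
#' connectivity is significantly greater in the unassigned map than in every
#' assigned map.
#'
#' @param unassigned_maps subject-by-voxel matrix of unassigned evidence.
#' @param assigned_maps named list of subject-by-voxel matrices (or
#'   `similarity_map`s), one per template, paired with `unassigned_maps` by
#'   row.
#' @param grid grid reference.
#' @param n_perm,alpha,rng_seed,tfce_params passed to
#'   [group_onesample_tfce()].
#' @return List with `conjunction` (logical voxel vector), `masks`
#'   (voxel-by-template logical), `stat_maps` (per-contrast `stat_map`s).
#' @export
conjunction_difference <- function(unassigned_maps, assigned_maps,
                                   grid = NULL, n_perm = 1000L, alpha = 0.05,
                                   rng_seed = 1L,
                                   tfce_params = list(E = 0.5, H = 2,
                                                      dh = NULL,
                                                      connectivity = 6L)) {
  U <- if (inherits(unassigned_maps, "similarity_map")) {
    grid <- grid %||% unassigned_maps$grid
    unassigned_maps$z
  } else as.matrix(unassigned_maps)
  smaps <- lapply(seq_along(assigned_maps), function(k) {
    A <- assigned_maps[[k]]
    if (inherits(A, "similarity_map")) {
      grid <<- grid %||% A$grid
      A <- A$z
    }
    A <- as.matrix(A)
    if (!all(dim(A) == dim(U)))
      stop("unpaired inputs: subject/voxel dimensions differ", call. = FALSE)
    group_onesample_tfce(U - A, grid = grid, n_perm = n_perm, alpha = alpha,
                         rng_seed = derive_seed(rng_seed, k),
                         tfce_params = tfce_params)
  })
  names(smaps) <- names(assigned_maps) %||%
    paste0("template", seq_along(assigned_maps))
  masks <- do.call(cbind, lapply(smaps, function(s) s$p_corrected < alpha))
  list(conjunction = apply(masks, 1, all), masks = masks, stat_maps = smaps)
}

#' Weighted summary timeseries over positively matched voxels
#'
#' Weights are `max(t, 0)` normalised to sum 1; the output series is the
#' weighted sum of voxel series (only similar voxels contribute).
#'
#' @param t_map a `stat_map` (its `t` field is used) or a numeric vector of
#'   voxel t values.
#' @param voxel_ts [region_ts()] with one column per voxel, same order.
#' @return Numeric series of length n_time.
#' @export
weighted_timeseries <- function(t_map, voxel_ts) {
  tv <- if (inherits(t_map, "stat_map")) t_map$t else as.numeric(t_map)
  X <- if (inherits(voxel_ts, "region_ts")) voxel_ts$values else
    as.matrix(voxel_ts)
  if (length(tv) != ncol(X))
    stop_invalid("voxel_ts", "one column per t value required")
  w <- pmax(tv, 0)
  if (sum(w) == 0) stop("no voxel with positive t", call. = FALSE)
  as.vector(X %*% (w / sum(w)))
}

#' Seeded whole-brain connectivity map with cluster-extent FDR
#'
#' Per subject, the weighted seed series is correlated with every brain
#' voxel and Fisher r-to-z transformed; a one-sample group t map is
#' thresholded at an uncorrected voxel p, clusters are formed by
#' connected-component labelling, the null distribution of the maximum
#' cluster size comes from sign-flip permutations, and cluster p-values are
#' corrected across observed clusters by Benjamini-Hochberg.
#'
#' @param weighted_series list (per subject) of seed summary series.
#' @param brain_voxel_ts list (per subject) of [region_ts()] over brain
#'   voxels.
#' @param grid grid reference for the brain voxels.
#' @param n_perm sign-flip permutations.
#' @param voxel_p cluster-forming uncorrected voxel threshold (default 0.001).
#' @param cluster_alpha FDR level across clusters (default 0.05).
#' @param rng_seed integer seed.
#' @param connectivity component connectivity.
#' @return List with `t`, `z` (subject-by-voxel matrix), `clusters` (integer
#'   labels per voxel), `cluster_table` (size, p, p_fdr, significant), and
#'   `significant` (logical voxel vector).
#' @export
wholebrain_connectivity_map <- function(weighted_series, brain_voxel_ts, grid,
                                        n_perm = 1000L, voxel_p = 0.001,
                                        cluster_alpha = 0.05, rng_seed = 1L,
                                        connectivity = 6L) {
  if (length(voxel_p) != 1L || voxel_p <= 0 || voxel_p >= 1)
    stop_invalid("voxel_p", "must lie in (0, 1)")
  n <- length(weighted_series)
  if (n < 2L) stop_invalid("weighted_series", "need >= 2 subjects")
  Z <- do.call(rbind, lapply(seq_len(n), function(i) {
    X <- brain_voxel_ts[[i]]
    X <- if (inherits(X, "region_ts")) X$values else as.matrix(X)
    r <- as.vector(cor(weighted_series[[i]], X))
    r[is.na(r)] <- 0
    suppressWarnings(fisher_z(r))
  }))
  t_obs <- col_tstat(Z)
  t_thresh <- qt(1 - voxel_p, df = n - 1)
  idx <- grid_index(grid)
  cluster_sizes <- function(tv) {
    vol <- vol_from_vox(tv, grid)
    lab <- label_components(vol > t_thresh, connectivity)
    list(labels = lab[idx], sizes = tabulate(lab))
  }
  obs <- cluster_sizes(t_obs)
  ssq <- colSums(Z^2)
  set.seed(rng_seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.vector(crossprod(Z, s)) / n
    v <- (ssq - n * m^2) / (n - 1)
    v[v < 0] <- 0
    tt <- m / sqrt(v / n)
    tt[v == 0] <- 0
    sz <- cluster_sizes(pmin(tt, 50))$sizes
    if (length(sz)) max(sz) else 0L
  }, numeric(1))
  if (length(obs$sizes)) {
    p_clu <- vapply(obs$sizes, function(s)
      (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
    p_fdr <- stats::p.adjust(p_clu, method = "BH")
    tab <- data.frame(cluster = seq_along(obs$sizes), size = obs$sizes,
                      p = p_clu, p_fdr = p_fdr,
                      significant = p_fdr < cluster_alpha)
  } else {
    tab <- data.frame(cluster = integer(), size = integer(), p = numeric(),
                      p_fdr = numeric(), significant = logical())
  }
  sig_clusters <- tab$cluster[tab$significant]
  list(t = t_obs, z = Z, clusters = obs$labels, cluster_table = tab,
       significant = obs$labels %in% sig_clusters)
}
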