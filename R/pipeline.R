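#' Pipeline configuration
#'
#' Defaults mirror the published analysis settings: 10,000 permutations,
#' TFCE-corrected alpha 0.05, cluster-forming voxel p 0.001 with
#' cluster-extent FDR 0.05, the 12-target reduced model (an extended
#' 17-target model differs only in fingerprint length), and per-species
#' bandpass bands.
#'
#' @param band a [bandpass_spec()] or NULL to skip filtering (synthetic
#'   white-noise data carries no drift or physiological band).
#' @param tr_seconds sampling interval.
#' @param target_model `"reduced"` (12 targets) or `"extended"` (17).
#' @param n_perm permutations for all permutation tests.
#' @param alpha TFCE-corrected significance level.
#' @param tfce_params list(E, H, dh, connectivity).
#' @param voxel_p cluster-forming threshold for whole-brain maps.
#' @param cluster_alpha cluster-extent FDR level.
#' @param condition logical; run detrend/despike/bandpass conditioning.
#' @param scale fingerprint scale for templates and distances.
#' @param rng_seed master seed; every stochastic stage derives its own
#'   stream from it and records it in the manifest.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(band = NULL, tr_seconds = 1,
                            target_model = c("reduced", "extended"),
                            n_perm = 10000L, alpha = 0.05,
                            tfce_params = list(E = 0.5, H = 2, dh = NULL,
                                               connectivity = 6L),
                            voxel_p = 0.001, cluster_alpha = 0.05,
                            condition = FALSE, scale = c("r", "fisher_z"),
                            rng_seed = 1L) {
  target_model <- match.arg(target_model)
  scale <- match.arg(scale)
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha", "must lie in (0, 1)")
  if (voxel_p <= 0 || voxel_p >= 1) stop_invalid("voxel_p", "must lie in (0, 1)")
  structure(list(band = band, tr_seconds = check_pos(tr_seconds, "tr_seconds"),
                 target_model = target_model,
                 n_targets = if (target_model == "reduced") 12L else 17L,
                 n_perm = check_count(n_perm, "n_perm"),
                 alpha = alpha, tfce_params = tfce_params,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 condition = condition, scale = scale,
                 rng_seed = check_count(rng_seed, "rng_seed", min = 0L)),
            class = "pipeline_config")
}

condition_if <- function(ts, config) {
  if (!isTRUE(config$condition)) return(ts)
  condition_timeseries(ts, config$band)
}

# Per-subject unit-by-target fingerprint matrices. Equivalent to calling
# compute_fingerprint() per unit (tested as such) but vectorised; constant
# units yield all-zero fingerprints with a warning instead of an error.
subject_fingerprints <- function(dataset, config, unit = c("seeds", "voxels")) {
  unit <- match.arg(unit)
  lapply(seq_along(dataset$subjects), function(i) {
    subj <- dataset$subjects[[i]]
    tg <- condition_if(subj$targets, config)
    src <- condition_if(subj[[unit]], config)
    r <- suppressWarnings(cor(src$values, tg$values))
    if (anyNA(r)) {
      warning(sprintf("subject %d: constant series; %d fingerprint value(s) set to 0",
                      i, sum(is.na(r))))
      r[is.na(r)] <- 0
    }
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    if (config$scale == "fisher_z") r <- atanh(r)
    r
  })
}

#' Run one cross-species fingerprint-matching comparison
#'
#' The full chain: (optional) conditioning, per-subject seed fingerprints in
#' the source species, robust-mean templates, per-subject voxelwise
#' fingerprints in the target species, similarity maps per template,
#' one-sample sign-flip TFCE inference, voxel classification
#' (matched / unassigned), the unassigned-vs-assigned conjunction, and
#' volume-fraction summaries against any supplied structure masks.
#' Unassigned evidence per voxel is `1 - max_k z_k` (one minus the best
#' template similarity), paired per subject — the published analysis does
#' not state its weighting, so this documented choice is used.
#'
#' @param source_data,target_data datasets as returned by
#'   [generate_species_dataset()] (or the same shape built from real data).
#' @param config a [pipeline_config()].
#' @param structures optional named list of logical voxel masks (target grid)
#'   for volume-fraction reporting.
#' @return A `comparison_result`: list with `templates`, `similarity`,
#'   `stat_maps`, `assignment`, `conjunction`, `volume_fractions`,
#'   `manifest`.
#' @export
run_comparison <- function(source_data, target_data, config = pipeline_config(),
                           structures = NULL) {
  src_tl <- source_data$spec$target_labels
  tgt_tl <- target_data$spec$target_labels
  if (!identical(src_tl, tgt_tl))
    stop(sprintf("target-model mismatch between species; missing targets: %s",
                 paste(union(setdiff(src_tl, tgt_tl), setdiff(tgt_tl, src_tl)),
                       collapse = ", ")), call. = FALSE)
  seed_names <- names(source_data$spec$seed_defs)
  # source species: per-subject seed fingerprints -> robust-mean templates
  seed_fp <- subject_fingerprints(source_data, config, "seeds")
  templates <- lapply(seq_along(seed_names), function(k) {
    fps <- lapply(seq_along(seed_fp), function(i)
      fingerprint(seed_fp[[i]][k, ], src_tl, config$scale, paste0("s", i)))
    tpl <- robust_mean_template(fps)
    attr(tpl, "id") <- seed_names[k]
    tpl
  })
  names(templates) <- seed_names
  # target species: voxel fingerprints -> similarity map per template
  vox_fp <- subject_fingerprints(target_data, config, "voxels")
  grid <- list(dim = target_data$grid$dim, coords = target_data$grid$coords)
  similarity <- lapply(templates, function(tpl)
    voxelwise_similarity_map(vox_fp, tpl, grid))
  stat_maps <- lapply(seq_along(similarity), function(k)
    group_onesample_tfce(similarity[[k]], n_perm = config$n_perm,
                         alpha = config$alpha,
                         rng_seed = derive_seed(config$rng_seed, k),
                         tfce_params = config$tfce_params))
  names(stat_maps) <- seed_names
  assignment <- classify_voxels(stat_maps, config$alpha)
  # conjunction: unassigned evidence = 1 - best template similarity
  zmax <- Reduce(pmax, lapply(similarity, `[[`, "z"))
  conjunction <- conjunction_difference(
    1 - zmax, lapply(similarity, `[[`, "z"), grid = grid,
    n_perm = config$n_perm, alpha = config$alpha,
    rng_seed = derive_seed(config$rng_seed, 100L),
    tfce_params = config$tfce_params)
  vf <- NULL
  if (!is.null(structures)) {
    labels <- c(lapply(seq_along(seed_names), function(k)
      assignment$assigned[, k]),
      list(assignment$unassigned))
    names(labels) <- c(seed_names, "unassigned")
    vf <- volume_fractions(labels, structures)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fingermatch")),
    config = config[setdiff(names(config), "band")],
    band = if (!is.null(config$band)) unclass(config$band),
    seeds = list(master = config$rng_seed,
                 stat_maps = vapply(seq_along(seed_names), function(k)
                   derive_seed(config$rng_seed, k), integer(1)),
                 conjunction = derive_seed(config$rng_seed, 100L)),
    n_subjects = c(source = length(source_data$subjects),
                   target = length(target_data$subjects)),
    n_voxels = nrow(grid$coords),
    templates = lapply(templates, `[[`, "values"))
  structure(list(templates = templates, similarity = similarity,
                 stat_maps = stat_maps, assignment = assignment,
                 conjunction = conjunction, volume_fractions = vf,
                 manifest = manifest),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  n <- length(x$assignment$unassigned)
  cat(sprintf("<comparison_result> %d voxels, %d templates\n", n,
              length(x$templates)))
  for (k in seq_along(x$templates))
    cat(sprintf("  %-12s assigned %4d voxels (%.1f%%)\n",
                x$assignment$templates[k], sum(x$assignment$assigned[, k]),
                100 * mean(x$assignment$assigned[, k])))
  cat(sprintf("  %-12s %13d voxels (%.1f%%)\n", "unassigned",
              sum(x$assignment$unassigned), 100 * mean(x$assignment$unassigned)))
  cat(sprintf("  %-12s %13d voxels (%.1f%%)\n", "sig. diff.",
              sum(x$conjunction$conjunction),
              100 * mean(x$conjunction$conjunction)))
  invisible(x)
}

#' Write the reports of a comparison run
#'
#' Emits the manifest (JSON), template fingerprints (CSV), assignment
#' summary (CSV), and any volume fractions (CSV) under a directory.
#'
#' @param result a `comparison_result`.
#' @param out_dir output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
write_comparison <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(manifest = file.path(out_dir, "manifest.json"),
             templates = file.path(out_dir, "templates.csv"),
             assignment = file.path(out_dir, "assignment.csv"))
  jsonlite::write_json(result$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  tpl <- do.call(rbind, lapply(names(result$templates), function(k) {
    t <- result$templates[[k]]
    data.frame(seed = k, target = t$target_labels, value = t$values,
               dispersion = t$dispersion, scale = t$scale)
  }))
  write.csv(tpl, paths[["templates"]], row.names = FALSE)
  asg <- data.frame(voxel = seq_along(result$assignment$unassigned),
                    result$assignment$assigned,
                    unassigned = result$assignment$unassigned,
                    significantly_different = result$conjunction$conjunction,
                    check.names = FALSE)
  write.csv(asg, paths[["assignment"]], row.names = FALSE)
  if (!is.null(result$volume_fractions)) {
    paths <- c(paths, volume_fractions = file.path(out_dir,
                                                   "volume_fractions.csv"))
    write.csv(result$volume_fractions, paths[["volume_fractions"]],
              row.names = FALSE)
  }
  invisible(paths)
}
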