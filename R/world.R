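#' Default 12-target seed loading matrix
#'
#' Three circuits, each loading unit weight on a disjoint block of four of
#' the twelve targets — orthogonal by construction, so each planted
#' fingerprint is maximally distinct in target space.
#'
#' @param n_targets 12 (reduced model) or 17 (extended; the five extra
#'   targets carry zero loading, mirroring targets present in only some
#'   species pairs).
#' @return A 3 x n_targets matrix with rownames `seed1..seed3`.
#' @export
default_seed_loadings <- function(n_targets = 12L) {
  n_targets <- check_count(n_targets, "n_targets", min = 12L)
  W <- matrix(0, 3, n_targets,
              dimnames = list(paste0("seed", 1:3),
                              paste0("target", seq_len(n_targets))))
  for (k in 1:3) W[k, seq(4 * (k - 1) + 1, 4 * k)] <- 1
  W
}

#' The planted two-species shared-circuit world
#'
#' Builds paired synthetic datasets for one cross-species comparison: a
#' source species carrying three seed circuits, and a target species whose
#' striatal voxels belong to `n_shared` of those circuits plus one "unique"
#' circuit orthogonal to all three — the configuration in which matching
#' should assign shared-circuit voxels to the correct template, leave unique
#' voxels unassigned, and let the conjunction flag exactly the unique
#' circuit.
#'
#' @param n_subjects subjects per species (default 20, a typical
#'   animal-cohort size).
#' @param n_timepoints timepoints (default 500).
#' @param tr_seconds sampling interval (default 1).
#' @param n_shared shared circuits, 0..3 (default 2).
#' @param voxels_per_circuit target-species voxels per circuit block
#'   (default 64 = a 4x4x4 box).
#' @param noise_sd mixture noise sd (default 1; with unit loadings on four
#'   targets this puts each planted seed-target correlation at
#'   `1/sqrt(5) ~ 0.447`, a realistic rsfMRI effect size).
#' @param n_targets 12 or 17.
#' @param rng_seed master seed; the two species get derived streams.
#' @return List with `source`, `target` (datasets as from
#'   [generate_species_dataset()]) and `truth` (target voxel circuit labels,
#'   `shared_seeds`, `unique_label`).
#' @export
shared_circuit_world <- function(n_subjects = 20L, n_timepoints = 500L,
                                 tr_seconds = 1, n_shared = 2L,
                                 voxels_per_circuit = 64L, noise_sd = 1,
                                 n_targets = 12L, rng_seed = 1L) {
  if (n_shared < 0L || n_shared > 3L)
    stop_invalid("n_shared", "must lie in 0..3")
  W <- default_seed_loadings(n_targets)
  targets <- colnames(W)
  seed_defs <- stats::setNames(lapply(1:3, function(k) W[k, ]), rownames(W))
  shared <- rownames(W)[seq_len(n_shared)]
  tgt_labels <- c(rep(shared, each = voxels_per_circuit),
                  rep("unique", voxels_per_circuit * (3L - n_shared)))
  src <- species_sim_spec(
    n_subjects = n_subjects, n_timepoints = n_timepoints,
    tr_seconds = tr_seconds, target_labels = targets,
    seed_defs = seed_defs, voxel_labels = rownames(W),
    noise_sd = noise_sd, rng_seed = derive_seed(rng_seed, 1L))
  tgt <- species_sim_spec(
    n_subjects = n_subjects, n_timepoints = n_timepoints,
    tr_seconds = tr_seconds, target_labels = targets,
    seed_defs = seed_defs, voxel_labels = tgt_labels,
    noise_sd = noise_sd, rng_seed = derive_seed(rng_seed, 2L))
  list(source = generate_species_dataset(src),
       target = generate_species_dataset(tgt),
       truth = list(voxel_circuit = tgt_labels, shared_seeds = shared,
                    unique_label = "unique"))
}
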