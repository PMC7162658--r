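#' Z-score a tracer connectome per injection
#'
#' Standardises every injection row across voxels (population sd), mirroring
#' z-transformed terminal tracer volume. A constant row cannot be
#' standardised and is an error.
#'
#' @param raw an injection-by-voxel matrix or a `tracer_connectome`.
#' @return A `tracer_connectome` with `zscored = TRUE`.
#' @export
zscore_connectome <- function(raw) {
  conn <- if (inherits(raw, "tracer_connectome")) raw else
    structure(list(strengths = as.matrix(raw),
                   injection_labels = rownames(raw) %||%
                     paste0("inj", seq_len(nrow(raw))),
                   voxel_coordinates = NULL, grid_dim = NULL,
                   zscored = FALSE), class = "tracer_connectome")
  X <- conn$strengths
  mu <- rowMeans(X)
  sdp <- sqrt(rowMeans((X - mu)^2))  # population sd
  bad <- which(sdp == 0)
  if (length(bad))
    stop(sprintf("constant injection row(s): %s",
                 paste(conn$injection_labels[bad], collapse = ", ")),
         call. = FALSE)
  conn$strengths <- (X - mu) / sdp
  conn$zscored <- TRUE
  conn
}

#' Voxel-by-voxel similarity of connectivity fingerprints
#'
#' Pearson correlation between voxel columns of the (z-scored) connectome;
#' the similarity of two voxels' injection profiles. Constant voxel columns
#' cannot be correlated: they are excluded with a warning and recorded in the
#' `excluded` attribute.
#'
#' @param conn a `tracer_connectome` (z-scored first via
#'   [zscore_connectome()] if not already).
#' @return A symmetric voxel-by-voxel correlation matrix with unit diagonal;
#'   attribute `excluded` holds indices of dropped constant voxels.
#' @export
fingerprint_similarity_matrix <- function(conn) {
  if (!inherits(conn, "tracer_connectome")) conn <- zscore_connectome(conn)
  if (!isTRUE(conn$zscored)) conn <- zscore_connectome(conn$strengths)
  X <- conn$strengths
  if (nrow(X) < 2L) stop_invalid("conn", "need >= 2 injections")
  sds <- apply(X, 2, sd)
  excluded <- which(sds == 0)
  if (length(excluded)) {
    warning(sprintf("excluding %d constant voxel column(s): %s",
                    length(excluded),
                    paste(head(excluded, 10), collapse = ", ")))
    X <- X[, -excluded, drop = FALSE]
  }
  r <- cor(X)
  diag(r) <- 1
  attr(r, "excluded") <- excluded
  r
}

#' Hierarchical connectivity-based parcellation with silhouette selection
#'
#' Agglomerative clustering of voxels on the distance `d = 1 - r`, labels at
#' every `k` in `k_range` by cutting the dendrogram, mean silhouette width
#' (same distance) per `k`, and the selected `k` as the silhouette argmax
#' with ties broken toward smaller `k`.
#'
#' @param sim voxel-by-voxel correlation matrix (e.g. from
#'   [fingerprint_similarity_matrix()]).
#' @param k_range integer vector of candidate cluster counts (default 2:10).
#' @param linkage `"average"` (default, the common choice for correlation
#'   distances) or `"ward.D2"` behind the same interface.
#' @return A `parcellation`: list with `labels` (for the selected `k`),
#'   `k`, `labels_by_k`, `silhouette_by_k`, `linkage_record` (the hclust
#'   merge history), and `degenerate` (TRUE when all distances collapse to
#'   zero, in which case no `k` is selected).
#' @export
hierarchical_parcellation <- function(sim, k_range = 2:10,
                                      linkage = c("average", "ward.D2")) {
  linkage <- match.arg(linkage)
  n <- nrow(sim)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop_invalid("k_range", "must be non-empty")
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_invalid("k_range", sprintf("must lie within [2, %d]", n - 1L))
  d <- 1 - sim
  diag(d) <- 0
  d[d < 0] <- 0
  if (max(d) < 1e-12) {
    return(structure(list(labels = rep(1L, n), k = NA_integer_,
                          labels_by_k = NULL, silhouette_by_k = NULL,
                          linkage_record = NULL, degenerate = TRUE),
                     class = "parcellation"))
  }
  hc <- hclust(stats::as.dist(d), method = linkage)
  labels_by_k <- lapply(k_range, function(k) cutree(hc, k = k))
  names(labels_by_k) <- k_range
  sil <- vapply(labels_by_k, function(lab) {
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(sil)]  # which.max takes the first (smallest k) tie
  structure(list(labels = labels_by_k[[as.character(best)]],
                 k = best, labels_by_k = labels_by_k,
                 silhouette_by_k = sil, linkage_record = hc,
                 degenerate = FALSE),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("<parcellation> degenerate (no structure)\n")
  else cat(sprintf("<parcellation> %d voxels, selected k = %d (silhouette %.3f)\n",
                   length(x$labels), x$k, max(x$silhouette_by_k, na.rm = TRUE)))
  invisible(x)
}

#' Dice overlap between two parcellations of the same voxels
#'
#' Dice(a, b) = 2|a n b| / (|a| + |b|) for every cluster pair, plus a greedy
#' matching that pairs clusters by descending Dice without reuse.
#'
#' @param parcA,parcB `parcellation` objects (or bare label vectors) over the
#'   same voxel set.
#' @return A list with `dice` (cluster-pair matrix) and `matching`
#'   (data.frame of matched `cluster_a`, `cluster_b`, `dice`).
#' @export
dice_overlap <- function(parcA, parcB) {
  la <- if (inherits(parcA, "parcellation")) parcA$labels else parcA
  lb <- if (inherits(parcB, "parcellation")) parcB$labels else parcB
  if (length(la) != length(lb))
    stop("parcellations cover different voxel sets", call. = FALSE)
  ca <- sort(unique(la)); cb <- sort(unique(lb))
  dice <- matrix(0, length(ca), length(cb), dimnames = list(ca, cb))
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    A <- la == ca[i]; B <- lb == cb[j]
    dice[i, j] <- 2 * sum(A & B) / (sum(A) + sum(B))
  }
  m <- dice
  match_rows <- list()
  while (nrow(m) > 0L && ncol(m) > 0L) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    match_rows[[length(match_rows) + 1L]] <-
      data.frame(cluster_a = rownames(m)[ij[1]], cluster_b = colnames(m)[ij[2]],
                 dice = m[ij[1], ij[2]])
    m <- m[-ij[1], -ij[2], drop = FALSE]
  }
  list(dice = dice, matching = do.call(rbind, match_rows))
}

#' Erode a voxel mask by one voxel
#'
#' Optional border-voxel exclusion: removes mask voxels with any
#' 6-neighbour outside the mask, guarding parcellations against signal
#' contamination from bordering structures.
#'
#' @param mask logical 3D array.
#' @return The eroded logical array.
#' @export
erode_mask <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  keep <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    keep <- keep & padded[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2],
                          2:(d[3] + 1) + sh[3]]
  }
  keep
}
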