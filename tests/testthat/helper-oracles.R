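# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (brute force, closed form,
# or a different library), so agreement is evidence, not tautology.

# TFCE by explicit per-threshold connected-component labelling via igraph.
tfce_oracle <- function(vol, E = 0.5, H = 2, dh = NULL, connectivity = 6L) {
  d <- dim(vol)
  vmax <- max(abs(vol))
  if (vmax == 0) return(vol * 0)
  if (is.null(dh)) dh <- vmax / 100
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  deg <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[deg > 0 & deg <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
  one_side <- function(v) {
    out <- array(0, d)
    nsteps <- floor(max(v) / dh + 1e-9)
    if (nsteps < 1) return(out)
    coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                    z = seq_len(d[3])))
    for (s in seq_len(nsteps)) {
      h <- s * dh
      act <- which(v >= h)
      if (!length(act)) next
      key <- function(m) paste(m[, 1], m[, 2], m[, 3])
      idx_of <- stats::setNames(seq_along(act), key(coords[act, , drop = FALSE]))
      edges <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(coords[act, , drop = FALSE], 2,
                    as.numeric(offs[o, ]), `+`)
        j <- idx_of[key(nb)]
        ok <- !is.na(j)
        if (any(ok)) edges <- c(edges, rbind(which(ok), j[ok]))
      }
      g <- igraph::make_graph(edges, n = length(act), directed = FALSE)
      comp <- igraph::components(g)
      ext <- comp$csize[comp$membership]
      out[act] <- out[act] + ext^E * h^H * dh
    }
    out
  }
  pos <- vol; pos[pos < 0] <- 0
  neg <- -vol; neg[neg < 0] <- 0
  one_side(pos) - one_side(neg)
}

# Exhaustive average-linkage agglomeration straight from the distance matrix.
naive_average_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > k) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      v <- avg_dist(clusters[[i]], clusters[[j]])
      if (v < bestv) { bestv <- v; best <- c(j, i) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# |H(f)| evaluated directly from filter coefficients (frequency-response
# oracle; f in cycles per sample).
hmag <- function(b, a, f) {
  z <- exp(-2i * pi * f)
  num <- vapply(z, function(e) sum(b * e^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(e) sum(a * e^(seq_along(a) - 1)), complex(1))
  abs(num / den)
}

# Small fingerprint-list builder around plain matrices.
fps_from_matrix <- function(M, targets = paste0("t", seq_len(ncol(M))),
                            scale = "r") {
  lapply(seq_len(nrow(M)), function(i)
    fingerprint(M[i, ], targets, scale, paste0("s", i)))
}

expect_perm_equal_labels <- function(a, b) {
  expect_equal(adjusted_rand_index(a, b), 1)
}
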