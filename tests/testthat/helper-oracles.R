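# Independent oracles used by the unit and acceptance tests. Each recomputes
# a quantity by a method unrelated to the implementation it checks.

# --- Brute-force rotation-grid RMSD oracle -------------------------------
# Minimum RMSD over rigid motions by exhaustive search on an axis-angle
# grid (coarse global pass, then a 1-degree local refinement around the
# best rotation). Translation is optimal at fixed rotation when centroids
# coincide, so both point sets are centred first.

.rodrigues <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.grid_axes <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

bruteforce_rmsd <- function(P, Q, coarse_axes = 400L, coarse_deg = 9,
                            refine_deg = 1) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  n <- nrow(P)
  eval_rot <- function(R) sqrt(sum((P %*% t(R) - Q)^2) / n)
  best <- Inf; best_axis <- c(0, 0, 1); best_theta <- 0
  axes <- .grid_axes(coarse_axes)
  thetas <- seq(0, 2 * pi, by = coarse_deg * pi / 180)
  for (k in seq_len(nrow(axes))) {
    for (th in thetas) {
      v <- eval_rot(.rodrigues(axes[k, ], th))
      if (v < best) { best <- v; best_axis <- axes[k, ]; best_theta <- th }
    }
  }
  # local refinement: tilt the axis on a fine tangent grid, fine angles
  ref <- if (abs(best_axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - best_axis * sum(ref * best_axis); u <- u / sqrt(sum(u^2))
  v <- c(best_axis[2] * u[3] - best_axis[3] * u[2],
         best_axis[3] * u[1] - best_axis[1] * u[3],
         best_axis[1] * u[2] - best_axis[2] * u[1])
  tilt <- seq(-coarse_deg, coarse_deg, by = refine_deg) * pi / 180
  fine <- seq(best_theta - coarse_deg * pi / 180,
              best_theta + coarse_deg * pi / 180, by = refine_deg * pi / 180)
  for (du in tilt) for (dv in tilt) {
    ax <- best_axis + du * u + dv * v
    for (th in fine) {
      val <- eval_rot(.rodrigues(ax, th))
      if (val < best) best <- val
    }
  }
  best
}

# --- Naive average-linkage agglomeration oracle --------------------------
# Recomputes every inter-cluster average linkage directly from the raw
# distance matrix at each step (no Lance-Williams update); merges the
# closest pair (ties: smallest minimum member, then smallest of the other
# cluster) while the minimum linkage is within the cutoff.
naive_average_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      link <- mean(d[clusters[[i]], clusters[[j]]])
      key <- c(link, min(clusters[[i]]), min(clusters[[j]]))
      if (is.null(best) ||
          link < best$key[1] - 1e-12 ||
          (abs(link - best$key[1]) <= 1e-12 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3]))))
        best <- list(i = i, j = j, key = key)
    }
    if (best$key[1] > cutoff) break
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  assignment
}

# Canonical form of a partition (labels in order of first appearance), for
# comparing partitions up to relabelling.
canonical_partition <- function(assignment) {
  as.integer(factor(assignment, levels = unique(assignment)))
}

# --- Spherical-cap SASA oracle -------------------------------------------
# Exact accessible area of a sphere of radius R clipped by one neighbour
# sphere of radius Rn at centre distance dist.
cap_sasa <- function(R, Rn, dist) {
  if (dist >= R + Rn) return(4 * pi * R^2)
  # height of the buried cap on the first sphere
  h <- R - (dist^2 + R^2 - Rn^2) / (2 * dist)
  h <- min(max(h, 0), 2 * R)
  4 * pi * R^2 - 2 * pi * R * h
}
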