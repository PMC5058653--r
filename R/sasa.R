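# Shrake-Rupley solvent-accessible surface area. Deterministic golden-spiral
# sphere points (no randomness), water-mimicking probe of 1.4 A by default,
# and a trajectory-averaged lysine sidechain exposure (ASASA) used as the
# cross-linker reactivity descriptor.

# Canonical molecular pose: centroid at the origin, principal axes of the
# coordinate covariance as the lab frame (signs fixed deterministically,
# proper rotation). Makes the quadrature, and hence the SASA values,
# invariant under rigid transformation of the input.
.canonical_pose <- function(xyz) {
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2L, ctr)
  if (nrow(X) < 2L) return(X)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    # orient each axis by the third moment of the projections: a property
    # of the molecule, not of the incoming lab frame
    proj <- X %*% V[, k]
    m3 <- sum(proj^3)
    if (abs(m3) < 1e-9) m3 <- proj[which.max(abs(proj))]
    if (m3 < 0) V[, k] <- -V[, k]
  }
  V[, 3L] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
               V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
               V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  X %*% V
}

# n deterministic, near-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For every atom, `n_points` test points are placed on a deterministic
#' golden-spiral sphere of radius `vdw + probe_radius`; a point is accessible
#' if it lies outside every other atom's expanded sphere, and the atom's SASA
#' is `4 pi R^2 * accessible / n_points`. The neighbour search is restricted
#' to atoms whose expanded spheres can overlap.
#'
#' @param conformer a `Conformer`.
#' @param probe_radius probe radius in Angstrom (default 1.4, a water
#'   mimicking probe).
#' @param n_points sphere points per atom (default 960; quadrature error on
#'   an isolated sphere is below 1 percent).
#' @param atom_subset optional integer indices: compute SASA only for these
#'   atoms (all atoms still act as occluders). Used for the lysine-only
#'   trajectory average.
#' @details Coordinates are first brought to a canonical pose (centroid at
#'   the origin, principal axes as the frame), so the computed areas are
#'   invariant under rigid transformation of the input conformer.
#' @return object of class `SasaResult`: list with `per_atom` (A^2 per atom,
#'   NA outside `atom_subset` when given), `per_residue_sidechain` (named by
#'   residue number: sum over that residue's sidechain atoms),
#'   `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(conformer, probe_radius = 1.4, n_points = 960L,
                          atom_subset = NULL) {
  top <- conformer$topology
  n <- nrow(conformer$xyz)
  if (!n) stop("empty conformer", call. = FALSE)
  if (n_points < 12L) stop("n_points must be >= 12", call. = FALSE)
  xyz <- .canonical_pose(conformer$xyz)
  radii <- top$vdw_radius + probe_radius
  sphere <- .sphere_points(n_points)
  targets <- if (is.null(atom_subset)) seq_len(n) else as.integer(atom_subset)

  per_atom <- rep(NA_real_, n)
  for (i in targets) {
    Ri <- radii[i]
    # neighbours whose expanded sphere can clip atom i's surface
    dx <- xyz[, 1L] - xyz[i, 1L]
    dy <- xyz[, 2L] - xyz[i, 2L]
    dz <- xyz[, 3L] - xyz[i, 3L]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (Ri + radii)^2)
    nb <- nb[nb != i]
    pts <- sphere * Ri
    pts <- cbind(pts[, 1L] + xyz[i, 1L], pts[, 2L] + xyz[i, 2L],
                 pts[, 3L] + xyz[i, 3L])
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      ddx <- pts[accessible, 1L] - xyz[j, 1L]
      ddy <- pts[accessible, 2L] - xyz[j, 2L]
      ddz <- pts[accessible, 3L] - xyz[j, 3L]
      buried <- (ddx * ddx + ddy * ddy + ddz * ddz) < radii[j]^2
      accessible[accessible] <- !buried
    }
    per_atom[i] <- 4 * pi * Ri^2 * sum(accessible) / n_points
  }

  side <- !(top$atom_name %in% .BACKBONE_ATOMS)
  resnos <- unique(top$residue_number)
  per_res <- vapply(resnos, function(r) {
    idx <- which(top$residue_number == r & side)
    idx <- idx[idx %in% targets]
    if (!length(idx)) 0 else sum(per_atom[idx])
  }, numeric(1))
  names(per_res) <- resnos
  structure(list(per_atom = per_atom, per_residue_sidechain = per_res,
                 probe_radius = probe_radius, n_points = as.integer(n_points)),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  tot <- sum(x$per_atom, na.rm = TRUE)
  cat("SasaResult: ", sum(!is.na(x$per_atom)), " atoms, total ",
      round(tot, 1), " A^2 (probe ", x$probe_radius, " A, ",
      x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Trajectory-averaged lysine sidechain exposure (ASASA)
#'
#' For every lysine in the ensemble, the mean over frames of its sidechain
#' solvent-accessible surface area: the exposure descriptor for NHS-ester
#' cross-linker adduct propensity. Only the lysine sidechain atoms are
#' integrated, but every heavy atom of the structure occludes.
#'
#' @param ensemble an `Ensemble` containing at least one Lys residue.
#' @param probe_radius probe radius (A).
#' @param n_points sphere points per atom.
#' @return data.frame with columns `residue_number`, `residue_name`,
#'   `asasa` (A^2). Zero rows (with a warning) when no lysine is present.
#' @export
lysine_asasa <- function(ensemble, probe_radius = 1.4, n_points = 960L) {
  top <- ensemble$topology
  lys_res <- unique(top$residue_number[top$residue_name == "LYS"])
  if (!length(lys_res)) {
    warning("no lysine residues in the ensemble", call. = FALSE)
    return(data.frame(residue_number = integer(), residue_name = character(),
                      asasa = numeric(), stringsAsFactors = FALSE))
  }
  side_idx <- which(top$residue_number %in% lys_res &
                    !(top$atom_name %in% .BACKBONE_ATOMS))
  acc <- matrix(0, nrow = n_frames(ensemble), ncol = length(lys_res),
                dimnames = list(NULL, lys_res))
  for (f in seq_len(n_frames(ensemble))) {
    sr <- shrake_rupley(get_frame(ensemble, f), probe_radius = probe_radius,
                        n_points = n_points, atom_subset = side_idx)
    acc[f, ] <- sr$per_residue_sidechain[as.character(lys_res)]
  }
  data.frame(residue_number = lys_res,
             residue_name = "LYS",
             asasa = colMeans(acc),
             stringsAsFactors = FALSE, row.names = NULL)
}
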