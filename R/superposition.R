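# Optimal rigid-body superposition (Kabsch) and RMSd over atom selections.
# Fit and measure selections are deliberately separate: conformer clustering
# uses fit = measure = backbone, while the fragment/protein cross matrix fits
# on the mapped backbone and measures over all mapped heavy atoms.

#' Kabsch optimal superposition
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `target`, via SVD of the covariance of the centred point sets. The
#' reflection case (negative determinant) is corrected by flipping the sign
#' of the smallest singular vector, so the returned rotation is always
#' proper (det = +1).
#'
#' @param mobile,target n x 3 coordinate matrices with corresponding rows,
#'   n >= 3, not all collinear.
#' @return object of class `RigidTransform` with fields `rotation` (3 x 3)
#'   and `translation` (length 3): the map is `x %*% t(rotation) +
#'   translation`.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)) || ncol(mobile) != 3L)
    stop("mobile and target must be n x 3 matrices of equal size",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate input: need at least 3 points", call. = FALSE)
  mc <- colMeans(mobile); tc <- colMeans(target)
  P <- sweep(mobile, 2L, mc); Q <- sweep(target, 2L, tc)
  if (.is_collinear(P) || .is_collinear(Q))
    stop("degenerate input: points are collinear", call. = FALSE)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  structure(list(rotation = R, translation = as.numeric(tc - R %*% mc)),
            class = "RigidTransform")
}

.is_collinear <- function(X, tol = 1e-8) {
  # X already centred
  s <- svd(X, nu = 0L, nv = 0L)$d
  s[2L] <= tol * max(s[1L], 1)
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat("RigidTransform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation: ", paste(round(x$translation, 6), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform a `RigidTransform`.
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2L, -transform$translation)
}

# Internal: RMSd between two coordinate matrices after Kabsch fit on the
# `fit` rows, measured over the `measure` rows. Assumes matching dims.
.rmsd_fit_measure <- function(axyz, bxyz, fit, measure) {
  tr <- kabsch(axyz[fit, , drop = FALSE], bxyz[fit, , drop = FALSE])
  am <- apply_transform(tr, axyz[measure, , drop = FALSE])
  d <- am - bxyz[measure, , drop = FALSE]
  sqrt(sum(d * d) / nrow(d))
}

#' RMSd between two conformers over atom selections
#'
#' Superposes `a` onto `b` on `fit_selection` (Kabsch), then computes the
#' root-mean-square deviation over `measure_selection`. Both selections are
#' index vectors referring to corresponding atoms in both conformers.
#'
#' @param a,b `Conformer` objects with corresponding atoms at the selected
#'   indices.
#' @param fit_selection atom indices used for the superposition; defaults to
#'   all atoms.
#' @param measure_selection atom indices the deviation is measured over;
#'   defaults to `fit_selection`.
#' @return RMSd in Angstrom.
#' @export
rmsd <- function(a, b, fit_selection = NULL, measure_selection = NULL) {
  axyz <- a$xyz; bxyz <- b$xyz
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(axyz))
  if (is.null(measure_selection)) measure_selection <- fit_selection
  if (!length(fit_selection) || !length(measure_selection))
    stop("fit and measure selections must be non-empty", call. = FALSE)
  if (max(fit_selection, measure_selection) > min(nrow(axyz), nrow(bxyz)))
    stop("selection index out of range", call. = FALSE)
  .rmsd_fit_measure(axyz, bxyz, fit_selection, measure_selection)
}

#' Align an ensemble to its converged mean structure
#'
#' Iteratively superposes every frame onto the running mean structure
#' (initialised to frame 1) on the given selection, recomputing the mean
#' until the mean coordinates shift by less than `tol` Angstrom or
#' `max_iter` iterations are reached.
#'
#' @param ensemble an `Ensemble` with at least 2 frames.
#' @param fit_selection selection keyword passed to [select_atoms()]
#'   (default `"backbone"`).
#' @param tol convergence threshold on the maximum mean-coordinate shift
#'   (Angstrom).
#' @param max_iter iteration cap.
#' @return list with `ensemble` (aligned frames), `mean` (a `Conformer` of
#'   the converged mean coordinates) and `iterations`.
#' @export
align_ensemble <- function(ensemble, fit_selection = "backbone",
                           tol = 1e-6, max_iter = 10L) {
  stopifnot(inherits(ensemble, "Ensemble"))
  if (n_frames(ensemble) < 2L)
    stop("alignment needs at least 2 frames", call. = FALSE)
  fit <- select_atoms(ensemble, fit_selection)
  frames <- ensemble$frames
  mean_xyz <- frames[[1L]]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    frames <- lapply(frames, function(f) {
      tr <- kabsch(f[fit, , drop = FALSE], mean_xyz[fit, , drop = FALSE])
      apply_transform(tr, f)
    })
    new_mean <- Reduce(`+`, frames) / length(frames)
    shift <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  dimnames(mean_xyz) <- list(NULL, c("x", "y", "z"))
  list(ensemble = .ensemble_from_xyz(ensemble$topology, frames,
                                     label = ensemble$label),
       mean = structure(list(topology = ensemble$topology, xyz = mean_xyz),
                        class = "Conformer"),
       iterations = iterations)
}
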