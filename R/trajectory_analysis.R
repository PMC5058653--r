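# Trajectory-level analyses: residue fluctuation (RMSF) profiles, pairwise
# and cross-ensemble RMSd matrices, the fraction-in-range statistic, and
# average-linkage agglomerative clustering with medoid representatives.

#' Residue fluctuation analysis (RMSF)
#'
#' Aligns the ensemble to its converged mean structure (backbone fit), then
#' computes for each residue the root-mean-square fluctuation of its basis
#' atoms about their mean positions:
#' `RMSF_r = sqrt(mean_f mean_a |x_fa - xbar_a|^2)`.
#'
#' @param ensemble an `Ensemble` with at least 2 frames.
#' @param atom_basis `"calpha"` (default: the standard per-residue
#'   fluctuation measure) or `"residue_heavy"` (all heavy atoms of the
#'   residue).
#' @param align whether to align the ensemble first (default TRUE; set FALSE
#'   only if the frames are already superposed).
#' @return a `FluctuationProfile`: data.frame with columns `residue_number`
#'   and `rmsf` (A), with the basis recorded in attribute `atom_basis`.
#' @export
residue_fluctuation <- function(ensemble,
                                atom_basis = c("calpha", "residue_heavy"),
                                align = TRUE) {
  atom_basis <- match.arg(atom_basis)
  if (n_frames(ensemble) < 2L)
    stop("residue fluctuation needs at least 2 frames", call. = FALSE)
  if (align) ensemble <- align_ensemble(ensemble, "backbone")$ensemble
  top <- ensemble$topology
  basis <- if (atom_basis == "calpha") which(top$atom_name == "CA")
           else seq_len(nrow(top))
  X <- array(unlist(ensemble$frames, use.names = FALSE),
             dim = c(nrow(top), 3L, n_frames(ensemble)))
  Xb <- X[basis, , , drop = FALSE]
  mean_xyz <- apply(Xb, c(1L, 2L), mean)
  dev2 <- sweep(Xb, c(1L, 2L), mean_xyz)^2
  msd_atom <- apply(dev2, 1L, sum) / n_frames(ensemble)  # per-atom MSD
  resno <- top$residue_number[basis]
  msd_res <- tapply(msd_atom, resno, mean)
  out <- data.frame(residue_number = as.integer(names(msd_res)),
                    rmsf = sqrt(as.numeric(msd_res)),
                    row.names = NULL)
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "atom_basis") <- atom_basis
  class(out) <- c("FluctuationProfile", "data.frame")
  out
}

# Precompute per-frame centred fit/measure coordinate blocks for fast
# repeated Kabsch fits. The measure block is centred on the *fit* centroid
# so the fitted transform applies directly.
.prep_frames <- function(frames, fit, measure) {
  lapply(frames, function(xyz) {
    ctr <- colMeans(xyz[fit, , drop = FALSE])
    list(fit = sweep(xyz[fit, , drop = FALSE], 2L, ctr),
         measure = sweep(xyz[measure, , drop = FALSE], 2L, ctr))
  })
}

# RMSd between two prepped frames (fit by Kabsch, measured on measure block).
.rmsd_prepped <- function(a, b) {
  s <- svd(crossprod(a$fit, b$fit))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dif <- a$measure %*% t(R) - b$measure
  sqrt(sum(dif * dif) / nrow(dif))
}

.new_rmsd_matrix <- function(values, fit, measure, symmetric) {
  structure(list(values = values, fit = fit, measure = measure,
                 symmetric = symmetric),
            class = "RmsdMatrix")
}

#' @export
print.RmsdMatrix <- function(x, ...) {
  cat("RmsdMatrix: ", nrow(x$values), " x ", ncol(x$values),
      if (x$symmetric) " (symmetric)", ", fit = ", x$fit,
      ", measure = ", x$measure, "\n", sep = "")
  v <- if (x$symmetric) x$values[upper.tri(x$values)] else x$values
  if (length(v))
    cat("  range ", round(min(v), 3), " - ", round(max(v), 3), " A, mean ",
        round(mean(v), 3), " A\n", sep = "")
  invisible(x)
}

#' Frame-vs-frame RMSd matrix of one ensemble
#'
#' Symmetric, zero-diagonal matrix of pairwise RMSd values; by default fit
#' and measure are both the backbone selection (the clustering convention).
#'
#' @param ensemble an `Ensemble` with >= 2 frames.
#' @param fit,measure selection keywords for [select_atoms()].
#' @return an `RmsdMatrix` with a square symmetric `values` field.
#' @export
pairwise_rmsd_matrix <- function(ensemble, fit = "backbone", measure = fit) {
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  fidx <- select_atoms(ensemble, fit)
  midx <- select_atoms(ensemble, measure)
  pp <- .prep_frames(ensemble$frames, fidx, midx)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L))
    for (j in (i + 1L):nf)
      m[i, j] <- m[j, i] <- .rmsd_prepped(pp[[i]], pp[[j]])
  .new_rmsd_matrix(m, fit, measure, symmetric = TRUE)
}

#' Cross-ensemble RMSd matrix over mapped residues
#'
#' Compares every fragment frame with every protein frame: superposition on
#' the backbone atoms of the mapped residues, deviation measured over all
#' mapped heavy atoms (the standard reading of an "all atoms" RMSd between
#' backbone-superposed structures). Atoms are matched within each mapped
#' residue pair by atom name.
#'
#' @param fragment,protein `Ensemble` objects.
#' @param mapping a [residue_mapping()] between fragment and protein residue
#'   numbers; defaults to the identity mapping over the fragment residues.
#' @param fit,measure selection keywords applied within the mapped residues.
#' @return an `RmsdMatrix` of shape (fragment frames x protein frames).
#' @export
cross_rmsd_matrix <- function(fragment, protein, mapping = NULL,
                              fit = "backbone", measure = "all") {
  if (is.null(mapping)) {
    res <- unique(fragment$topology$residue_number)
    mapping <- residue_mapping(res, res)
  }
  idx <- .mapped_atom_indices(fragment$topology, protein$topology, mapping)
  fsel <- fragment$topology$atom_name[idx$fragment] %in% .BACKBONE_ATOMS
  fit_rows <- switch(fit, backbone = which(fsel), all = seq_along(idx$fragment),
                     calpha = which(fragment$topology$atom_name[idx$fragment] == "CA"),
                     stop("unsupported fit selection: ", fit, call. = FALSE))
  measure_rows <- switch(measure, all = seq_along(idx$fragment),
                         backbone = which(fsel),
                         calpha = which(fragment$topology$atom_name[idx$fragment] == "CA"),
                         stop("unsupported measure selection: ", measure,
                              call. = FALSE))
  if (!length(fit_rows) || !length(measure_rows))
    stop("empty fit or measure selection over the mapped residues",
         call. = FALSE)

  frag_frames <- lapply(fragment$frames, function(m)
    m[idx$fragment, , drop = FALSE])
  prot_frames <- lapply(protein$frames, function(m)
    m[idx$protein, , drop = FALSE])
  pa <- .prep_frames(frag_frames, fit_rows, measure_rows)
  pb <- .prep_frames(prot_frames, fit_rows, measure_rows)
  m <- matrix(0, length(pa), length(pb))
  for (i in seq_along(pa))
    for (j in seq_along(pb))
      m[i, j] <- .rmsd_prepped(pa[[i]], pb[[j]])
  .new_rmsd_matrix(m, paste0(fit, " (mapped)"), paste0(measure, " (mapped)"),
                   symmetric = FALSE)
}

# 1:1 atom correspondence over mapped residues, matched by atom name.
.mapped_atom_indices <- function(frag_top, prot_top, mapping) {
  fi <- integer(0); pj <- integer(0)
  for (k in seq_len(nrow(mapping$pairs))) {
    fr <- mapping$pairs$fragment[k]; pr <- mapping$pairs$protein[k]
    fa <- which(frag_top$residue_number == fr)
    pa <- which(prot_top$residue_number == pr)
    if (!length(fa) || !length(pa))
      stop("mapped residue absent: fragment ", fr, " / protein ", pr,
           call. = FALSE)
    pos <- match(frag_top$atom_name[fa], prot_top$atom_name[pa])
    if (anyNA(pos) || length(fa) != length(pa))
      stop("atom correspondence mismatch at fragment residue ", fr,
           " / protein residue ", pr, call. = FALSE)
    fi <- c(fi, fa); pj <- c(pj, pa[pos])
  }
  list(fragment = fi, protein = pj)
}

#' Fraction of RMSd values inside a range
#'
#' Counts matrix entries with `lo <= value <= hi` (closed on both ends)
#' divided by the total number of entries. The frame-wise variant reports,
#' for each fragment frame (row), the fraction of its entries in range.
#'
#' @param matrix an `RmsdMatrix` or a plain numeric matrix.
#' @param lo,hi range bounds in Angstrom (defaults 2 and 4).
#' @param by `"entry"` (default) for the global fraction, `"frame"` for the
#'   per-row vector.
#' @return a single fraction in `[0, 1]`, or a numeric vector (one per row)
#'   when `by = "frame"`.
#' @export
fraction_in_range <- function(matrix, lo = 2.0, hi = 4.0,
                              by = c("entry", "frame")) {
  by <- match.arg(by)
  v <- if (inherits(matrix, "RmsdMatrix")) matrix$values else as.matrix(matrix)
  if (!length(v)) stop("empty matrix", call. = FALSE)
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  inr <- v >= lo & v <= hi
  if (by == "entry") mean(inr) else rowMeans(inr)
}

#' Average-linkage agglomerative clustering of conformers
#'
#' Starts from singletons and repeatedly merges the pair of clusters with
#' the smallest average linkage (unweighted mean of all inter-cluster
#' pairwise distances), stopping when the minimum linkage exceeds the
#' cutoff. Ties are broken by the smallest cluster index pair, indices being
#' ordered by each cluster's smallest member, so the partition is fully
#' deterministic. Equivalent to cutting an average-linkage dendrogram at the
#' cutoff height.
#'
#' @param matrix a symmetric self `RmsdMatrix` (or plain symmetric matrix).
#' @param cutoff merge threshold in Angstrom (default 2.0).
#' @return object of class `Clustering`: list with `assignment` (cluster id
#'   per frame, ids numbered by smallest member frame), `cutoff`, `linkage
#'   = "average"` and `representatives` (medoid frame per cluster, see
#'   [cluster_representatives()]).
#' @export
average_linkage_cluster <- function(matrix, cutoff = 2.0) {
  d <- if (inherits(matrix, "RmsdMatrix")) matrix$values else as.matrix(matrix)
  n <- nrow(d)
  if (!isSymmetric(unname(d), tol = 1e-9))
    stop("clustering requires a symmetric self-matrix", call. = FALSE)

  members <- lapply(seq_len(n), identity)  # cluster -> member frames
  D <- d                                   # average linkage between clusters
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    sub <- D[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    if (!is.finite(mn) || mn > cutoff) break
    w <- which(sub == mn, arr.ind = TRUE)
    # smallest (i, j) pair among the ties
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
    i <- act[w[1L]]; j <- act[w[2L]]
    # Lance-Williams update for unweighted average linkage
    others <- act[act != i & act != j]
    D[i, others] <- D[others, i] <-
      (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
      (sizes[i] + sizes[j])
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  clusters <- members[active]
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  cl <- structure(list(assignment = assignment, cutoff = cutoff,
                       linkage = "average", representatives = NULL),
                  class = "Clustering")
  cl$representatives <- cluster_representatives(cl, d)
  cl
}

#' @export
print.Clustering <- function(x, ...) {
  k <- max(x$assignment)
  cat("Clustering: ", length(x$assignment), " frames in ", k,
      " cluster(s), average linkage, cutoff ", x$cutoff, " A\n", sep = "")
  tab <- table(x$assignment)
  cat("  sizes: ", paste(as.integer(tab), collapse = ", "), "\n", sep = "")
  cat("  representatives: ", paste(x$representatives, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Medoid representative of each cluster
#'
#' The representative ("most representative structure") of a cluster is its
#' medoid: the member frame minimising the mean RMSd to the other members.
#' Singletons represent themselves; ties go to the lowest frame index.
#'
#' @param clustering a `Clustering`.
#' @param matrix the RMSd self-matrix the clustering was computed from
#'   (`RmsdMatrix` or plain matrix).
#' @return named integer vector: cluster id -> representative frame index.
#' @export
cluster_representatives <- function(clustering, matrix) {
  d <- if (inherits(matrix, "RmsdMatrix")) matrix$values else as.matrix(matrix)
  assignment <- clustering$assignment
  ks <- sort(unique(assignment))
  reps <- vapply(ks, function(k) {
    mem <- which(assignment == k)
    if (length(mem) == 1L) return(mem)
    mean_d <- rowMeans(d[mem, mem, drop = FALSE]) * length(mem) /
      (length(mem) - 1L)  # mean over the *other* members
    mem[which.min(mean_d)]
  }, integer(1))
  names(reps) <- ks
  reps
}
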