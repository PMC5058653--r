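# Core containers: Conformer (one structural model), Ensemble (a list of
# conformers sharing one topology), ResidueRange. Heavy-atom only throughout.

#' Construct a Conformer
#'
#' A single structural model: an atom table (topology) plus an n x 3
#' coordinate matrix in Angstrom. The topology holds, per atom, the PDB atom
#' name, element, 3-letter residue name, 1-based residue number and the vdW
#' radius assigned from the packaged Bondi table.
#'
#' @param topology data.frame with columns `residue_number`, `residue_name`,
#'   `atom_name`, `element` and optionally `vdw_radius` (assigned from the
#'   element when absent).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `Conformer`.
#' @export
conformer <- function(topology, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(is.data.frame(topology), ncol(xyz) == 3L,
            nrow(topology) == nrow(xyz))
  needed <- c("residue_number", "residue_name", "atom_name", "element")
  missing_cols <- setdiff(needed, names(topology))
  if (length(missing_cols))
    stop("topology lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  if (is.unsorted(topology$residue_number))
    stop("residue numbers must be non-decreasing along the atom list",
         call. = FALSE)
  if (is.null(topology$vdw_radius))
    topology$vdw_radius <- vdw_radius(topology$element)
  if (any(topology$vdw_radius <= 0))
    stop("vdW radii must be positive", call. = FALSE)
  rownames(topology) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(topology = topology, xyz = xyz), class = "Conformer")
}

#' @export
print.Conformer <- function(x, ...) {
  nres <- length(unique(x$topology$residue_number))
  cat("Conformer: ", nrow(x$xyz), " heavy atoms, ", nres, " residues\n", sep = "")
  invisible(x)
}

#' Topology key of a conformer or ensemble
#'
#' One string per atom, `residue_number:residue_name:atom_name`; frames of an
#' ensemble must agree on it exactly.
#'
#' @param x a `Conformer` or `Ensemble`.
#' @return character vector, one element per atom.
#' @export
topology_key <- function(x) {
  top <- x$topology
  paste(top$residue_number, top$residue_name, top$atom_name, sep = ":")
}

#' Construct an Ensemble
#'
#' An ordered set of conformers ("frames") sharing an identical topology:
#' the unit of all trajectory analyses.
#'
#' @param frames list of `Conformer` objects, or a single `Conformer`.
#' @param label optional text label.
#' @return object of class `Ensemble` with fields `topology`, `frames`
#'   (list of coordinate matrices) and `label`.
#' @export
ensemble <- function(frames, label = "") {
  if (inherits(frames, "Conformer")) frames <- list(frames)
  if (!length(frames)) stop("ensemble needs at least one frame", call. = FALSE)
  key <- topology_key(frames[[1L]])
  for (i in seq_along(frames)) {
    ki <- topology_key(frames[[i]])
    if (length(ki) != length(key) || any(ki != key))
      stop("topology mismatch at frame ", i, call. = FALSE)
  }
  structure(list(topology = frames[[1L]]$topology,
                 frames = lapply(frames, function(f) f$xyz),
                 label = label),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  nres <- length(unique(x$topology$residue_number))
  cat("Ensemble", if (nzchar(x$label)) paste0(" '", x$label, "'"), ": ",
      n_frames(x), " frames, ", nrow(x$topology), " heavy atoms, ",
      nres, " residues\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

#' Extract one frame as a Conformer
#' @param x an `Ensemble`.
#' @param i frame index.
#' @return a `Conformer`.
#' @export
get_frame <- function(x, i) {
  stopifnot(i >= 1L, i <= n_frames(x))
  structure(list(topology = x$topology, xyz = x$frames[[i]]),
            class = "Conformer")
}

# Internal fast constructor: topology assumed already validated.
.ensemble_from_xyz <- function(topology, xyz_list, label = "") {
  structure(list(topology = topology, frames = xyz_list, label = label),
            class = "Ensemble")
}

#' Inclusive 1-based residue range
#'
#' @param start,end first and last residue number (inclusive).
#' @return object of class `ResidueRange`.
#' @export
residue_range <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start > end) stop("residue range start must be <= end", call. = FALSE)
  structure(list(start = start, end = end), class = "ResidueRange")
}

#' @export
print.ResidueRange <- function(x, ...) {
  cat("ResidueRange ", x$start, "-", x$end, "\n", sep = "")
  invisible(x)
}

#' @export
format.ResidueRange <- function(x, ...) paste0(x$start, "-", x$end)

.range_seq <- function(r) seq.int(r$start, r$end)

.as_residue_range <- function(x) {
  if (inherits(x, "ResidueRange")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(residue_range(x[1L], x[2L]))
  stop("expected a ResidueRange or a length-2 numeric vector", call. = FALSE)
}
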