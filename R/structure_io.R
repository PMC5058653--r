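# Multi-model PDB input/output and atom bookkeeping. Parsing and writing are
# delegated to bio3d; this layer enforces the ensemble contracts: heavy atoms
# only, water removed, altloc ' '/'A' only, first chain only, and an
# identical topology across models.

#' Read a multi-model PDB file as an Ensemble
#'
#' Parses a PDB file (one or more MODEL/ENDMDL blocks, or a single plain
#' model) into an [ensemble()]. Hydrogens and water (HOH) records are dropped,
#' only alternate locations ' ' and 'A' are kept, and for multi-chain files
#' only the first chain is used (with a warning). All models must share an
#' identical atom topology.
#'
#' @param path path to a PDB file.
#' @param label optional ensemble label; defaults to the file name.
#' @return an `Ensemble`.
#' @export
read_pdb_models <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_model_topology(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!nrow(at)) stop("no atom records in ", path, call. = FALSE)

  keep <- at$type %in% c("ATOM", "HETATM")
  keep <- keep & at$resid != "HOH"
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", " ", "A"))
  elem <- .guess_element(at$elesy, at$elety)
  keep <- keep & elem != "H"
  chains <- unique(at$chain[keep])
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L) {
    warning("multiple chains (", paste(chains, collapse = ", "),
            "); using first chain '", chains[1L], "'", call. = FALSE)
    keep <- keep & (!is.na(at$chain) & at$chain == chains[1L])
  }
  idx <- which(keep)
  if (!length(idx)) stop("no heavy atoms retained from ", path, call. = FALSE)

  topology <- data.frame(
    residue_number = as.integer(at$resno[idx]),
    residue_name = as.character(at$resid[idx]),
    atom_name = as.character(at$elety[idx]),
    element = elem[idx],
    stringsAsFactors = FALSE
  )
  topology$vdw_radius <- vdw_radius(topology$element)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- bio3d::atom2xyz(idx)
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    mat <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
    dimnames(mat) <- list(NULL, c("x", "y", "z"))
    mat
  })
  if (is.unsorted(topology$residue_number))
    stop("residue numbers are not non-decreasing in ", path, call. = FALSE)
  .ensemble_from_xyz(topology, frames, label = label)
}

# Cheap per-model consistency scan: bio3d assumes equal atom counts across
# MODEL blocks, so mismatches must be caught and reported by model number.
.check_model_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2L) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
  keys <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    block <- lines[(model_starts[m] + 1L):(model_ends[m] - 1L)]
    atoms <- block[substr(block, 1L, 6L) %in% c("ATOM  ", "HETATM")]
    keys[[m]] <- substr(atoms, 13L, 27L)  # atom name .. residue number
  }
  ref <- keys[[1L]]
  for (m in seq_along(keys)[-1L]) {
    if (length(keys[[m]]) != length(ref) || any(keys[[m]] != ref))
      stop("topology mismatch: model ", m, " differs from model 1 in ", path,
           call. = FALSE)
  }
  invisible(TRUE)
}

.guess_element <- function(elesy, elety) {
  e <- toupper(trimws(as.character(elesy)))
  miss <- is.na(e) | e == ""
  if (any(miss)) {
    # fall back to first alphabetic character of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(elety[miss])))
    e[miss] <- toupper(substr(nm, 1L, 1L))
  }
  e
}

#' Write an Ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; coordinates fixed-width `%8.3f`, so a
#' read/write round trip reproduces coordinates to 3 decimals and the exact
#' topology key.
#'
#' @param ensemble an `Ensemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb_models <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "Ensemble"))
  if (!n_frames(ensemble)) stop("cannot write an empty ensemble", call. = FALSE)
  top <- ensemble$topology
  xyz <- do.call(rbind, lapply(ensemble$frames, function(m) as.vector(t(m))))
  ok <- try(bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = top$residue_number,
    resid = top$residue_name,
    eleno = seq_len(nrow(top)),
    elety = top$atom_name,
    chain = rep("A", nrow(top)),
    elesy = top$element
  ), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write PDB to ", path, ": ", attr(ok, "condition")$message,
         call. = FALSE)
  invisible(path)
}

#' One-letter sequence of a conformer
#'
#' One character per distinct residue number, in order; non-standard residue
#' names map to 'X' with a warning.
#'
#' @param conformer a `Conformer` (or an `Ensemble`, whose shared topology is
#'   used).
#' @return one-letter amino-acid string.
#' @export
extract_sequence <- function(conformer) {
  top <- conformer$topology
  first <- !duplicated(top$residue_number)
  res3 <- toupper(top$residue_name[first])
  one <- .AA_THREE_TO_ONE[res3]
  if (anyNA(one)) {
    warning("unknown residue name(s) ",
            paste(unique(res3[is.na(one)]), collapse = ", "),
            " mapped to 'X'", call. = FALSE)
    one[is.na(one)] <- "X"
  }
  paste(one, collapse = "")
}

#' Resolve an atom selection to indices
#'
#' Supported selections: `"all"` (all heavy atoms), `"backbone"` (N, CA, C,
#' O), `"calpha"` (CA), `"sidechain"` (heavy atoms not in the backbone).
#' Optionally restricted to a residue range. Selections feeding RMSd must be
#' non-empty, so an empty result is an error.
#'
#' @param conformer a `Conformer` or `Ensemble`.
#' @param selection one of `"all"`, `"backbone"`, `"calpha"`, `"sidechain"`.
#' @param residues optional [residue_range()] restriction.
#' @return integer vector of atom indices in atom-list order.
#' @export
select_atoms <- function(conformer, selection = c("all", "backbone", "calpha",
                                                  "sidechain"),
                         residues = NULL) {
  selection <- match.arg(selection)
  top <- conformer$topology
  keep <- switch(selection,
    all = rep(TRUE, nrow(top)),
    backbone = top$atom_name %in% .BACKBONE_ATOMS,
    calpha = top$atom_name == "CA",
    sidechain = !(top$atom_name %in% .BACKBONE_ATOMS)
  )
  if (!is.null(residues)) {
    residues <- .as_residue_range(residues)
    keep <- keep & top$residue_number >= residues$start &
      top$residue_number <= residues$end
  }
  idx <- which(keep)
  if (!length(idx))
    stop("empty atom selection ('", selection, "'",
         if (!is.null(residues)) paste0(", residues ", format(residues)), ")",
         call. = FALSE)
  idx
}

#' Report residues missing from a conformer
#'
#' Compares the residue numbers present in a conformer against an expected
#' full-length sequence and returns the maximal ranges of absent positions.
#' Missing stretches are reported, never rebuilt.
#'
#' @param conformer a `Conformer` or `Ensemble`.
#' @param expected_sequence one-letter string covering positions 1..n.
#' @return list of `ResidueRange` (possibly empty), disjoint and sorted.
#' @export
detect_missing_residues <- function(conformer, expected_sequence) {
  n <- nchar(expected_sequence)
  present <- unique(conformer$topology$residue_number)
  if (n < max(present))
    stop("expected sequence (length ", n,
         ") shorter than highest residue number present (", max(present), ")",
         call. = FALSE)
  absent <- setdiff(seq_len(n), present)
  if (!length(absent)) return(list())
  breaks <- c(0L, which(diff(absent) != 1L), length(absent))
  lapply(seq_len(length(breaks) - 1L), function(k) {
    seg <- absent[(breaks[k] + 1L):breaks[k + 1L]]
    residue_range(seg[1L], seg[length(seg)])
  })
}
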