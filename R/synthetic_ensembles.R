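# Seeded synthetic conformational ensembles emulating the statistical
# structure of protein MD trajectories: a Gaussian rigid-residue sampler with
# analytic RMSF control, and an elastic-network Langevin sampler giving
# correlated, physically flavoured motion with a plantable low-contact
# (flexible) loop. Neither computes force-field energetics; both honour the
# 150-frame regular-interval sampling contract of the trajectories they
# stand in for.

# Evaluate `expr` under a private RNG stream; global .Random.seed untouched.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification of a synthetic ensemble
#'
#' Collects everything needed to generate one ensemble deterministically:
#' an identical spec and seed always reproduce the same coordinates.
#'
#' @param sequence one-letter amino-acid string.
#' @param n_frames number of frames to record (default 150, the sampling
#'   depth of the trajectories the generator emulates).
#' @param sampler `"gaussian"` (independent rigid-residue displacements with
#'   analytic RMSF) or `"enm"` (elastic-network Langevin dynamics).
#' @param amplitude per-residue per-axis displacement standard deviation in
#'   Angstrom for the Gaussian sampler; scalar (recycled) or full profile.
#'   The expected unaligned CA RMSF of residue r is `amplitude[r] * sqrt(3)`.
#' @param loop_range optional [residue_range()] marking an elevated-
#'   flexibility loop. The Gaussian sampler multiplies the loop amplitudes by
#'   `loop_multiplier`; the ENM sampler strips the loop's non-bonded springs
#'   (see [sample_enm_ensemble()]).
#' @param loop_multiplier amplitude multiplier (> 1) for `loop_range` under
#'   the Gaussian sampler.
#' @param seed integer seed; mandatory, no global RNG state is consumed.
#' @param enm list of ENM parameters: `k` spring constant (energy/A^2),
#'   `cutoff` contact cutoff (A, default 10), `kT` temperature factor,
#'   `dt` step size, `gamma` friction, `n_equil` equilibration steps,
#'   `stride` recording stride.
#' @return object of class `EnsembleSpec`.
#' @export
ensemble_spec <- function(sequence, n_frames = 150L,
                          sampler = c("gaussian", "enm"),
                          amplitude = 0.3, loop_range = NULL,
                          loop_multiplier = 3, seed,
                          enm = list()) {
  sampler <- match.arg(sampler)
  .validate_peptide(sequence, "sequence")
  n_res <- nchar(sequence)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, n_res)
  if (length(amplitude) != n_res)
    stop("amplitude profile length must equal sequence length", call. = FALSE)
  if (any(amplitude <= 0)) stop("all amplitudes must be > 0", call. = FALSE)
  if (!is.null(loop_range)) {
    loop_range <- .as_residue_range(loop_range)
    if (loop_range$start < 1L || loop_range$end > n_res)
      stop("loop_range outside the sequence", call. = FALSE)
    if (loop_multiplier <= 1) stop("loop_multiplier must be > 1", call. = FALSE)
  }
  enm_defaults <- list(k = 1.0, cutoff = 10.0, kT = 0.5, dt = 0.05,
                       gamma = 1.0, n_equil = 2000L, stride = 20L)
  enm <- utils::modifyList(enm_defaults, enm)
  structure(list(sequence = sequence, n_frames = n_frames, sampler = sampler,
                 amplitude = amplitude, loop_range = loop_range,
                 loop_multiplier = loop_multiplier,
                 seed = as.integer(seed), enm = enm),
            class = "EnsembleSpec")
}

# Effective per-residue amplitude with the loop multiplier applied.
.effective_amplitude <- function(spec) {
  a <- spec$amplitude
  if (!is.null(spec$loop_range))
    a[.range_seq(spec$loop_range)] <- a[.range_seq(spec$loop_range)] *
      spec$loop_multiplier
  a
}

#' Deterministic reference chain geometry
#'
#' Builds an idealised single-conformer chain for a sequence: CA atoms on a
#' regular helix of large pitch with consecutive CA-CA spacing exactly
#' `ca_spacing`, four backbone atoms (N, CA, C, O) placed at fixed offsets in
#' the local (tangent, normal, binormal) frame, and one pseudo-sidechain atom
#' (CB, except for Gly) offset 1.5 A perpendicular to the local chain
#' direction. The helix is parameterised by the rise per residue `rise` and
#' residues per turn `per_turn`; its radius follows from the chord
#' constraint `(2 R sin(pi/per_turn))^2 + rise^2 = ca_spacing^2`.
#'
#' @param sequence one-letter amino-acid string.
#' @param ca_spacing consecutive CA-CA distance (A, default 3.8).
#' @param rise helix rise per residue (A, default 3.5: a gently curled,
#'   nearly extended chain).
#' @param per_turn residues per helix turn (default 20).
#' @return a `Conformer`.
#' @export
build_reference_chain <- function(sequence, ca_spacing = 3.8, rise = 3.5,
                                  per_turn = 20) {
  aa <- .validate_peptide(sequence, "sequence")
  n <- length(aa)
  theta <- 2 * pi / per_turn
  chord2 <- ca_spacing^2 - rise^2
  if (chord2 <= 0) stop("rise must be smaller than ca_spacing", call. = FALSE)
  R <- sqrt(chord2) / (2 * sin(theta / 2))
  i <- seq_len(n) - 1L
  ca <- cbind(x = R * cos(i * theta), y = R * sin(i * theta), z = i * rise)

  # local frames: tangent along the chain (central differences, one-sided at
  # the termini), normal pointing away from the helix axis
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  tangent <- ca[nxt, , drop = FALSE] - ca[prv, , drop = FALSE]
  tnorm <- sqrt(rowSums(tangent^2))
  zero <- tnorm < 1e-12  # single-residue chain: take the helix axis
  tangent[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  tnorm[zero] <- 1
  tangent <- tangent / tnorm
  normal <- cbind(ca[, 1L], ca[, 2L], 0)
  normal <- normal / sqrt(rowSums(normal^2))
  # orthogonalise normal against tangent, then binormal = t x n
  normal <- normal - tangent * rowSums(normal * tangent)
  normal <- normal / sqrt(rowSums(normal^2))
  binormal <- cbind(
    tangent[, 2L] * normal[, 3L] - tangent[, 3L] * normal[, 2L],
    tangent[, 3L] * normal[, 1L] - tangent[, 1L] * normal[, 3L],
    tangent[, 1L] * normal[, 2L] - tangent[, 2L] * normal[, 1L]
  )

  place <- function(dt, dn, db) ca + dt * tangent + dn * normal + db * binormal
  pos <- list(N = place(-1.20, 0.80, 0.00),
              CA = ca,
              C = place(1.20, 0.80, 0.00),
              O = place(1.95, 1.20, 0.60),
              CB = place(0.00, 0.00, 1.50))

  res3 <- .AA_ONE_TO_THREE[aa]
  rows <- list(); coords <- list()
  for (r in seq_len(n)) {
    atoms <- c("N", "CA", "C", "O", if (aa[r] != "G") "CB")
    rows[[r]] <- data.frame(
      residue_number = r, residue_name = unname(res3[r]), atom_name = atoms,
      element = c("N", "C", "C", "O", if (aa[r] != "G") "C"),
      stringsAsFactors = FALSE)
    coords[[r]] <- do.call(rbind, lapply(atoms, function(a) pos[[a]][r, ]))
  }
  conformer(do.call(rbind, rows), do.call(rbind, coords))
}

#' Gaussian rigid-residue ensemble sampler
#'
#' Each frame displaces every residue rigidly from the reference chain by an
#' independent isotropic Gaussian 3-vector with per-axis standard deviation
#' equal to that residue's (loop-multiplied) amplitude. The expected
#' unaligned CA RMSF of residue r about the reference is therefore exactly
#' `a_r * sqrt(3)`, which makes the sampler an analytic ground truth for the
#' fluctuation analysis.
#'
#' @param spec an [ensemble_spec()] with `sampler = "gaussian"`.
#' @param reference optional pre-built reference `Conformer` (defaults to
#'   [build_reference_chain()] of the spec sequence).
#' @return an `Ensemble` of `n_frames` frames.
#' @export
sample_gaussian_ensemble <- function(spec, reference = NULL) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  if (is.null(reference)) reference <- build_reference_chain(spec$sequence)
  a <- .effective_amplitude(spec)
  n_res <- nchar(spec$sequence)
  resno <- reference$topology$residue_number
  atom_of_res <- match(resno, seq_len(n_res))
  frames <- .with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      disp <- matrix(stats::rnorm(3L * n_res, sd = rep(a, 3L)),
                     ncol = 3L)  # residue-wise rigid displacement
      reference$xyz + disp[atom_of_res, , drop = FALSE]
    })
  })
  .ensemble_from_xyz(reference$topology, frames,
                     label = sprintf("gaussian seed %d", spec$seed))
}

#' Elastic-network Langevin ensemble sampler
#'
#' Coarse-grained surrogate for an MD engine: CA beads connected by harmonic
#' springs (rest length = reference distance) between all CA pairs within
#' the contact cutoff in the reference chain, propagated by overdamped
#' Langevin (Euler-Maruyama) dynamics
#' `x <- x - (dt/gamma) * grad(U) + sqrt(2 kT dt / gamma) * xi`.
#' Backbone and CB atoms ride rigidly with their CA. Frames are recorded
#' every `stride` steps after `n_equil` equilibration steps until `n_frames`
#' are collected.
#'
#' When `loop_range` is set, springs between pairs involving a loop residue
#' are removed except for chain-adjacent (|i-j| = 1) ones, emulating a
#' solvent-exposed loop without tertiary packing; such a low-contact loop
#' fluctuates more than the spring-rich core.
#'
#' @param spec an [ensemble_spec()] with `sampler = "enm"`.
#' @param reference optional reference `Conformer`. The default is a compact
#'   helical chain (`rise = 1.5`, `per_turn = 3.6`, alpha-helix-like): an
#'   elastic network emulates a folded protein, whose core owes its rigidity
#'   to a dense contact network (about 12 contacts per residue at the 10 A
#'   cutoff), in contrast to the stripped loop.
#' @return an `Ensemble` of `n_frames` frames.
#' @export
sample_enm_ensemble <- function(spec, reference = NULL) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  if (is.null(reference))
    reference <- build_reference_chain(spec$sequence, rise = 1.5,
                                       per_turn = 3.6)
  p <- spec$enm
  n_res <- nchar(spec$sequence)
  ca_idx <- select_atoms(reference, "calpha")
  ca0 <- reference$xyz[ca_idx, , drop = FALSE]

  # contact springs from the reference geometry
  d <- as.matrix(stats::dist(ca0))
  pairs <- which(upper.tri(d) & d <= p$cutoff, arr.ind = TRUE)
  if (!is.null(spec$loop_range)) {
    loop <- .range_seq(spec$loop_range)
    in_loop <- pairs[, 1L] %in% loop | pairs[, 2L] %in% loop
    keep <- !in_loop | (pairs[, 2L] - pairs[, 1L] == 1L)
    pairs <- pairs[keep, , drop = FALSE]
  }
  i1 <- pairs[, 1L]; i2 <- pairs[, 2L]
  r0 <- d[pairs]

  step_sd <- sqrt(2 * p$kT * p$dt / p$gamma)
  scale <- p$dt / p$gamma
  n_steps <- p$n_equil + spec$n_frames * p$stride
  resno <- reference$topology$residue_number
  atom_of_res <- match(resno, seq_len(n_res))

  frames <- .with_seed(spec$seed, {
    x <- ca0
    out <- vector("list", spec$n_frames)
    rec <- 0L
    for (s in seq_len(n_steps)) {
      dv <- x[i1, , drop = FALSE] - x[i2, , drop = FALSE]
      len <- sqrt(rowSums(dv * dv))
      fmag <- p$k * (len - r0) / pmax(len, 1e-12)
      fv <- dv * fmag  # force on i2 along +dv; on i1 along -dv
      grad <- matrix(0, n_res, 3L)
      for (ax in 1:3) {
        grad[, ax] <- grad[, ax] +
          tabulate2(i1, fv[, ax], n_res) - tabulate2(i2, fv[, ax], n_res)
      }
      x <- x - scale * grad +
        if (p$kT > 0) matrix(stats::rnorm(3L * n_res, sd = step_sd),
                             n_res, 3L) else 0
      if (max(abs(x)) > 1e3)
        stop("ENM integration blew up (|coordinate| > 1000 A); ",
             "use a smaller dt or larger gamma", call. = FALSE)
      if (s > p$n_equil && (s - p$n_equil) %% p$stride == 0L) {
        rec <- rec + 1L
        disp <- x - ca0
        out[[rec]] <- reference$xyz + disp[atom_of_res, , drop = FALSE]
        if (rec == spec$n_frames) break
      }
    }
    out
  })
  .ensemble_from_xyz(reference$topology, frames,
                     label = sprintf("enm seed %d", spec$seed))
}

# grouped sum: sum of w by index, length n
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Specification of a planted fragment/protein mimicry pair
#'
#' @param fragment_range [residue_range()] of the N-terminal fragment within
#'   the protein sequence (default 1-38).
#' @param planted_window [residue_range()] where the fragment's amplitudes
#'   equal the protein's (the mimetic region to be recovered downstream).
#' @param outside_scale multiplier (> 0, != 1) applied to the fragment's
#'   amplitudes outside the planted window.
#' @param seed integer seed for the fragment ensemble (independent of the
#'   protein's).
#' @return object of class `MimicrySpec`.
#' @export
mimicry_spec <- function(fragment_range = residue_range(1, 38),
                         planted_window, outside_scale = 3, seed) {
  fragment_range <- .as_residue_range(fragment_range)
  planted_window <- .as_residue_range(planted_window)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (outside_scale <= 0) stop("outside_scale must be > 0", call. = FALSE)
  if (planted_window$start < fragment_range$start ||
      planted_window$end > fragment_range$end)
    stop("planted_window must lie within fragment_range", call. = FALSE)
  structure(list(fragment_range = fragment_range,
                 planted_window = planted_window,
                 outside_scale = outside_scale, seed = as.integer(seed)),
            class = "MimicrySpec")
}

#' Generate a protein/fragment ensemble pair with a planted mimetic window
#'
#' The protein ensemble follows `protein_spec`. The fragment ensemble covers
#' the truncated N-terminal sequence with an amplitude profile equal to the
#' protein's inside the planted window and multiplied by `outside_scale`
#' elsewhere, sampled with the mimicry seed. Downstream fluctuation
#' comparison should therefore recover the planted window as the region of
#' closest dynamic similarity.
#'
#' @param protein_spec an [ensemble_spec()] for the full-length chain
#'   (Gaussian sampler).
#' @param mimicry a [mimicry_spec()].
#' @return list with elements `protein` and `fragment` (both `Ensemble`).
#' @export
sample_fragment_pair <- function(protein_spec, mimicry) {
  stopifnot(inherits(protein_spec, "EnsembleSpec"),
            inherits(mimicry, "MimicrySpec"))
  n_res <- nchar(protein_spec$sequence)
  fr <- mimicry$fragment_range
  if (fr$end > n_res)
    stop("fragment_range extends beyond the protein sequence", call. = FALSE)
  protein <- sample_gaussian_ensemble(protein_spec)

  frag_seq <- substr(protein_spec$sequence, fr$start, fr$end)
  prot_amp <- .effective_amplitude(protein_spec)
  frag_amp <- prot_amp[.range_seq(fr)]
  frag_pos <- .range_seq(fr)
  outside <- frag_pos < mimicry$planted_window$start |
    frag_pos > mimicry$planted_window$end
  frag_amp[outside] <- frag_amp[outside] * mimicry$outside_scale
  frag_spec <- ensemble_spec(frag_seq, n_frames = protein_spec$n_frames,
                             sampler = "gaussian", amplitude = frag_amp,
                             seed = mimicry$seed)
  fragment <- sample_gaussian_ensemble(frag_spec)
  fragment$label <- sprintf("fragment %s seed %d", format(fr), mimicry$seed)
  list(protein = protein, fragment = fragment)
}
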