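# Shared fixtures: all built in code, nothing stored on disk.

# A small random ensemble over a given sequence (gaussian sampler).
toy_ensemble <- function(sequence = "QHLIKPS", n_frames = 3L, seed = 1L,
                         amplitude = 0.4) {
  sample_gaussian_ensemble(
    ensemble_spec(sequence, n_frames = n_frames, amplitude = amplitude,
                  seed = seed))
}

# Hand-built conformer from a compact spec: list of (resno, resname, atom,
# element, x, y, z) rows.
manual_conformer <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(residue_number = r[[1]], residue_name = r[[2]],
               atom_name = r[[3]], element = r[[4]], stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r[5:7])))
  conformer(df, xyz)
}

# Random rigid transform (proper rotation + translation).
random_rigid <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, rig) sweep(xyz %*% t(rig$R), 2, -rig$t)
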