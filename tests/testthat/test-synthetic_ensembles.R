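test_that("reference chain geometry follows the documented construction", {
  rc <- build_reference_chain("QHLIKPS")
  # 4 backbone atoms per residue plus one CB pseudo-sidechain (Gly excepted;
  # Pro carries a CB like any other non-Gly residue)
  expect_equal(nrow(rc$xyz), 4L * 7L + 7L)
  ca <- rc$xyz[select_atoms(rc, "calpha"), ]
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(3.8, 6), tolerance = 1e-9)

  gly <- build_reference_chain("G")
  expect_equal(nrow(gly$xyz), 4L)
  expect_false("CB" %in% gly$topology$atom_name)

  mixed <- build_reference_chain("GAG")
  expect_equal(sum(mixed$topology$atom_name == "CB"), 1L)
  # CB sits 1.5 A from its CA
  cb <- mixed$xyz[mixed$topology$atom_name == "CB", ]
  ca2 <- mixed$xyz[mixed$topology$atom_name == "CA", ][2, ]
  expect_equal(sqrt(sum((cb - ca2)^2)), 1.5, tolerance = 1e-9)

  expect_error(build_reference_chain("AZB"), "invalid")
})

test_that("ensemble specs validate their invariants", {
  expect_error(ensemble_spec("AAA", n_frames = 1, seed = 1), "n_frames")
  expect_error(ensemble_spec("AAA", amplitude = c(1, 1), seed = 1), "length")
  expect_error(ensemble_spec("AAA", amplitude = 0, seed = 1), "> 0")
  expect_error(ensemble_spec("AAA", seed = 1, loop_range = c(1, 5)),
               "loop_range")
  expect_error(ensemble_spec("AAA", seed = 1, loop_range = c(1, 2),
                             loop_multiplier = 0.5), "multiplier")
  expect_error(ensemble_spec("AAA"), "seed")
  spec <- ensemble_spec("AAA", seed = 1)
  expect_equal(spec$n_frames, 150L)
})

test_that("identical spec and seed reproduce the ensemble bitwise", {
  spec <- ensemble_spec("QHLIKPS", n_frames = 5L, seed = 99L)
  e1 <- sample_gaussian_ensemble(spec)
  e2 <- sample_gaussian_ensemble(spec)
  expect_identical(e1$frames, e2$frames)
  e3 <- sample_gaussian_ensemble(ensemble_spec("QHLIKPS", n_frames = 5L,
                                               seed = 100L))
  expect_false(identical(e1$frames, e3$frames))
})

test_that("gaussian sampler reproduces its analytic per-residue RMSF", {
  a <- 0.5
  spec <- ensemble_spec(strrep("A", 30), n_frames = 1000L, amplitude = a,
                        seed = 3L)
  e <- sample_gaussian_ensemble(spec)
  ref <- build_reference_chain(spec$sequence)
  cai <- select_atoms(ref, "calpha")
  # unaligned RMSF about the reference (no superposition: the sampler adds
  # no rigid drift)
  msd <- rowMeans(sapply(e$frames, function(f)
    rowSums((f[cai, ] - ref$xyz[cai, ])^2)))
  ratio <- sqrt(msd) / (a * sqrt(3))
  expect_true(all(ratio > 0.95 & ratio < 1.05))
})

test_that("the loop multiplier scales loop amplitudes only", {
  spec <- ensemble_spec(strrep("A", 20), n_frames = 800L, amplitude = 0.2,
                        loop_range = c(8, 12), loop_multiplier = 3,
                        seed = 17L)
  e <- sample_gaussian_ensemble(spec)
  ref <- build_reference_chain(spec$sequence)
  cai <- select_atoms(ref, "calpha")
  rmsf <- sqrt(rowMeans(sapply(e$frames, function(f)
    rowSums((f[cai, ] - ref$xyz[cai, ])^2))))
  expect_gt(min(rmsf[8:12]), max(rmsf[c(1:7, 13:20)]))
})

test_that("residues move rigidly in the gaussian sampler", {
  e <- toy_ensemble("KW", n_frames = 3L, seed = 8L)
  ref <- build_reference_chain("KW")
  for (f in e$frames) {
    d <- f - ref$xyz
    for (r in 1:2) {
      rows <- which(e$topology$residue_number == r)
      expect_equal(max(d[rows, 1]) - min(d[rows, 1]), 0, tolerance = 1e-12)
      expect_equal(max(d[rows, 3]) - min(d[rows, 3]), 0, tolerance = 1e-12)
    }
  }
})

test_that("ENM at zero temperature stays at the equilibrated reference", {
  spec <- ensemble_spec(strrep("A", 25), n_frames = 5L, sampler = "enm",
                        seed = 4L, enm = list(kT = 0, n_equil = 500L))
  e <- sample_enm_ensemble(spec)
  rf <- residue_fluctuation(e, align = FALSE)
  expect_true(all(rf$rmsf < 1e-8))
})

test_that("ENM trajectories are seed-deterministic", {
  spec <- ensemble_spec(strrep("A", 20), n_frames = 4L, sampler = "enm",
                        seed = 12L, enm = list(n_equil = 200L, stride = 5L))
  expect_identical(sample_enm_ensemble(spec)$frames,
                   sample_enm_ensemble(spec)$frames)
})

test_that("a low-contact ENM loop fluctuates more than the packed core", {
  seqs <- fhit_sequence()
  hits <- sapply(1:5, function(s) {
    spec <- ensemble_spec(seqs, n_frames = 40L, sampler = "enm",
                          loop_range = c(108, 127), seed = s)
    rf <- residue_fluctuation(sample_enm_ensemble(spec))
    loop <- rf$residue_number >= 108 & rf$residue_number <= 127
    mean(rf$rmsf[loop]) > mean(rf$rmsf[!loop])
  })
  expect_true(all(hits))
})

test_that("fragment pair plants the mimetic window in the amplitudes", {
  seqs <- fhit_sequence()
  pspec <- ensemble_spec(seqs, n_frames = 400L, amplitude = 0.3,
                         loop_range = c(108, 127), seed = 21L)
  mspec <- mimicry_spec(c(1, 38), c(8, 12), outside_scale = 3, seed = 22L)
  pair <- sample_fragment_pair(pspec, mspec)
  expect_equal(length(unique(pair$fragment$topology$residue_number)), 38L)
  expect_equal(n_frames(pair$fragment), 400L)

  ref <- build_reference_chain(substr(seqs, 1, 38))
  cai <- select_atoms(ref, "calpha")
  rmsf <- sqrt(rowMeans(sapply(pair$fragment$frames, function(f)
    rowSums((f[cai, ] - ref$xyz[cai, ])^2))))
  # inside the window amplitudes match the protein (0.3), outside 3x
  expect_equal(mean(rmsf[8:12]) / (0.3 * sqrt(3)), 1, tolerance = 0.1)
  expect_equal(mean(rmsf[-(8:12)]) / (0.9 * sqrt(3)), 1, tolerance = 0.1)

  expect_error(
    sample_fragment_pair(pspec, mimicry_spec(c(1, 38), c(30, 40), seed = 1)),
    "within")
})

test_that("a null fragment pair (outside_scale 1) shows no planted signal", {
  seqs <- fhit_sequence()
  pspec <- ensemble_spec(seqs, n_frames = 600L, amplitude = 0.3, seed = 31L)
  mspec <- mimicry_spec(c(1, 38), c(8, 12), outside_scale = 1, seed = 32L)
  pair <- sample_fragment_pair(pspec, mspec)
  rp <- residue_fluctuation(pair$protein)
  rf <- residue_fluctuation(pair$fragment)
  d <- rfa_difference_profile(rf, rp[rp$residue_number <= 38, ],
                              residue_mapping(1:38, 1:38))
  # windowed differences shrink toward zero: all small relative to the RMSF
  expect_lt(mean(d$delta), 0.1 * mean(rp$rmsf[rp$residue_number <= 38]))
})
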