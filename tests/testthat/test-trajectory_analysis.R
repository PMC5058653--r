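test_that("identical frames give zero RMSF; one frame is an error", {
  rc <- build_reference_chain("QHLIKPS")
  e <- ensemble(list(rc, rc, rc))
  rf <- residue_fluctuation(e)
  expect_true(all(rf$rmsf < 1e-12))
  expect_error(residue_fluctuation(ensemble(rc)), "at least 2")
})

test_that("RMSF recovers the gaussian sampler amplitude", {
  a <- 0.5
  spec <- ensemble_spec(strrep("A", 30), n_frames = 1000L, amplitude = a,
                        seed = 14L)
  rf <- residue_fluctuation(sample_gaussian_ensemble(spec), align = FALSE)
  expect_equal(rf$rmsf / (a * sqrt(3)), rep(1, 30), tolerance = 0.05)
  # the residue-heavy basis agrees for rigid-residue displacements
  rh <- residue_fluctuation(sample_gaussian_ensemble(spec),
                            atom_basis = "residue_heavy", align = FALSE)
  expect_equal(rh$rmsf, rf$rmsf, tolerance = 1e-9)
})

test_that("pairwise matrix is symmetric, zero-diagonal, and recomputable", {
  e <- toy_ensemble("QHLIKPS", n_frames = 5L, seed = 4)
  pw <- pairwise_rmsd_matrix(e)
  m <- pw$values
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(diag(m), rep(0, 5))
  bb <- select_atoms(e, "backbone")
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j], rmsd(get_frame(e, i), get_frame(e, j), bb),
                 tolerance = 1e-9)

  two <- e; two$frames <- rep(e$frames[1], 2)
  expect_equal(pairwise_rmsd_matrix(two)$values, matrix(0, 2, 2),
               tolerance = 1e-9)
})

test_that("cross matrix has fragment x protein shape with zero self-diagonal", {
  seqs <- fhit_sequence()
  pspec <- ensemble_spec(seqs, n_frames = 4L, seed = 5L)
  prot <- sample_gaussian_ensemble(pspec)
  # fragment = protein restricted to residues 1-38
  keep <- prot$topology$residue_number <= 38
  frag <- structure(list(topology = prot$topology[keep, ],
                         frames = lapply(prot$frames, function(f) f[keep, ]),
                         label = "restriction"), class = "Ensemble")
  cm <- cross_rmsd_matrix(frag, prot)
  expect_equal(dim(cm$values), c(4L, 4L))
  expect_equal(diag(cm$values), rep(0, 4), tolerance = 1e-9)

  frag3 <- frag; frag3$frames <- frag$frames[1:3]
  expect_equal(dim(cross_rmsd_matrix(frag3, prot)$values), c(3L, 4L))
})

test_that("cross matrix rejects mismatched atom correspondence", {
  prot <- toy_ensemble("QHLIKPS", n_frames = 2L, seed = 6)
  frag <- toy_ensemble("QHLIKPG", n_frames = 2L, seed = 7)  # Gly lacks CB
  expect_error(cross_rmsd_matrix(frag, prot), "correspondence")
})

test_that("fraction_in_range counts closed-interval entries", {
  m <- matrix(c(1.0, 2.5, 3.9, 4.1), 2, byrow = TRUE)
  expect_equal(fraction_in_range(m), 0.5)
  expect_equal(fraction_in_range(matrix(3, 2, 2)), 1)
  expect_equal(fraction_in_range(matrix(5, 2, 2)), 0)
  expect_equal(fraction_in_range(matrix(c(2, 4), 1)), 1)  # bounds included
  expect_equal(fraction_in_range(m, -1e9, 1e9), 1)
  expect_equal(fraction_in_range(m, by = "frame"), c(0.5, 0.5))
  expect_error(fraction_in_range(m, 4, 2), "lo")
  expect_error(fraction_in_range(matrix(numeric(0), 0, 0)), "empty")
})

test_that("degenerate clustering cases: all singletons and one cluster", {
  d <- matrix(5, 4, 4); diag(d) <- 0
  cl <- average_linkage_cluster(d, 2)
  expect_equal(cl$assignment, 1:4)
  d2 <- matrix(1, 4, 4); diag(d2) <- 0
  cl2 <- average_linkage_cluster(d2, 2)
  expect_equal(cl2$assignment, rep(1L, 4))
  expect_error(average_linkage_cluster(matrix(1:9, 3), 2), "symmetric")
})

test_that("clustering equals the naive exhaustive agglomeration oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(runif(3 * n) * 4, n)
    d <- as.matrix(dist(x))
    cutoff <- runif(1, 0.5, 4)
    mine <- average_linkage_cluster(d, cutoff)$assignment
    oracle <- naive_average_linkage(d, cutoff)
    expect_equal(canonical_partition(mine), canonical_partition(oracle))
  }
})

test_that("clustering agrees with hclust/cutree average linkage", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- as.matrix(dist(matrix(runif(3 * n) * 5, n)))
    cutoff <- runif(1, 1, 4)
    mine <- average_linkage_cluster(d, cutoff)$assignment
    ref <- stats::cutree(stats::hclust(stats::as.dist(d),
                                       method = "average"), h = cutoff)
    expect_equal(canonical_partition(mine), canonical_partition(ref))
  }
})

test_that("clustering is invariant to frame order up to relabelling", {
  set.seed(31)
  d <- as.matrix(dist(matrix(runif(24) * 3, 8)))
  base <- average_linkage_cluster(d, 1.5)$assignment
  for (i in 1:5) {
    perm <- sample(8)
    permuted <- average_linkage_cluster(d[perm, perm], 1.5)$assignment
    # map back to original frame order and compare as partitions
    back <- integer(8); back[perm] <- permuted
    same <- outer(base, base, "==") == outer(back, back, "==")
    expect_true(all(same))
  }
})

test_that("medoid representatives minimise mean distance, ties to lowest", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 1; d[2, 3] <- d[3, 2] <- 2
  cl <- average_linkage_cluster(d, 3)
  expect_equal(cl$assignment, rep(1L, 3))
  expect_equal(unname(cl$representatives), 1L)

  dd <- matrix(1, 4, 4); diag(dd) <- 0
  cle <- average_linkage_cluster(dd, 3)
  expect_equal(unname(cle$representatives), 1L)  # all-equal: lowest index

  ds <- matrix(10, 2, 2); diag(ds) <- 0
  cls <- average_linkage_cluster(ds, 1)
  expect_equal(unname(cls$representatives), c(1L, 2L))  # singletons
})
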