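test_that("PDB write/read round trip preserves topology and coordinates", {
  for (seed in 1:3) {
    e <- toy_ensemble("QHLIKPS", n_frames = 4L, seed = seed)
    path <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_models(e, path)
    e2 <- read_pdb_models(path)
    expect_identical(topology_key(e2), topology_key(e))
    expect_equal(n_frames(e2), n_frames(e))
    for (f in seq_len(n_frames(e)))
      expect_equal(e2$frames[[f]], e$frames[[f]], tolerance = 1e-3,
                   ignore_attr = TRUE)
  }
})

test_that("a 150-model file yields a 150-frame ensemble", {
  e <- toy_ensemble("GAS", n_frames = 150L, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(e, path)
  expect_equal(n_frames(read_pdb_models(path)), 150L)
})

test_that("single-model files and empty ensembles behave at the edges", {
  e1 <- ensemble(get_frame(toy_ensemble(n_frames = 2L), 1L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(e1, path)
  back <- read_pdb_models(path)
  expect_equal(n_frames(back), 1L)
  expect_equal(nrow(back$topology), nrow(e1$topology))
  expect_error(ensemble(list()), "at least one frame")
})

test_that("a model with a missing atom triggers a topology error naming it", {
  e <- toy_ensemble("GAS", n_frames = 3L, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(e, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  # drop one atom from the second model
  n_atoms <- nrow(e$topology)
  drop <- atom_lines[n_atoms + 2L]
  writeLines(lines[-drop], path)
  expect_error(read_pdb_models(path), "model 2")
})

test_that("hydrogens and water records are excluded at parse time", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       2.000   1.000   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A   2       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  e <- read_pdb_models(path)
  expect_equal(nrow(e$topology), 2L)
  expect_false(any(e$topology$element == "H"))
  expect_false(any(e$topology$residue_name == "HOH"))
})

test_that("sequence extraction maps three-letter codes and flags unknowns", {
  rc <- build_reference_chain("QHLIKPS")
  expect_equal(extract_sequence(rc), "QHLIKPS")
  single <- manual_conformer(list(
    list(1, "ALA", "CA", "C", 0, 0, 0),
    list(1, "ALA", "CB", "C", 1.5, 0, 0)))
  expect_equal(extract_sequence(single), "A")
  odd <- manual_conformer(list(list(1, "XYZ", "CA", "C", 0, 0, 0)))
  expect_warning(s <- extract_sequence(odd), "XYZ")
  expect_equal(s, "X")
})

test_that("atom selections partition the conformer and count correctly", {
  rc <- build_reference_chain(fhit_sequence(c(1, 20)))
  all_idx <- select_atoms(rc, "all")
  bb <- select_atoms(rc, "backbone")
  sc <- select_atoms(rc, "sidechain")
  expect_setequal(c(bb, sc), all_idx)
  expect_length(intersect(bb, sc), 0)
  expect_length(select_atoms(rc, "calpha"), 20L)
  # 4 backbone atoms per residue over an inclusive 7-residue range
  expect_length(select_atoms(rc, "backbone", residue_range(7, 13)), 28L)
  # glycine (position 6 of Fhit) has no heavy sidechain atoms
  expect_error(select_atoms(rc, "sidechain", residue_range(6, 6)),
               "empty")
})

test_that("missing-residue detection reports maximal sorted ranges", {
  full_seq <- fhit_sequence()
  rc <- build_reference_chain(full_seq)
  keep <- rc$topology$residue_number %in% c(2:107, 128:147)
  partial <- conformer(rc$topology[keep, ], rc$xyz[keep, ])
  gaps <- detect_missing_residues(partial, full_seq)
  expect_length(gaps, 2L)
  expect_equal(c(gaps[[1]]$start, gaps[[1]]$end), c(1L, 1L))
  expect_equal(c(gaps[[2]]$start, gaps[[2]]$end), c(108L, 127L))
  expect_length(detect_missing_residues(rc, full_seq), 0L)

  keep2 <- !(rc$topology$residue_number %in% 40:42)
  partial2 <- conformer(rc$topology[keep2, ], rc$xyz[keep2, ])
  gaps2 <- detect_missing_residues(partial2, full_seq)
  expect_length(gaps2, 1L)
  expect_equal(c(gaps2[[1]]$start, gaps2[[1]]$end), c(40L, 42L))
})

test_that("missing ranges are the exact complement of observed positions", {
  set.seed(11)
  full_seq <- fhit_sequence()
  rc <- build_reference_chain(full_seq)
  for (rep in 1:5) {
    present <- sort(sample(1:147, 100))
    keep <- rc$topology$residue_number %in% present
    part <- conformer(rc$topology[keep, ], rc$xyz[keep, ])
    gaps <- detect_missing_residues(part, full_seq)
    covered <- unlist(lapply(gaps, function(g) g$start:g$end))
    expect_setequal(covered, setdiff(1:147, present))
    if (length(gaps) > 1) {
      starts <- vapply(gaps, function(g) g$start, integer(1))
      ends <- vapply(gaps, function(g) g$end, integer(1))
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1] > ends[-length(ends)] + 1L))
    }
  }
})
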