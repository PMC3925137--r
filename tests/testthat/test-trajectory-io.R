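test_that("multi-MODEL PDB round trip preserves counts, topology, coordinates", {
  f <- build_zipper_fibril("aa-apho",
    fibril_build_params(n_layers = 4, twist_per_layer = 10,
                        residues_per_strand = 5,
                        include_backbone_atoms = TRUE))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(f, p)
  rd <- read_pdb(p)
  expect_equal(n_frames(rd$trajectory), 1)
  expect_equal(nrow(rd$structure$atoms), nrow(f$atoms))
  expect_identical(rd$structure$atoms$atom_name, f$atoms$atom_name)
  expect_identical(rd$structure$atoms$layer_index, f$atoms$layer_index)
  expect_identical(rd$structure$atoms$strand_index, f$atoms$strand_index)
  expect_lt(max(abs(rd$structure$coords - f$coords)), 1e-3)

  tr <- sample_beam_trajectory(small_beam_spec(), 3, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, p2)
  rd2 <- read_pdb(p2)
  expect_equal(n_frames(rd2$trajectory), 3)
  expect_lt(max(abs(rd2$trajectory$coords - round(tr$coords, 3))), 1e-9)
})

test_that("PDB reader reports malformed and structurally inconsistent files", {
  tr <- sample_beam_trajectory(small_beam_spec(), 2, seed = 1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, p)
  lines <- readLines(p)

  bad <- lines
  i <- grep("^ATOM", bad)[4]
  substr(bad[i], 31, 38) <- "  xx.xxx"
  pb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, pb)
  expect_error(read_pdb(pb), paste("line", i))

  am <- grep("^ATOM", lines)
  m2 <- grep("^MODEL", lines)[2]
  pc <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-am[am > m2][1]], pc)
  expect_error(read_pdb(pc), "inconsistent atom count")

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "no such file")
})

test_that("XYZ trajectory round trip and malformed-frame errors", {
  tr <- sample_beam_trajectory(small_beam_spec(), 3, seed = 2)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, p)
  back <- read_xyz_trajectory(p, tr$atoms)
  expect_equal(n_frames(back), 3)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3 + 1e-12)

  # wrong atom-count line
  lines <- readLines(p)
  lines[1] <- "999"
  pb <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, pb)
  expect_error(read_xyz_trajectory(pb), "truncated|count")
  # element mismatch against the supplied topology
  at2 <- tr$atoms; at2$element[1] <- "O"
  expect_error(read_xyz_trajectory(p, at2), "element")
})

test_that("C-alpha selection keeps one site per residue and errors when absent", {
  f <- build_zipper_fibril("co-pho",
    fibril_build_params(n_layers = 6, residues_per_strand = 9,
                        include_backbone_atoms = TRUE))
  traj <- fibril_trajectory(array(f$coords, dim = c(nrow(f$coords), 3, 1)),
                            f$atoms)
  ca <- select_calpha(traj)
  expect_equal(nrow(ca$atoms), 9 * 12)   # one CA per residue x 12 strands
  # bead-only synthetic trajectory: identity selection
  tr <- sample_beam_trajectory(small_beam_spec(), 1, seed = 1)
  expect_equal(nrow(select_calpha(tr)$atoms), nrow(tr$atoms))
  # no CA at all
  at <- f$atoms[f$atoms$atom_name == "O", ]
  co <- f$coords[f$atoms$atom_name == "O", ]
  tro <- fibril_trajectory(array(co, dim = c(nrow(co), 3, 1)), at)
  expect_error(select_calpha(tro), "C-alpha")
})

test_that("frame windowing honours discard fraction and stride", {
  tr <- sample_beam_trajectory(small_beam_spec(), 100, seed = 3)
  expect_equal(n_frames(window_frames(tr, 0.5, 1)), 50)
  expect_equal(n_frames(window_frames(tr, 0, 10)), 10)
  w <- window_frames(tr, 0, 4)
  expect_equal(w$time_per_frame, tr$time_per_frame * 4)
  tr10 <- window_frames(tr, 0.9, 1)
  expect_error(window_frames(window_frames(tr, 0, 10), 0.99), "no frames")
  # selection and windowing commute
  a <- select_calpha(window_frames(tr, 0.3, 3))
  b <- window_frames(select_calpha(tr), 0.3, 3)
  expect_identical(a$coords, b$coords)
})
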