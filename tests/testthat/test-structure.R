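fixture_pair <- function(seed = 1, n_frames = 2, noise = 0.1) {
  generate_barrel_trajectory(split_gfp_fixture("cis", seed = seed)$spec,
                             n_frames = n_frames, thermal_noise = noise)
}

test_that("superposition: self gives zero, rigid motions are removed", {
  g <- fixture_pair()
  f1 <- get_frame(g$trajectory, 1)
  s <- superpose(f1, f1)
  expect_lt(s$rmsd, 1e-9)
  f2 <- strandgate:::transform_frame(f1, random_rotation(4), c(3, -2, 5))
  expect_lt(superpose(f2, f1)$rmsd, 1e-6)
  expect_lt(superpose(f2, f1, select_backbone)$rmsd, 1e-6)
})

test_that("superposition matches brute-force rotation search on clouds", {
  set.seed(7)
  for (i in 1:3) {
    A <- matrix(rnorm(30), 10)
    B <- matrix(rnorm(30), 10)
    fa <- make_frame(data.frame(serial = 1:10, atom_name = "CA",
                                element = "C", resno = 1:10, resid = "ALA",
                                chain = "A"), A)
    fb <- make_frame(fa$atoms, B)
    got <- superpose(fa, fb)$rmsd
    expect_equal(got, oracle_min_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("superposition RMSD is symmetric and rejects degenerate input", {
  set.seed(8)
  A <- matrix(rnorm(30), 10)
  B <- matrix(rnorm(30), 10)
  at <- data.frame(serial = 1:10, atom_name = "CA", element = "C",
                   resno = 1:10, resid = "ALA", chain = "A")
  fa <- make_frame(at, A); fb <- make_frame(at, B)
  expect_equal(superpose(fa, fb)$rmsd, superpose(fb, fa)$rmsd,
               tolerance = 1e-6)
  expect_error(superpose(fa, fb, 1:2), "at least 3")
  line <- make_frame(at, cbind(1:10, 2 * (1:10), -(1:10)))
  expect_error(superpose(line, line), "collinear")
})

test_that("rmsd series: zero for the reference, grows with noise", {
  spec <- barrel_fixture_spec()   # no alternating contacts: frames identical
  g0 <- generate_barrel_trajectory(spec, n_frames = 4, thermal_noise = 0)
  ref <- get_frame(g0$trajectory, 1)
  expect_equal(rmsd_series(g0$trajectory, ref), rep(0, 4),
               tolerance = 1e-9)
  spec2 <- split_gfp_fixture("cis")$spec
  ref <- get_frame(generate_barrel_trajectory(spec2, n_frames = 1)$trajectory, 1)
  means <- sapply(c(0.1, 0.2, 0.4), function(s) {
    sp <- spec2; sp$seed <- 99
    g <- generate_barrel_trajectory(sp, n_frames = 5, thermal_noise = s)
    mean(rmsd_series(g$trajectory, ref, select_heavy))
  })
  expect_true(all(diff(means) > 0))
})

test_that("chromophore dihedrals read back the generated state", {
  for (phi in c(0, 60, 160, 180)) {
    spec <- split_gfp_fixture("cis", phi_I = phi)$spec
    g <- generate_barrel_trajectory(spec, n_frames = 1)
    f <- get_frame(g$trajectory, 1)
    expect_equal(dihedral(f, g$topology$dihedral_specs$phi_I), phi,
                 tolerance = 1e-6)
    expect_equal(dihedral(f, g$topology$dihedral_specs$phi_P), 0,
                 tolerance = 1e-6)
  }
  # 160 degrees falls on the trans side of the cycle
  expect_true(strandgate:::in_circular_region(160, c(150, 210)))
  expect_false(strandgate:::in_circular_region(160, c(-30, 30)))
})

test_that("solvent accessibility: isolated-sphere closed form and probes", {
  at <- data.frame(serial = 1L, atom_name = "CA", element = "C",
                   resno = 1L, resid = "ALA", chain = "A")
  f <- make_frame(at, matrix(c(0, 0, 0), 1))
  for (p in c(1.4, 2.8)) {
    a <- sum(sasa(f, probe_radius = p))
    expect_equal(a, 4 * pi * (1.7 + p)^2, tolerance = 0.02 * a)
  }
  expect_gt(sum(sasa(f, probe_radius = 2.8)), sum(sasa(f, probe_radius = 1.4)))
  bad <- make_frame(transform(at, element = "Zz"), matrix(0, 1, 3))
  expect_error(sasa(bad), "unknown element")
})

test_that("burial reduces SASA and totals are rigid-motion invariant", {
  # one atom, then the same atom caged by a shell of neighbors
  shell <- rbind(c(0, 0, 0),
                 3 * rbind(diag(3), -diag(3),
                           c(1, 1, 1) / sqrt(3), -c(1, 1, 1) / sqrt(3)))
  at <- data.frame(serial = seq_len(nrow(shell)), atom_name = "CA",
                   element = "C", resno = seq_len(nrow(shell)),
                   resid = "ALA", chain = "A")
  f <- make_frame(at, shell)
  caged <- sasa(f, atom_subset = 1)
  free <- sasa(make_frame(at[1, ], shell[1, , drop = FALSE]))
  expect_lt(sum(caged), 0.6 * sum(free))
  moved <- make_frame(at, sweep(shell %*% random_rotation(3), 2,
                                c(5, 1, -2), "+"))
  expect_equal(sum(sasa(moved)), sum(sasa(f)), tolerance = 5e-3)
})

test_that("orientation: parity rule on the ideal fixture", {
  g <- generate_barrel_trajectory(barrel_fixture_spec(seed = 3),
                                  n_frames = 1)
  f <- get_frame(g$trajectory, 1)
  lab <- classify_orientation(f, g$topology)
  s10 <- strandgate:::strand_residues(g$topology, "10")
  expect_true(all(lab[as.character(s10[s10 %% 2 == 1])] == "in"))
  expect_true(all(lab[as.character(s10[s10 %% 2 == 0])] == "out"))
})

test_that("orientation: labels survive rigid motion; forced-in is in", {
  g <- generate_barrel_trajectory(barrel_fixture_spec(seed = 5),
                                  n_frames = 1)
  f <- get_frame(g$trajectory, 1)
  lab <- classify_orientation(f, g$topology)
  f2 <- strandgate:::transform_frame(f, random_rotation(11), c(-4, 9, 2))
  expect_identical(classify_orientation(f2, g$topology), lab)
  # reflect every CB through its CA along the radial direction: all "in"
  ax <- strandgate:::barrel_axis(f, g$topology)
  f3 <- f
  for (rn in strandgate:::strand_residues(g$topology, c("7", "10", "11"))) {
    ca <- which(f$atoms$resno == rn & f$atoms$atom_name == "CA")
    cb <- which(f$atoms$resno == rn & f$atoms$atom_name == "CB")
    if (length(cb) != 1) next
    v <- f$xyz[ca, ] - ax$center
    radial <- v - sum(v * ax$axis) * ax$axis
    f3$xyz[cb, ] <- f$xyz[ca, ] - 1.5 * radial / sqrt(sum(radial^2))
  }
  lab3 <- classify_orientation(f3, g$topology)
  nonterm <- setdiff(names(lab3), as.character(207:216))
  expect_true(all(lab3[nonterm] == "in"))
})

test_that("trajectory I/O round-trips at PDB precision", {
  g <- fixture_pair(seed = 6, n_frames = 3)
  pdb <- tempfile(fileext = ".pdb")
  json <- sub("pdb$", "json", pdb)
  write_trajectory(g$trajectory, g$topology, pdb, json)
  back <- read_trajectory(pdb, json)
  expect_equal(n_frames(back$trajectory), 3)
  expect_equal(back$trajectory$coords, round(g$trajectory$coords, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$topology$strand, g$topology$strand)
  expect_identical(back$topology$dihedral_specs, g$topology$dihedral_specs)
  # single-model file reads as one frame
  g1 <- fixture_pair(seed = 6, n_frames = 1)
  write_trajectory(g1$trajectory, g1$topology, pdb, json)
  expect_equal(n_frames(read_trajectory(pdb, json)$trajectory), 1)
})

test_that("inconsistent models are a format error", {
  g <- fixture_pair(seed = 6, n_frames = 2)
  pdb <- tempfile(fileext = ".pdb")
  json <- sub("pdb$", "json", pdb)
  write_trajectory(g$trajectory, g$topology, pdb, json)
  lines <- readLines(pdb)
  drop <- max(grep("^ATOM", lines))
  writeLines(lines[-drop], pdb)
  expect_error(read_trajectory(pdb, json), "format error")
})
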