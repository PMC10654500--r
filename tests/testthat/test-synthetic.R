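test_that("generation is deterministic under the spec seed", {
  spec <- split_gfp_fixture("cis", seed = 42)$spec
  a <- generate_barrel_trajectory(spec, n_frames = 3, thermal_noise = 0.2)
  b <- generate_barrel_trajectory(spec, n_frames = 3, thermal_noise = 0.2)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  spec2 <- split_gfp_fixture("cis", seed = 43)$spec
  c <- generate_barrel_trajectory(spec2, n_frames = 3, thermal_noise = 0.2)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("zero noise with no event gives identical frames", {
  g <- generate_barrel_trajectory(barrel_fixture_spec(), n_frames = 5)
  for (f in 2:5)
    expect_identical(g$trajectory$coords[, , f], g$trajectory$coords[, , 1])
})

test_that("planted interactions are detected, non-planted pairs are not", {
  # sparse planted set on the ideal fixture, noise-free
  si <- data.frame(res_a = c(201, 204, 208),
                   res_b = c(151, 219, 215),
                   kind = c("stacking", "hbond", "salt_bridge"),
                   phase = "all", mc_b = FALSE, breaker = "a")
  nm <- c("201" = "TYR", "151" = "TYR", "204" = "SER", "219" = "ASN",
          "208" = "LYS", "215" = "GLU")
  spec <- barrel_fixture_spec(residue_names = nm,
                              sidechain_interactions = si, seed = 4)
  g <- generate_barrel_trajectory(spec, n_frames = 1)
  det <- detect_interactions(get_frame(g$trajectory, 1), g$topology)
  sc <- det[det$side_a == "sc" | det$side_b == "sc", ]
  got <- sort(paste(pmin(sc$res_a, sc$res_b), pmax(sc$res_a, sc$res_b),
                    sc$kind))
  want <- sort(paste(pmin(si$res_a, si$res_b), pmax(si$res_a, si$res_b),
                     si$kind))
  expect_identical(got, want)
  # backbone ladder fully present, and only where planted
  mc <- det[det$side_a == "mc" & det$side_b == "mc", ]
  bb <- attr(g$trajectory, "planted")$backbone
  expect_setequal(paste(pmin(mc$res_a, mc$res_b), pmax(mc$res_a, mc$res_b)),
                  unique(paste(pmin(bb$donor, bb$acceptor),
                               pmax(bb$donor, bb$acceptor))))
})

test_that("planted event losses are read back in order by re-detection", {
  fx <- split_gfp_fixture("trans_anneal", seed = 11)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 70,
                                  thermal_noise = 0, event = fx$event)
  pl <- attr(g$trajectory, "planted")$anchor_order
  expect_true(all(diff(pl$last_present_frame) > 0))
  # geometric re-detection of the exact planted interactions
  want_key <- vapply(seq_len(nrow(pl)), function(i) {
    side_b <- if (pl$mc_b[i]) "mc" else "sc"
    atom_b <- if (pl$mc_b[i]) "O" else "SC"
    strandgate:::interaction_key(pl$kind[i], pl$res_a[i], "sc", "SC",
                                 pl$res_b[i], side_b, atom_b)
  }, character(1))
  presence <- sapply(seq_len(60), function(f)
    want_key %in% detect_interactions(get_frame(g$trajectory, f),
                                      g$topology)$key)
  last_seen <- apply(presence, 1, function(p) max(which(p)))
  expect_identical(last_seen, as.integer(pl$last_present_frame))
})

test_that("post-heating state keeps only the two residual sidechain sites", {
  fx <- split_gfp_fixture("trans_postheat", seed = 3)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 10)
  tab <- occupancy(g$trajectory, g$topology)
  s10 <- strandgate:::strand_residues(g$topology, "10")
  sc10 <- sort(unique(c(
    tab$res_a[tab$side_a == "sc" & tab$res_a %in% s10 & tab$occupancy > 0],
    tab$res_b[tab$side_b == "sc" & tab$res_b %in% s10 & tab$occupancy > 0])))
  expect_identical(as.integer(sc10), c(200L, 202L))
})

test_that("planted interactions referencing absent residues are rejected", {
  si <- data.frame(res_a = 500, res_b = 151, kind = "hbond",
                   phase = "all", mc_b = FALSE, breaker = "a")
  expect_error(barrel_fixture_spec(residue_names = c("151" = "TYR"),
                                   sidechain_interactions = si),
               "fixture error")
})

test_that("umbrella samples reach the stiff-bias Gaussian limit", {
  pot <- periodic_potential("zero", temperature = 300)
  w <- generate_umbrella_samples(pot, centers = 0, k_bias = 0.025,
                                 n_per_window = 5000, seed = 2)[[1]]
  kT <- 1.98720425864083e-3 * 300
  expect_lt(abs(mean(w$samples)), 0.3)
  expect_equal(sd(w$samples), sqrt(kT / 0.025), tolerance = 0.05)
  # determinism
  w2 <- generate_umbrella_samples(pot, centers = 0, k_bias = 0.025,
                                  n_per_window = 5000, seed = 2)[[1]]
  expect_identical(w$samples, w2$samples)
  expect_error(generate_umbrella_samples(pot, centers = numeric(0)),
               "no umbrella windows")
})

test_that("double-well windows at +90 and -90 are mirror images", {
  pot <- periodic_potential("sinsq", height = 5, temperature = 300)
  w <- generate_umbrella_samples(pot, centers = c(-90, 90), k_bias = 0.01,
                                 n_per_window = 4000, seed = 5)
  ks <- suppressWarnings(ks.test(w[[2]]$samples, -w[[1]]$samples))
  expect_gt(ks$p.value, 0.01)
})

test_that("exchange traces follow the closed form and validate input", {
  t <- seq(0, 50, 5)
  flat <- generate_exchange_trace(0, amplitude = 2, offset = 1, times = t)
  expect_equal(flat$signal, rep(1, length(t)))
  tr <- generate_exchange_trace(0.1, amplitude = 2, offset = 1,
                                times = c(0, 10))
  expect_equal(tr$signal[2] - 1, 2 * (1 - exp(-1)))
  expect_error(generate_exchange_trace(0.1, 1, 0, times = c(0, 5, 5)),
               "increasing")
  expect_error(generate_exchange_trace(-1, 1, 0, times = c(0, 1)),
               "non-negative")
})
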