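anneal_run <- function(seed, event = TRUE, noise = 0.2, n_frames = 120) {
  fx <- split_gfp_fixture("trans_anneal", seed = seed)
  generate_barrel_trajectory(fx$spec, n_frames = n_frames,
                             thermal_noise = noise,
                             event = if (event) fx$event else NULL,
                             schedule = annealing_schedule(n_frames))
}

test_that("native-contact fraction: reference unity, displaced zero", {
  g <- anneal_run(1, event = FALSE, noise = 0)
  ref <- get_frame(g$trajectory, 1)
  q <- native_contact_fraction(g$trajectory, ref, g$topology)
  expect_equal(unname(q[1]), 1)
  moved <- g$trajectory
  s10 <- which(moved$atoms$resno %in%
                 strandgate:::strand_residues(g$topology, "10"))
  moved$coords[s10, 1, 2] <- moved$coords[s10, 1, 2] + 50
  q2 <- native_contact_fraction(moved, ref, g$topology)
  expect_equal(unname(q2[2]), 0)
})

test_that("Q decays after a planted onset and matches a recount", {
  g <- anneal_run(2, noise = 0.1)
  ref <- get_frame(g$trajectory, 1)
  q <- native_contact_fraction(g$trajectory, ref, g$topology)
  post <- q[50:70]
  expect_true(all(diff(post) <= 0.15))      # decays (small jitter allowed)
  expect_lt(q[70], 0.2)
  # recount a few frames by brute force
  contacts <- attr(q, "contacts")
  for (f in c(1, 55, 90)) {
    xyz <- g$trajectory$coords[, , f]
    kept <- mapply(function(a, b) {
      ia <- which(g$trajectory$atoms$resno == a)
      ib <- which(g$trajectory$atoms$resno == b)
      min(as.matrix(dist(rbind(xyz[ia, ], xyz[ib, ])))[
        seq_along(ia), length(ia) + seq_along(ib)]) <= 1.2 * 5.5
    }, contacts$res_a, contacts$res_b)
    expect_equal(unname(q[f]), mean(kept))
  }
})

test_that("dissociation detection: planted events found, stable runs not", {
  g <- anneal_run(3)
  ev <- detect_dissociation(g$trajectory, g$topology)
  expect_false(is.null(ev))
  expect_gte(ev$onset_frame, 50)
  expect_lte(ev$onset_frame, 60)
  expect_equal(ev$onset_temperature, 600)
  stable <- anneal_run(4, event = FALSE)
  expect_null(detect_dissociation(stable$trajectory, stable$topology))
  # q_threshold = 1 fires at the first sustained loss of any contact
  ev2 <- detect_dissociation(g$trajectory, g$topology, q_threshold = 1)
  expect_lt(ev2$onset_frame, 50)
})

test_that("anchor-loss ordering recovers the planted sequence", {
  g <- anneal_run(5)
  ao <- anchor_loss_order(g$trajectory, g$topology)
  pl <- attr(g$trajectory, "planted")$anchor_order
  key_of <- function(p) vapply(seq_len(nrow(p)), function(i) {
    side_b <- if (p$mc_b[i]) "mc" else "sc"
    atom_b <- if (p$mc_b[i]) "O" else "SC"
    strandgate:::interaction_key(p$kind[i], p$res_a[i], "sc", "SC",
                                 p$res_b[i], side_b, atom_b)
  }, character(1))
  hit <- match(key_of(pl), ao$key)
  expect_false(anyNA(hit))
  expect_false(is.unsorted(hit))            # same order as planted
  expect_false(is.unsorted(ao$last_present_frame[hit]))
})

test_that("anchor ordering is atom-permutation stable and smoothing-monotone", {
  g <- anneal_run(6, n_frames = 80)
  ao <- anchor_loss_order(g$trajectory, g$topology)
  perm <- sample(nrow(g$trajectory$atoms))
  tp <- g$trajectory
  tp$atoms <- tp$atoms[perm, ]
  tp$coords <- tp$coords[perm, , , drop = FALSE]
  ao2 <- anchor_loss_order(tp, g$topology)
  expect_identical(ao$key, ao2$key)
  expect_identical(ao$last_present_frame, ao2$last_present_frame)
  ao5 <- anchor_loss_order(g$trajectory, g$topology, smoothing = 8)
  common <- intersect(ao$key, ao5$key)
  expect_true(all(ao5$last_present_frame[match(common, ao5$key)] <=
                    ao$last_present_frame[match(common, ao$key)]))
})

test_that("an unbroken interaction persists to the final frame", {
  fx <- split_gfp_fixture("trans_postheat", seed = 7)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 30)
  ao <- anchor_loss_order(g$trajectory, g$topology)
  stack <- ao[ao$kind == "stacking", ]
  expect_equal(stack$last_present_frame, 30)
})

test_that("terminal solvation precedes the dissociation onset", {
  g <- anneal_run(8, noise = 0.1, n_frames = 90)
  cross <- terminal_solvation(g$trajectory, g$topology)
  expect_equal(as.integer(cross), 1L)       # solvated from the start
  ev <- detect_dissociation(g$trajectory, g$topology)
  expect_lt(as.integer(cross), ev$onset_frame)
  expect_null(terminal_solvation(g$trajectory, g$topology,
                                 sasa_threshold = 1.01))
})

test_that("register shift scan: native register, planted slip, rigidity", {
  g <- generate_barrel_trajectory(barrel_fixture_spec(seed = 9),
                                  n_frames = 2, thermal_noise = 0.1)
  off <- register_shift_scan(g$trajectory, g$topology)
  expect_true(all(off == 0))
  # translate the dissociating strand one rung along the strand axis
  slip <- g$trajectory
  s10 <- which(slip$atoms$resno %in%
                 strandgate:::strand_residues(g$topology, "10"))
  slip$coords[s10, 1, 2] <- slip$coords[s10, 1, 2] + 3.4
  off2 <- register_shift_scan(slip, g$topology)
  expect_true(all(abs(off2[2, ]) == 1))
  # global rigid motion leaves offsets unchanged
  R <- random_rotation(12)
  rot <- g$trajectory
  for (f in 1:2)
    rot$coords[, , f] <- sweep(rot$coords[, , f] %*% R, 2, c(5, -3, 8), "+")
  expect_identical(register_shift_scan(rot, g$topology), off)
})
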