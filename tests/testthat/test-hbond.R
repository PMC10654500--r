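simple_pair_frame <- function(d, angle_deg = 170) {
  # donor backbone N of res 1 (strand 10) and acceptor O of res 2 (strand 7),
  # with the acceptor antecedent C placed to give the requested proxy angle
  at <- data.frame(serial = 1:4,
                   atom_name = c("N", "CA", "O", "C"),
                   element = c("N", "C", "O", "C"),
                   resno = c(201L, 201L, 150L, 150L),
                   resid = "ALA", chain = "A")
  cpos <- c(d - 1.2 * cos(angle_deg * pi / 180),
            1.2 * sin(angle_deg * pi / 180), 0)
  make_frame(at, rbind(c(0, 0, 0), c(-1.4, 0, 0), c(d, 0, 0), cpos))
}

pair_topo <- strand_topology(
  strand = c("201" = "10", "150" = "7", "66" = "loop"),
  dissociating_strand = "10", cleavage_site = c(209, 214),
  dihedral_specs = list(phi_I = paste0("A:201:", c("N", "CA", "O", "C")),
                        phi_P = paste0("A:201:", c("N", "CA", "O", "C"))))

test_that("hydrogen-bond criteria gate on distance and angle", {
  crit <- interaction_criteria()
  expect_equal(detect_interactions(simple_pair_frame(2.9), pair_topo,
                                   crit)$kind, "hbond")
  expect_equal(nrow(detect_interactions(simple_pair_frame(6.0), pair_topo,
                                        crit)), 0)
  expect_equal(nrow(detect_interactions(simple_pair_frame(2.9, 60),
                                        pair_topo, crit)), 0)
  tight <- interaction_criteria(hbond_da_max = 2.5)
  expect_equal(nrow(detect_interactions(simple_pair_frame(2.9), pair_topo,
                                        tight)), 0)
})

test_that("detection equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    spec <- random_fixture(seed)
    g <- generate_barrel_trajectory(spec, n_frames = 1,
                                    thermal_noise = runif(1, 0, 0.5))
    f <- get_frame(g$trajectory, 1)
    expect_identical(detect_interactions(f, g$topology)$key,
                     oracle_detect(f, g$topology))
  }
})

test_that("canonical identity is stable under atom-order permutation", {
  g <- generate_barrel_trajectory(split_gfp_fixture("cis")$spec,
                                  n_frames = 1, thermal_noise = 0.2)
  f <- get_frame(g$trajectory, 1)
  set.seed(9)
  perm <- sample(nrow(f$atoms))
  f2 <- make_frame(f$atoms[perm, ], f$xyz[perm, ])
  expect_identical(detect_interactions(f, g$topology)$key,
                   detect_interactions(f2, g$topology)$key)
})

test_that("occupancy counts presence fractions over the stated range", {
  fx <- split_gfp_fixture("cis", seed = 2)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 8)
  tab <- occupancy(g$trajectory, g$topology)
  # persistent planted contacts at 1.0
  full <- tab[grepl("salt_bridge|stacking", tab$kind), ]
  expect_true(all(full$occupancy == 1))
  # the alternating serine partners at exactly one half
  alt <- tab[tab$side_a == "sc" & tab$side_b == "sc" & tab$kind == "hbond" &
               (tab$res_a %in% c(149, 202) & tab$res_b %in% c(202, 225)), ]
  expect_true(all(alt$occupancy == 0.5))
  expect_error(occupancy(g$trajectory, g$topology,
                         frame_range = integer(0)), "empty")
})

test_that("occupancy matches a per-frame brute-force recount", {
  spec <- random_fixture(31)
  g <- generate_barrel_trajectory(spec, n_frames = 6, thermal_noise = 0.3)
  tab <- occupancy(g$trajectory, g$topology)
  counts <- integer(0)
  for (f in 1:6) {
    keys <- oracle_detect(get_frame(g$trajectory, f), g$topology)
    counts <- c(counts, keys)
  }
  recount <- table(counts) / 6
  expect_setequal(tab$key, names(recount))
  expect_equal(tab$occupancy[match(names(recount), tab$key)],
               as.numeric(recount), ignore_attr = TRUE)
})

test_that("occupancy never rises when distance criteria tighten", {
  g <- generate_barrel_trajectory(split_gfp_fixture("cis", seed = 8)$spec,
                                  n_frames = 6, thermal_noise = 0.3)
  loose <- occupancy(g$trajectory, g$topology, interaction_criteria())
  tight <- occupancy(g$trajectory, g$topology,
                     interaction_criteria(hbond_da_max = 3.0,
                                          salt_bridge_max = 3.5,
                                          stacking_centroid_max = 4.5))
  for (k in tight$key) {
    l <- loose$occupancy[match(k, loose$key)]
    if (!is.na(l))
      expect_lte(tight$occupancy[match(k, tight$key)], l)
  }
})

test_that("alternating partners are reported, co-present pairs are not", {
  fx <- split_gfp_fixture("cis", seed = 2)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 10)
  tab <- occupancy(g$trajectory, g$topology)
  alt <- find_alternating(tab)
  hit <- alt[alt$residue == 202, ]
  expect_true(nrow(hit) >= 1)
  expect_setequal(unique(c(hit$partner_1, hit$partner_2)), c(149, 225))
  # always co-present pairs (e.g. the two Lys209 anchors) are not reported
  expect_false(209 %in% alt$residue)
  # brute force over interaction pairs sharing a sidechain residue
  mask <- attr(tab, "mask")
  ok <- tab$occupancy >= 0.2
  brute <- 0
  for (i in which(ok)) for (j in which(ok)) {
    if (j <= i) next
    sc_i <- c(tab$res_a[i][tab$side_a[i] == "sc"],
              tab$res_b[i][tab$side_b[i] == "sc"])
    sc_j <- c(tab$res_a[j][tab$side_a[j] == "sc"],
              tab$res_b[j][tab$side_b[j] == "sc"])
    if (!length(intersect(sc_i, sc_j))) next
    jac <- sum(mask[i, ] & mask[j, ]) / max(1, sum(mask[i, ] | mask[j, ]))
    if (jac <= 0.2) brute <- brute + 1
  }
  expect_equal(nrow(alt), brute)
})

test_that("network diff separates broken, formed and persistent", {
  fx <- split_gfp_fixture("cis", seed = 3)
  g <- generate_barrel_trajectory(fx$spec, n_frames = 6)
  tab <- occupancy(g$trajectory, g$topology)
  same <- diff_networks(tab, tab, threshold = 0.5)
  expect_equal(nrow(same$broken), 0)
  expect_equal(nrow(same$formed), 0)
  ft <- generate_barrel_trajectory(split_gfp_fixture("trans", seed = 3)$spec,
                                   n_frames = 6)
  tab_t <- occupancy(ft$trajectory, ft$topology)
  d <- diff_networks(tab, tab_t, threshold = 0.4)
  # antisymmetry
  rev <- diff_networks(tab_t, tab, threshold = 0.4)
  expect_setequal(d$broken$key, rev$formed$key)
  expect_setequal(d$formed$key, rev$broken$key)
  # all cis strand-10/7 sidechain contacts are broken...
  is107 <- function(x) (x$strand_a == "10" & x$strand_b == "7") |
    (x$strand_a == "7" & x$strand_b == "10")
  sc107 <- tab$key[is107(tab) & (tab$side_a == "sc" | tab$side_b == "sc") &
                     tab$occupancy >= 0.4]
  expect_true(all(sc107 %in% d$broken$key))
  # ...and no new strand-10/7 hydrogen bond forms in the trans state
  expect_equal(sum(is107(d$formed)), 0)
})

test_that("pathway profile localizes contact windows along phi_I", {
  spec <- split_gfp_fixture("cis", seed = 5)$spec
  wins <- generate_pathway_windows(spec, centers = seq(0, 180, 20),
                                   n_frames = 4)
  pw <- pathway_profile(wins)
  cro <- function(res, atom) {
    i <- which((pw$info$res_a == res & pw$info$strand_b == "chromophore" &
                  pw$info$atom_b == atom) |
                 (pw$info$res_b == res & pw$info$strand_a == "chromophore" &
                    pw$info$atom_a == atom))
    pw$profile[i, , drop = FALSE]
  }
  # early contacts break by the 40-degree window
  expect_equal(unname(pw$break_point[rownames(cro(205, "O2"))]), 40)
  expect_equal(unname(pw$break_point[rownames(cro(148, "N2"))]), 40)
  # the far-side loop contact exists only in interior windows
  p121 <- colSums(cro(121, "O2"))
  expect_equal(p121[c("0", "180")], c("0" = 0, "180" = 0))
  expect_gt(sum(p121[c("60", "80", "100", "120")]), 0)
  # persistent planted interactions are flat across windows
  key209 <- pw$info$key[pw$info$res_a == 209 | pw$info$res_b == 209]
  expect_true(all(pw$profile[key209[1], ] == 1))
  expect_error(pathway_profile(wins[1]), "at least 2")
})
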