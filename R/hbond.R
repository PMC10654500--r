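#' Geometric criteria for noncovalent interaction detection
#'
#' Literature-standard cutoffs for hydrogen bonds, salt bridges and
#' aromatic stacking on hydrogen-free (heavy-atom) structures. Hydrogen
#' bonds use the donor-acceptor distance plus a heavy-atom angle proxy
#' (donor / acceptor / acceptor-antecedent angle) since crystal-derived and
#' reduced-representation frames carry no hydrogens.
#'
#' @param hbond_da_max donor-acceptor distance cutoff (angstrom).
#' @param hbond_angle_min donor-H-acceptor cutoff (degrees) when hydrogens
#'   are present (unused for heavy-atom-only frames).
#' @param proxy_angle_min donor-acceptor-antecedent cutoff (degrees) for the
#'   hydrogen-free proxy.
#' @param salt_bridge_max charged-group distance cutoff (angstrom).
#' @param stacking_centroid_max ring-centroid distance cutoff (angstrom).
#' @param stacking_plane_angle_max inter-ring axis angle cutoff (degrees).
#' @param persistent_min_occupancy occupancy above which an interaction
#'   counts as persistent in a state.
#' @param alternating_min_occupancy minimum occupancy of each partner of an
#'   alternating pair.
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_da_max = 3.5, hbond_angle_min = 120,
                                 proxy_angle_min = 90, salt_bridge_max = 4.0,
                                 stacking_centroid_max = 5.5,
                                 stacking_plane_angle_max = 30,
                                 persistent_min_occupancy = 0.5,
                                 alternating_min_occupancy = 0.2) {
  stopifnot(hbond_da_max > 0, salt_bridge_max > 0, stacking_centroid_max > 0,
            persistent_min_occupancy >= 0, persistent_min_occupancy <= 1,
            alternating_min_occupancy >= 0, alternating_min_occupancy <= 1)
  structure(as.list(environment()), class = "interaction_criteria")
}

# canonical identity of an interaction: kind plus the two partner
# descriptors "resno|side|atom" in lexical order, so the same contact hashes
# identically whatever the atom order of the frame
interaction_key <- function(kind, res_a, side_a, atom_a,
                            res_b, side_b, atom_b) {
  da <- sprintf("%05d|%s|%s", res_a, side_a, atom_a)
  db <- sprintf("%05d|%s|%s", res_b, side_b, atom_b)
  swap <- db < da
  k1 <- ifelse(swap, db, da)
  k2 <- ifelse(swap, da, db)
  paste(kind, k1, k2, sep = "~")
}

interaction_label <- function(name_a, res_a, side_a, name_b, res_b, side_b,
                              kind) {
  sprintf("%s%d(%s)-%s%d(%s):%s", aa_one(name_a), res_a, side_a,
          aa_one(name_b), res_b, side_b, kind)
}

# per-atom interaction roles for a frame given its topology
atom_roles <- function(atoms, topo) {
  n <- nrow(atoms)
  resno <- atoms$resno
  lab <- unname(topo$strand[as.character(resno)])
  lab[is.na(lab)] <- "loop"
  lab[resno %in% topo$chromophore_residues] <- "chromophore"
  mc <- atoms$atom_name %in% c("N", "CA", "C", "O")
  cro <- lab == "chromophore"
  side <- ifelse(mc & !cro, "mc", "sc")
  donor <- (atoms$atom_name == "N" & !cro) |
    (atoms$atom_name == "SC" & atoms$resid %in% .sc_donor) |
    (cro & atoms$atom_name %in% c("OH", "N2"))
  acceptor <- (atoms$atom_name == "O" & !cro) |
    (atoms$atom_name == "SC" & atoms$resid %in% .sc_acceptor) |
    (cro & atoms$atom_name %in% c("OH", "O2", "N2"))
  positive <- atoms$atom_name == "SC" & atoms$resid %in% .sc_positive
  negative <- atoms$atom_name == "SC" & atoms$resid %in% .sc_negative
  aromatic <- atoms$atom_name == "SC" & atoms$resid %in% .sc_aromatic
  # antecedent atom (for the hydrogen-free angle proxy and ring axes)
  ante <- rep(NA_integer_, n)
  key <- paste(resno, atoms$atom_name)
  idx <- function(rn, at) match(paste(rn, at), key)
  ante[atoms$atom_name == "N"] <- idx(resno[atoms$atom_name == "N"], "CA")
  ante[atoms$atom_name == "O"] <- idx(resno[atoms$atom_name == "O"], "C")
  ante[atoms$atom_name == "SC"] <- idx(resno[atoms$atom_name == "SC"], "CB")
  ante[cro & atoms$atom_name == "OH"] <-
    idx(resno[cro & atoms$atom_name == "OH"], "C5")
  ante[cro & atoms$atom_name == "O2"] <-
    idx(resno[cro & atoms$atom_name == "O2"], "C4")
  ante[cro & atoms$atom_name == "N2"] <-
    idx(resno[cro & atoms$atom_name == "N2"], "C3")
  list(label = lab, side = side, donor = donor, acceptor = acceptor,
       positive = positive, negative = negative, aromatic = aromatic,
       antecedent = ante)
}

# TRUE for pairs eligible for reporting: distinct barrel strands, or
# anything vs the chromophore group
pair_eligible <- function(lab_a, lab_b) {
  barrel <- c("7", "10", "11")
  (lab_a %in% barrel & lab_b %in% barrel & lab_a != lab_b) |
    xor(lab_a == "chromophore", lab_b == "chromophore")
}

#' Detect noncovalent inter-strand interactions in one frame
#'
#' Reports hydrogen bonds (donor-acceptor distance and angle proxy), salt
#' bridges (oppositely charged sidechain sites) and aromatic stacking
#' (sidechain-site distance and axis alignment) between atoms on distinct
#' barrel strands, or between any residue and the chromophore group. A
#' sidechain pair that qualifies as a salt bridge or stacking contact is
#' reported with that kind only (precedence salt_bridge > stacking > hbond).
#'
#' @param frame a `strand_frame`.
#' @param topo a `strand_topology`.
#' @param criteria an [interaction_criteria()].
#' @return data.frame with one row per interaction: `kind`, partner columns
#'   (`res_a`, `name_a`, `side_a`, `atom_a`, `strand_a`, and `_b`
#'   equivalents), `distance`, `key`, `label`, in canonical partner order.
#' @export
detect_interactions <- function(frame, topo,
                                criteria = interaction_criteria()) {
  atoms <- frame$atoms
  xyz <- frame$xyz
  roles <- atom_roles(atoms, topo)

  pair_dist <- function(i, j)
    sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  pair_angle <- function(v1, v2) {
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  }

  ii <- integer(0); jj <- integer(0); kind <- character(0)
  dd <- numeric(0)

  # charged and aromatic sidechain pairs claim their atoms first
  sc_idx <- which(atoms$atom_name == "SC")
  claimed <- character(0)
  if (length(sc_idx) > 1) {
    cmb <- utils::combn(sc_idx, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    elig <- pair_eligible(roles$label[i], roles$label[j])
    salt <- (roles$positive[i] & roles$negative[j]) |
      (roles$negative[i] & roles$positive[j])
    arom <- roles$aromatic[i] & roles$aromatic[j]
    claimed <- paste(i[elig & (salt | arom)], j[elig & (salt | arom)])
    sel <- which(elig & salt)
    if (length(sel)) {
      d <- pair_dist(i[sel], j[sel])
      hit <- d <= criteria$salt_bridge_max
      ii <- c(ii, i[sel][hit]); jj <- c(jj, j[sel][hit])
      kind <- c(kind, rep("salt_bridge", sum(hit))); dd <- c(dd, d[hit])
    }
    sel <- which(elig & arom & !salt)
    if (length(sel)) {
      d <- pair_dist(i[sel], j[sel])
      ai <- roles$antecedent[i[sel]]; aj <- roles$antecedent[j[sel]]
      ang <- pair_angle(xyz[i[sel], , drop = FALSE] -
                          xyz[ai, , drop = FALSE],
                        xyz[j[sel], , drop = FALSE] -
                          xyz[aj, , drop = FALSE])
      hit <- d <= criteria$stacking_centroid_max &
        pmin(ang, 180 - ang) <= criteria$stacking_plane_angle_max
      ii <- c(ii, i[sel][hit]); jj <- c(jj, j[sel][hit])
      kind <- c(kind, rep("stacking", sum(hit))); dd <- c(dd, d[hit])
    }
  }

  # hydrogen bonds over all remaining donor/acceptor pairs
  don <- which(roles$donor)
  acc <- which(roles$acceptor)
  if (length(don) && length(acc)) {
    i <- rep(don, each = length(acc))
    j <- rep(acc, times = length(don))
    ok <- i != j & atoms$resno[i] != atoms$resno[j] &
      pair_eligible(roles$label[i], roles$label[j]) &
      !paste(pmin(i, j), pmax(i, j)) %in% claimed
    i <- i[ok]; j <- j[ok]
    d <- pair_dist(i, j)
    near <- d <= criteria$hbond_da_max
    i <- i[near]; j <- j[near]; d <- d[near]
    if (length(i)) {
      a <- roles$antecedent[j]
      angle_ok <- rep(TRUE, length(i))
      has_a <- !is.na(a)
      if (any(has_a))
        angle_ok[has_a] <- pair_angle(
          xyz[i[has_a], , drop = FALSE] - xyz[j[has_a], , drop = FALSE],
          xyz[a[has_a], , drop = FALSE] - xyz[j[has_a], , drop = FALSE]) >=
          criteria$proxy_angle_min
      i <- i[angle_ok]; j <- j[angle_ok]; d <- d[angle_ok]
      # one row per unordered atom pair (a pair may satisfy both directions)
      dedup <- !duplicated(paste(pmin(i, j), pmax(i, j)))
      ii <- c(ii, i[dedup]); jj <- c(jj, j[dedup])
      kind <- c(kind, rep("hbond", sum(dedup))); dd <- c(dd, d[dedup])
    }
  }

  # canonical partner order by (resno, side, atom)
  ka <- sprintf("%05d|%s|%s", atoms$resno[ii], roles$side[ii],
                atoms$atom_name[ii])
  kb <- sprintf("%05d|%s|%s", atoms$resno[jj], roles$side[jj],
                atoms$atom_name[jj])
  swap <- kb < ka
  a_idx <- ifelse(swap, jj, ii)
  b_idx <- ifelse(swap, ii, jj)
  out <- data.frame(
    kind = kind,
    res_a = atoms$resno[a_idx], name_a = atoms$resid[a_idx],
    side_a = roles$side[a_idx], atom_a = atoms$atom_name[a_idx],
    strand_a = roles$label[a_idx],
    res_b = atoms$resno[b_idx], name_b = atoms$resid[b_idx],
    side_b = roles$side[b_idx], atom_b = atoms$atom_name[b_idx],
    strand_b = roles$label[b_idx],
    distance = dd, stringsAsFactors = FALSE)
  out$key <- interaction_key(out$kind, out$res_a, out$side_a, out$atom_a,
                             out$res_b, out$side_b, out$atom_b)
  out$label <- interaction_label(out$name_a, out$res_a, out$side_a,
                                 out$name_b, out$res_b, out$side_b, out$kind)
  out <- out[!duplicated(out$key), , drop = FALSE]
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction occupancy over a frame range
#'
#' Fraction of frames in which each canonical interaction is present.
#'
#' @param traj a `strand_trajectory`.
#' @param topo a `strand_topology`.
#' @param criteria an [interaction_criteria()].
#' @param frame_range integer vector of frame indices (default all frames).
#' @return an `occupancy_table`: data.frame of interactions with their
#'   `occupancy`; the per-frame presence mask matrix is in attribute
#'   `"mask"` (interactions x frames), the frame range in `"frames"`.
#' @export
occupancy <- function(traj, topo, criteria = interaction_criteria(),
                      frame_range = NULL) {
  if (is.null(frame_range)) frame_range <- seq_len(n_frames(traj))
  if (length(frame_range) == 0) stop("empty frame range")
  stopifnot(all(frame_range >= 1), all(frame_range <= n_frames(traj)))
  info <- NULL
  masks <- list()
  for (f in frame_range) {
    det <- detect_interactions(get_frame(traj, f), topo, criteria)
    masks[[as.character(f)]] <- det$key
    if (nrow(det)) {
      det$distance <- NULL
      info <- if (is.null(info)) det else
        rbind(info, det[!det$key %in% info$key, ])
    }
  }
  if (is.null(info)) {
    info <- detect_interactions(get_frame(traj, frame_range[1]), topo,
                                criteria)[0, ]
    info$distance <- NULL
  }
  info <- info[order(info$key), , drop = FALSE]
  mask <- matrix(FALSE, nrow(info), length(frame_range),
                 dimnames = list(info$key, as.character(frame_range)))
  for (f in names(masks)) mask[masks[[f]][masks[[f]] %in% info$key], f] <- TRUE
  info$occupancy <- rowMeans(mask)
  rownames(info) <- NULL
  structure(info, mask = mask, frames = frame_range,
            class = c("occupancy_table", "data.frame"))
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table: %d interactions over %d frames\n",
              nrow(x), length(attr(x, "frames"))))
  df <- data.frame(interaction = x$label, occupancy = round(x$occupancy, 3))
  print(df[order(-df$occupancy), ], row.names = FALSE)
  invisible(x)
}

#' Find alternating interaction partners
#'
#' Reports triples (shared residue, partner 1, partner 2) where a residue's
#' sidechain forms two interactions that are both well populated yet almost
#' never co-occur in the same frame (per-frame co-occurrence Jaccard index
#' below `jaccard_max`), the signature of a sidechain alternating between
#' two acceptors on opposite neighbor strands.
#'
#' @param table an [occupancy()] result (with its presence-mask attribute).
#' @param criteria an [interaction_criteria()]; uses
#'   `alternating_min_occupancy`.
#' @param jaccard_max maximum co-occurrence Jaccard index.
#' @return data.frame with columns `residue`, `partner_1`, `partner_2`,
#'   `key_1`, `key_2`, `jaccard`.
#' @export
find_alternating <- function(table, criteria = interaction_criteria(),
                             jaccard_max = 0.2) {
  mask <- attr(table, "mask")
  out <- list()
  ok <- table$occupancy >= criteria$alternating_min_occupancy
  for (i in which(ok)) {
    for (j in which(ok)) {
      if (j <= i) next
      # shared residue participating through its sidechain in both
      sc_i <- c(if (table$side_a[i] == "sc") table$res_a[i],
                if (table$side_b[i] == "sc") table$res_b[i])
      sc_j <- c(if (table$side_a[j] == "sc") table$res_a[j],
                if (table$side_b[j] == "sc") table$res_b[j])
      shared <- intersect(sc_i, sc_j)
      if (!length(shared)) next
      r <- shared[1]
      mi <- mask[i, ]; mj <- mask[j, ]
      jac <- sum(mi & mj) / max(1, sum(mi | mj))
      if (jac <= jaccard_max) {
        p1 <- if (table$res_a[i] == r) table$res_b[i] else table$res_a[i]
        p2 <- if (table$res_a[j] == r) table$res_b[j] else table$res_a[j]
        out[[length(out) + 1]] <- data.frame(
          residue = r, partner_1 = p1, partner_2 = p2,
          key_1 = table$key[i], key_2 = table$key[j], jaccard = jac)
      }
    }
  }
  if (!length(out))
    return(data.frame(residue = integer(), partner_1 = integer(),
                      partner_2 = integer(), key_1 = character(),
                      key_2 = character(), jaccard = numeric()))
  do.call(rbind, out)
}

#' Difference between two interaction networks
#'
#' @param table_a,table_b [occupancy()] results for the two states.
#' @param threshold occupancy threshold defining presence in a state.
#' @return a `network_diff`: list of data.frames `broken` (present in A,
#'   absent in B), `formed` (the converse) and `persistent` (present in
#'   both), pairwise disjoint.
#' @export
diff_networks <- function(table_a, table_b, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  a_on <- table_a$key[table_a$occupancy >= threshold]
  b_on <- table_b$key[table_b$occupancy >= threshold]
  pick <- function(tab, keys) {
    out <- tab[tab$key %in% keys, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "mask") <- NULL
    class(out) <- "data.frame"
    out
  }
  structure(list(
    broken = pick(table_a, setdiff(a_on, b_on)),
    formed = pick(table_b, setdiff(b_on, a_on)),
    persistent = pick(table_a, intersect(a_on, b_on)),
    threshold = threshold), class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf("network_diff (threshold %.2f): %d broken, %d formed, %d persistent\n",
              x$threshold, nrow(x$broken), nrow(x$formed),
              nrow(x$persistent)))
  if (nrow(x$broken)) cat("  broken:", paste(x$broken$label, collapse = ", "),
                          "\n")
  if (nrow(x$formed)) cat("  formed:", paste(x$formed$label, collapse = ", "),
                          "\n")
  invisible(x)
}

#' Interaction occupancy along the isomerization coordinate
#'
#' Occupancy of every interaction in each umbrella window, plus the last
#' window center at which each interaction is still populated (its break
#' point along phi_I).
#'
#' @param windows list as returned by [generate_pathway_windows()]: elements
#'   with `center`, `trajectory`, `topology`.
#' @param criteria an [interaction_criteria()].
#' @param threshold occupancy defining "still present" for the break point.
#' @return a `pathway_profile`: list with `centers`, `profile` (interaction
#'   x window occupancy matrix), `info` (interaction descriptors) and
#'   `break_point` (named numeric: last populated center per interaction).
#' @export
pathway_profile <- function(windows, criteria = interaction_criteria(),
                            threshold = 0.2) {
  if (length(windows) < 2) stop("need at least 2 windows")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (is.unsorted(centers)) stop("window centers must be sorted")
  topo0 <- windows[[1]]$topology
  for (w in windows)
    if (!identical(w$topology$strand, topo0$strand))
      stop("inconsistent topologies across windows")
  tabs <- lapply(windows, function(w)
    occupancy(w$trajectory, w$topology, criteria))
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  prof <- matrix(0, length(keys), length(centers),
                 dimnames = list(keys, as.character(centers)))
  info <- NULL
  for (k in seq_along(tabs)) {
    t <- tabs[[k]]
    prof[t$key, k] <- t$occupancy
    info <- if (is.null(info)) t else rbind(info, t[!t$key %in% info$key, ])
  }
  info <- as.data.frame(info[match(keys, info$key), , drop = FALSE])
  info$occupancy <- NULL
  rownames(info) <- NULL
  bp <- apply(prof, 1, function(p) {
    on <- which(p >= threshold)
    if (length(on)) centers[max(on)] else NA_real_
  })
  structure(list(centers = centers, profile = prof, info = info,
                 break_point = bp, threshold = threshold),
            class = "pathway_profile")
}
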