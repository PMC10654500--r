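# heavy-atom row indices per residue, for contact computations
residue_atom_index <- function(atoms, residues) {
  lapply(residues, function(r)
    which(atoms$resno == r & atoms$element != "H"))
}

min_dist <- function(xyz, ia, ib) {
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  sqrt(max(0, min(d2)))
}

#' Fraction of native inter-strand contacts per frame
#'
#' Native contacts are inter-strand residue pairs whose minimum heavy-atom
#' distance in the reference frame is at most `cutoff`; a contact counts as
#' retained in a frame while that distance stays within `tol * cutoff`.
#'
#' @param traj a `strand_trajectory`.
#' @param reference a `strand_frame` (same atom table).
#' @param topo a `strand_topology`.
#' @param cutoff native-contact distance cutoff (angstrom).
#' @param tol retention tolerance factor.
#' @return numeric vector Q per frame, with the native pair list in
#'   attribute `"contacts"`.
#' @export
native_contact_fraction <- function(traj, reference, topo, cutoff = 5.5,
                                    tol = 1.2) {
  atoms <- reference$atoms
  barrel <- c("7", "10", "11")
  res <- strand_residues(topo, barrel)
  lab <- topo$strand[as.character(res)]
  idx <- residue_atom_index(atoms, res)
  pairs <- list()
  for (i in seq_along(res)) {
    for (j in seq_along(res)) {
      if (j <= i || lab[i] == lab[j]) next
      if (min_dist(reference$xyz, idx[[i]], idx[[j]]) <= cutoff)
        pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (!length(pairs)) stop("no native inter-strand contacts in reference")
  involves_d <- vapply(pairs, function(p)
    any(lab[p] == topo$dissociating_strand), logical(1))
  if (!any(involves_d))
    stop("no native contacts involve the dissociating strand")
  q <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[, , f]
    kept <- vapply(pairs, function(p)
      min_dist(xyz, idx[[p[1]]], idx[[p[2]]]) <= tol * cutoff, logical(1))
    mean(kept)
  }, numeric(1))
  attr(q, "contacts") <- data.frame(
    res_a = res[vapply(pairs, `[`, integer(1), 1)],
    res_b = res[vapply(pairs, `[`, integer(1), 2)])
  q
}

#' Detect a strand-dissociation event
#'
#' Dissociation onset is the first frame at which the native-contact
#' fraction Q drops below `q_threshold` and stays below it for at least
#' `persistence` consecutive frames. Absence of such a frame is a valid
#' result (`NULL`), as for the cis complex, whose barrel stays intact even
#' at high temperature.
#'
#' @inheritParams native_contact_fraction
#' @param q_threshold Q threshold defining loss of the native arrangement.
#' @param persistence required consecutive frames below threshold.
#' @param reference reference frame for native contacts (default frame 1).
#' @param anchors also compute the anchor-loss ordering
#'   ([anchor_loss_order()]) and attach it.
#' @param criteria interaction criteria for anchor analysis.
#' @return a `dissociation_event` (fields `onset_frame`,
#'   `onset_temperature`, `q`, optionally `anchor_losses`) or `NULL`.
#' @export
detect_dissociation <- function(traj, topo, q_threshold = 0.2,
                                persistence = 10, reference = NULL,
                                anchors = FALSE,
                                criteria = interaction_criteria()) {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  q <- native_contact_fraction(traj, reference, topo)
  below <- q < q_threshold
  onset <- NA_integer_
  run <- 0
  for (f in seq_along(below)) {
    run <- if (below[f]) run + 1 else 0
    if (run >= persistence) { onset <- f - persistence + 1; break }
  }
  if (is.na(onset)) return(NULL)
  ev <- list(onset_frame = onset,
             onset_temperature = if (!is.null(traj$temperature))
               traj$temperature[onset] else NA_real_,
             q = q)
  if (anchors)
    ev$anchor_losses <- anchor_loss_order(traj, topo, criteria)
  structure(ev, class = "dissociation_event")
}

#' @export
print.dissociation_event <- function(x, ...) {
  cat(sprintf("dissociation event: onset frame %d (T = %s K)\n",
              x$onset_frame,
              ifelse(is.na(x$onset_temperature), "?",
                     format(x$onset_temperature))))
  if (!is.null(x$anchor_losses)) {
    cat("anchor losses (last present frame):\n")
    print(x$anchor_losses[, c("label", "last_present_frame")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Order of anchor-interaction losses
#'
#' For every inter-strand sidechain interaction involving the dissociating
#' strand that is present at the start of the trajectory, reports the last
#' frame of its final presence run of at least `smoothing` consecutive
#' frames (so a thermal flicker does not count as a re-formation), sorted
#' ascending; ties break by residue number, then interaction kind.
#'
#' @param traj a `strand_trajectory`.
#' @param topo a `strand_topology`.
#' @param criteria an [interaction_criteria()].
#' @param smoothing minimum presence-run length (frames).
#' @param flicker_gap absence gaps up to this many frames flanked by
#'   presence are treated as thermal flickers and bridged; a genuinely
#'   broken anchor stays absent and is never bridged.
#' @return data.frame of interactions with `last_present_frame`, ordered by
#'   loss time.
#' @export
anchor_loss_order <- function(traj, topo, criteria = interaction_criteria(),
                              smoothing = 5, flicker_gap = 2) {
  tab <- occupancy(traj, topo, criteria)
  mask <- attr(tab, "mask")
  d <- topo$dissociating_strand
  sel <- (tab$side_a == "sc" | tab$side_b == "sc") &
    (tab$strand_a == d | tab$strand_b == d) &
    tab$strand_a != "chromophore" & tab$strand_b != "chromophore"
  # present at the start (any presence within the first smoothing window)
  # and sustained somewhere for at least `smoothing` consecutive frames
  keep <- integer(0)
  last <- numeric(0)
  for (i in which(sel)) {
    m <- as.vector(mask[i, ])
    if (!any(m[seq_len(min(smoothing, length(m)))])) next
    # bridge short absence gaps (thermal flickers) inside presence runs
    if (flicker_gap > 0) {
      r0 <- rle(m)
      ends0 <- cumsum(r0$lengths)
      for (j in seq_along(r0$values)) {
        if (!r0$values[j] && r0$lengths[j] <= flicker_gap &&
            j > 1 && j < length(r0$values))
          m[(ends0[j] - r0$lengths[j] + 1):ends0[j]] <- TRUE
      }
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= smoothing)
    if (!length(runs)) next
    keep <- c(keep, i)
    last <- c(last, ends[runs[length(runs)]])
  }
  res_min <- pmin(tab$res_a[keep], tab$res_b[keep])
  ord <- order(last, res_min, tab$kind[keep])
  out <- tab[keep[ord], , drop = FALSE]
  out$last_present_frame <- last[ord]
  attr(out, "mask") <- NULL
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' First frame of terminal solvation
#'
#' Mean relative solvent accessibility of the terminal residues of the
#' dissociating strand (the cleaved end), per frame; returns the first
#' frame at which it exceeds `sasa_threshold` and stays above for
#' `persistence` frames, or `NULL`.
#'
#' @param traj a `strand_trajectory`.
#' @param topo a `strand_topology`.
#' @param terminal_residues number of terminal residues.
#' @param sasa_threshold relative-SASA threshold.
#' @param persistence consecutive frames required above threshold.
#' @return integer frame (with the per-frame series in attribute
#'   `"series"`) or `NULL`.
#' @export
terminal_solvation <- function(traj, topo, terminal_residues = 3,
                               sasa_threshold = 0.5, persistence = 5) {
  res <- topo$cleavage_site[1] - seq_len(terminal_residues) + 1
  series <- vapply(seq_len(n_frames(traj)), function(f)
    mean(relative_sasa(get_frame(traj, f), residues = res)),
    numeric(1))
  above <- series > sasa_threshold
  run <- 0
  crossing <- NULL
  for (f in seq_along(above)) {
    run <- if (above[f]) run + 1 else 0
    if (run >= persistence) { crossing <- f - persistence + 1; break }
  }
  if (is.null(crossing)) return(NULL)
  structure(as.integer(crossing), series = series)
}

#' Register shift of the dissociating strand against its neighbors
#'
#' For each frame and each neighbor strand, the integer residue shift
#' maximizing the number of cross-strand CA pairs within `cutoff` of the
#' reference pairing, reporting stepwise register slips of the strand.
#'
#' @param traj a `strand_trajectory`.
#' @param topo a `strand_topology`.
#' @param cutoff CA-CA pairing distance (angstrom).
#' @param max_shift largest shift magnitude scanned.
#' @return matrix frames x neighbors of integer offsets (0 = native
#'   register).
#' @export
register_shift_scan <- function(traj, topo, cutoff = 6.0, max_shift = 3) {
  atoms <- traj$atoms
  d <- topo$dissociating_strand
  neighbors <- setdiff(unique(topo$strand[topo$strand %in%
                                            c("7", "10", "11")]), d)
  res_d <- sort(strand_residues(topo, d))
  ca_row <- function(rn) which(atoms$resno == rn & atoms$atom_name == "CA")
  ca_d <- vapply(res_d, ca_row, integer(1))
  if (length(ca_d) < 4) stop("dissociating strand has fewer than 4 CA")
  ref <- traj$coords[, , 1]
  out <- matrix(NA_integer_, n_frames(traj), length(neighbors),
                dimnames = list(NULL, neighbors))
  for (nb in neighbors) {
    res_n <- sort(strand_residues(topo, nb))
    ca_n <- vapply(res_n, ca_row, integer(1))
    if (length(ca_n) < 4) stop("strand ", nb, " has fewer than 4 CA")
    # native pairing from the reference frame: nearest neighbor-strand CA
    pair <- vapply(ca_d, function(i) {
      dists <- sqrt(colSums((t(ref[ca_n, , drop = FALSE]) - ref[i, ])^2))
      which.min(dists)
    }, integer(1))
    for (f in seq_len(n_frames(traj))) {
      xyz <- traj$coords[, , f]
      score <- vapply(-max_shift:max_shift, function(s) {
        j <- pair + s
        ok <- j >= 1 & j <= length(ca_n)
        if (!any(ok)) return(0L)
        sum(sqrt(rowSums((xyz[ca_d[ok], , drop = FALSE] -
                            xyz[ca_n[j[ok]], , drop = FALSE])^2)) <= cutoff)
      }, integer(1))
      shifts <- (-max_shift:max_shift)
      best <- which(score == max(score))
      # prefer the smallest |shift| on ties (native register wins)
      out[f, nb] <- shifts[best[which.min(abs(shifts[best]))]]
    }
  }
  out
}
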