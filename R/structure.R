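#' Construct a trajectory object
#'
#' A `strand_trajectory` holds an atom table (constant topology) plus an
#' `n_atoms x 3 x n_frames` coordinate array, with optional per-frame
#' temperatures from an annealing schedule.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `resno`, `resid`, `chain`.
#' @param coords numeric array of dimension `c(nrow(atoms), 3, n_frames)`.
#' @param temperature optional numeric vector, one temperature (K) per frame.
#' @param schedule optional data.frame with columns `from`, `to`, `temp_K`
#'   whose frame ranges partition the trajectory.
#' @return an object of class `strand_trajectory`.
#' @export
strand_trajectory <- function(atoms, coords, temperature = NULL,
                              schedule = NULL) {
  req <- c("serial", "atom_name", "element", "resno", "resid", "chain")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[1] == nrow(atoms),
            dim(coords)[2] == 3, dim(coords)[3] >= 1)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom_name) in atom table")
  if (!is.null(schedule) && is.null(temperature)) {
    temperature <- numeric(dim(coords)[3])
    for (i in seq_len(nrow(schedule)))
      temperature[schedule$from[i]:schedule$to[i]] <- schedule$temp_K[i]
  }
  if (!is.null(temperature))
    stopifnot(length(temperature) == dim(coords)[3], all(temperature > 0))
  structure(list(atoms = atoms, coords = coords, temperature = temperature,
                 schedule = schedule),
            class = "strand_trajectory")
}

#' @export
print.strand_trajectory <- function(x, ...) {
  cat(sprintf("strand_trajectory: %d atoms, %d residues, %d frames\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), n_frames(x)))
  if (!is.null(x$temperature))
    cat(sprintf("  temperature: %.0f-%.0f K\n",
                min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `strand_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#'
#' @param traj a `strand_trajectory`.
#' @param i frame index (1-based).
#' @return a `strand_frame`: the atom table plus an `n_atoms x 3` coordinate
#'   matrix and the frame's temperature, if any.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  structure(list(atoms = traj$atoms,
                 xyz = traj$coords[, , i, drop = TRUE],
                 frame_index = i,
                 temperature = if (!is.null(traj$temperature))
                   traj$temperature[i] else NULL),
            class = "strand_frame")
}

#' Strand topology annotation
#'
#' Maps residues to strand labels, records the dissociating strand, the
#' cleavage site, the chromophore dihedral atom quadruples and the
#' chromophore residue group.
#'
#' @param strand named character vector: names are residue numbers (as
#'   strings), values are labels among `"7"`, `"10"`, `"11"`, `"helix"`,
#'   `"loop"`.
#' @param dissociating_strand one of the strand labels in `strand`.
#' @param cleavage_site integer pair of residue numbers flanking the
#'   proteolytic cut (dissociating-strand side first).
#' @param dihedral_specs named list with elements `phi_I` and `phi_P`, each a
#'   character vector of 4 atom identifiers `"chain:resno:atom"`.
#' @param chromophore_residues integer vector of residue numbers forming the
#'   chromophore group.
#' @return an object of class `strand_topology`.
#' @export
strand_topology <- function(strand, dissociating_strand, cleavage_site,
                            dihedral_specs, chromophore_residues = integer()) {
  stopifnot(is.character(strand), !is.null(names(strand)))
  if (!dissociating_strand %in% strand)
    stop("dissociating_strand label not present in strand map")
  stopifnot(length(cleavage_site) == 2)
  stopifnot(all(c("phi_I", "phi_P") %in% names(dihedral_specs)),
            all(vapply(dihedral_specs, length, 1L) == 4))
  structure(list(strand = strand,
                 dissociating_strand = dissociating_strand,
                 cleavage_site = as.integer(cleavage_site),
                 dihedral_specs = dihedral_specs,
                 chromophore_residues = as.integer(chromophore_residues)),
            class = "strand_topology")
}

#' @export
print.strand_topology <- function(x, ...) {
  tab <- table(x$strand)
  cat("strand_topology:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  dissociating strand: %s; cleavage site: %d|%d\n",
              x$dissociating_strand, x$cleavage_site[1], x$cleavage_site[2]))
  invisible(x)
}

# residues carrying a given strand label
strand_residues <- function(topo, label) {
  as.integer(names(topo$strand)[topo$strand %in% label])
}

atom_id <- function(atoms) paste(atoms$chain, atoms$resno, atoms$atom_name,
                                 sep = ":")

# resolve "chain:resno:atom" identifiers to row indices of the atom table
resolve_atoms <- function(atoms, ids) {
  idx <- match(ids, atom_id(atoms))
  if (anyNA(idx))
    stop("unresolvable atom identifier(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Measure a dihedral angle in a frame
#'
#' @param frame a `strand_frame`.
#' @param spec character vector of 4 atom identifiers `"chain:resno:atom"`,
#'   or one of the named specs in a topology's `dihedral_specs`.
#' @return angle in degrees in `(-180, 180]` (cis = 0, trans = 180).
#' @export
dihedral <- function(frame, spec) {
  idx <- resolve_atoms(frame$atoms, spec)
  torsion_angle(frame$xyz[idx, , drop = FALSE])
}

# ---- superposition ---------------------------------------------------------

resolve_selection <- function(frame, selection) {
  if (is.null(selection)) return(seq_len(nrow(frame$atoms)))
  if (is.function(selection)) {
    keep <- selection(frame$atoms)
    stopifnot(is.logical(keep), length(keep) == nrow(frame$atoms))
    return(which(keep))
  }
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Atom selections
#'
#' Predicates for the common selections: all non-hydrogen atoms
#' (`select_heavy`) and the peptide backbone N, CA, C, O (`select_backbone`).
#'
#' @param atoms an atom table.
#' @return logical vector over atoms.
#' @export
select_heavy <- function(atoms) atoms$element != "H"

#' @rdname select_heavy
#' @export
select_backbone <- function(atoms)
  atoms$atom_name %in% c("N", "CA", "C", "O")

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rigid motion of `mobile` minimizing the RMSD to `reference` over
#' the selected atoms.
#'
#' @param mobile,reference `strand_frame` objects with identical atom tables.
#' @param selection `NULL` (all atoms), a predicate `function(atoms)` returning
#'   a logical vector, a logical vector, or atom row indices.
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (angstrom) over the selection after fitting.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  idx <- resolve_selection(mobile, selection)
  if (length(idx) < 3) stop("need at least 3 atoms to superpose")
  A <- mobile$xyz[idx, , drop = FALSE]
  B <- reference$xyz[idx, , drop = FALSE]
  sv <- svd(stats::cov(A))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate geometry: selected atoms are collinear")
  fit <- kabsch(A, B)
  moved <- sweep(A %*% fit$rotation, 2, fit$translation, "+")
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = sqrt(mean(rowSums((moved - B)^2))))
}

# apply a rigid motion to a frame (used by tests and fixtures)
transform_frame <- function(frame, rotation, translation) {
  frame$xyz <- sweep(frame$xyz %*% rotation, 2, translation, "+")
  frame
}

#' Per-frame RMSD to a reference
#'
#' Superposes each frame onto `reference` over `selection` and reports the
#' fitted RMSD, the series behind statements like "average heavy-atom RMSD"
#' or "backbone RMSD" of an ensemble.
#'
#' @inheritParams superpose
#' @param traj a `strand_trajectory`.
#' @return numeric vector, one RMSD (angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  vapply(seq_len(n_frames(traj)),
         function(i) superpose(get_frame(traj, i), reference, selection)$rmsd,
         numeric(1))
}

# ---- solvent accessible surface area --------------------------------------

# deterministic near-uniform sphere points (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA by rolling a probe sphere over van der Waals surfaces
#' discretized with a deterministic point lattice.
#'
#' @param frame a `strand_frame`.
#' @param probe_radius probe radius in angstrom (water: 1.4).
#' @param n_points sphere test points per atom.
#' @param atom_subset optional atom row indices: areas are computed only for
#'   these atoms (all atoms still occlude).
#' @return numeric vector of per-atom areas (angstrom^2) for the subset, with
#'   the per-residue aggregation in attribute `"residue"` (named by
#'   `"chain:resno"`).
#' @export
sasa <- function(frame, probe_radius = 1.4, n_points = 960,
                 atom_subset = NULL) {
  atoms <- frame$atoms
  xyz <- frame$xyz
  r <- .vdw_radii[atoms$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop(sprintf("unknown element '%s' for atom %s",
                 atoms$element[bad], atom_id(atoms)[bad]))
  }
  r <- unname(r) + probe_radius
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(atoms))
  pts <- sphere_points(n_points)
  area <- numeric(length(atom_subset))
  maxr <- max(r)
  for (k in seq_along(atom_subset)) {
    i <- atom_subset[k]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        acc[acc] <- rowSums(sweep(p[acc, , drop = FALSE], 2,
                                  xyz[j, ])^2) >= r[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    area[k] <- frac * 4 * pi * r[i]^2
  }
  reskey <- paste(atoms$chain[atom_subset], atoms$resno[atom_subset], sep = ":")
  structure(area, residue = tapply(area, reskey, sum),
            names = atom_id(atoms)[atom_subset])
}

#' Relative per-residue solvent accessibility
#'
#' Ratio of a residue's SASA in context to its SASA in a reference state
#' containing only the residue and the backbone of its chain neighbors (the
#' tripeptide, Gly-X-Gly-style reference adapted to reduced residue
#' representations), so covalent-neighbor occlusion does not count against
#' exposure.
#'
#' @inheritParams sasa
#' @param residues residue numbers to evaluate (default: all).
#' @return named numeric vector (names `"chain:resno"`) of fractions in
#'   `[0, 1]` up to discretization error.
#' @export
relative_sasa <- function(frame, residues = NULL, probe_radius = 1.4,
                          n_points = 960) {
  atoms <- frame$atoms
  if (is.null(residues)) residues <- unique(atoms$resno)
  out <- numeric(length(residues))
  names(out) <- paste(atoms$chain[match(residues, atoms$resno)], residues,
                      sep = ":")
  bb <- c("N", "CA", "C", "O", "CB")
  for (k in seq_along(residues)) {
    rn <- residues[k]
    idx <- which(atoms$resno == rn)
    ctx <- sasa(frame, probe_radius, n_points, atom_subset = idx)
    nb <- which(atoms$resno %in% c(rn - 1, rn + 1) &
                  atoms$chain == atoms$chain[idx[1]] &
                  atoms$atom_name %in% bb)
    ref_idx <- c(idx, nb)
    iso_frame <- structure(list(atoms = atoms[ref_idx, , drop = FALSE],
                                xyz = frame$xyz[ref_idx, , drop = FALSE]),
                           class = "strand_frame")
    iso <- sasa(iso_frame, probe_radius, n_points,
                atom_subset = seq_along(idx))
    out[k] <- sum(ctx) / sum(iso)
  }
  out
}

# first principal axis of the barrel-strand CA coordinates, with centroid
barrel_axis <- function(frame, topo) {
  res <- strand_residues(topo, c("7", "10", "11"))
  idx <- which(frame$atoms$resno %in% res & frame$atoms$atom_name == "CA")
  if (length(idx) < 3) stop("barrel axis undefined: fewer than 3 barrel CA")
  x <- frame$xyz[idx, , drop = FALSE]
  ctr <- colMeans(x)
  pc <- stats::prcomp(x, center = TRUE)
  list(center = ctr, axis = pc$rotation[, 1])
}

#' Classify sidechain orientation relative to the barrel
#'
#' Each residue is labelled `"in"` (sidechain pointing toward the barrel
#' axis), `"out"` (away from it), or `"exposed"` when it sits in the
#' cleaved-terminus region and its relative SASA reaches the exposure
#' threshold. The barrel axis is the first principal component of the
#' barrel-strand CA coordinates. Glycine, lacking CB, is labelled from
#' backbone exposure alone (`"exposed"` or `"out"`).
#'
#' @param frame a `strand_frame`.
#' @param topo a `strand_topology`.
#' @param exposure_threshold relative-SASA threshold for `"exposed"`.
#' @param terminus_width residues on each side of the cleavage site eligible
#'   for the `"exposed"` override.
#' @param residues residue numbers to classify (default: all strand-labelled
#'   residues).
#' @return named character vector of labels, names are residue numbers.
#' @export
classify_orientation <- function(frame, topo, exposure_threshold = 0.65,
                                 terminus_width = 2, residues = NULL) {
  ax <- barrel_axis(frame, topo)
  if (is.null(residues))
    residues <- strand_residues(topo, c("7", "10", "11"))
  atoms <- frame$atoms
  terminus <- c(topo$cleavage_site[1] - 0:terminus_width,
                topo$cleavage_site[2] + 0:terminus_width)
  labels <- character(length(residues))
  names(labels) <- residues
  for (k in seq_along(residues)) {
    rn <- residues[k]
    ca <- which(atoms$resno == rn & atoms$atom_name == "CA")
    cb <- which(atoms$resno == rn & atoms$atom_name == "CB")
    if (length(ca) != 1) stop("residue ", rn, " lacks CA")
    exposed <- FALSE
    if (rn %in% terminus || length(cb) != 1)
      exposed <- relative_sasa(frame, residues = rn) >= exposure_threshold
    if (rn %in% terminus && exposed) {
      labels[k] <- "exposed"
    } else if (length(cb) != 1) {
      labels[k] <- if (exposed) "exposed" else "out"
    } else {
      v <- frame$xyz[ca, ] - ax$center
      radial <- v - sum(v * ax$axis) * ax$axis
      side <- frame$xyz[cb, ] - frame$xyz[ca, ]
      labels[k] <- if (sum(side * radial) >= 0) "out" else "in"
    }
  }
  labels
}

# ---- I/O -------------------------------------------------------------------

#' Write a trajectory as a multi-model PDB with a JSON topology sidecar
#'
#' @param traj a `strand_trajectory`.
#' @param topo a `strand_topology` (written to `topology_path`).
#' @param path output PDB file.
#' @param topology_path output JSON file (default: `path` with `.json`).
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, topo, path,
                             topology_path = sub("\\.pdb$", ".json", path)) {
  atoms <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    nm <- ifelse(nchar(atoms$atom_name) < 4,
                 sprintf(" %-3s", atoms$atom_name), atoms$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$serial, nm, atoms$resid, atoms$chain, atoms$resno,
      traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f],
      1.00, 0.00, atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  topo_list <- unclass(topo)
  topo_list$strand <- as.list(topo$strand)
  if (!is.null(traj$schedule)) topo_list$schedule <- traj$schedule
  jsonlite::write_json(topo_list, topology_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-model PDB trajectory and its topology sidecar
#'
#' @param path multi-model PDB file.
#' @param topology_path JSON topology file.
#' @return list with elements `trajectory` and `topology`.
#' @export
read_trajectory <- function(path, topology_path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) starts <- 0  # single implicit model
  counts <- integer(0)
  if (starts[1] != 0) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("format error: unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(starts), function(i)
      sum(grepl("^ATOM|^HETATM", lines[starts[i]:ends[i]])), integer(1))
    if (length(unique(counts)) > 1)
      stop("format error: inconsistent atom count across models (",
           paste(unique(counts), collapse = ", "), ")")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = at$eleno, atom_name = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(at$elety, 1, 1), at$elesy),
                      resno = at$resno, resid = at$resid, chain = at$chain,
                      stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(atoms)
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  tl <- jsonlite::read_json(topology_path, simplifyVector = TRUE)
  topo <- strand_topology(
    strand = unlist(tl$strand),
    dissociating_strand = tl$dissociating_strand,
    cleavage_site = tl$cleavage_site,
    dihedral_specs = lapply(tl$dihedral_specs, unlist),
    chromophore_residues = tl$chromophore_residues)
  schedule <- if (!is.null(tl$schedule)) as.data.frame(tl$schedule) else NULL
  traj <- strand_trajectory(atoms, coords, schedule = schedule)
  for (spec in topo$dihedral_specs) resolve_atoms(atoms, spec)
  list(trajectory = traj, topology = topo)
}
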