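#' Specification of a synthetic three-strand barrel fragment
#'
#' Defines an idealized antiparallel three-strand fragment of a beta-barrel
#' (strands labelled "7", "10", "11" by default, the central strand "10"
#' dissociating) with a planted, fully known interaction registry. Strands
#' lie on a cylinder of radius `radius` around the barrel axis (the x axis);
#' CA atoms are spaced `spacing` angstrom along each strand and sidechains
#' are reduced to CB plus one interaction-site pseudo-atom (`SC`), placed so
#' that every planted interaction satisfies the default geometric detection
#' criteria in noise-free frames.
#'
#' @param n_residues_per_strand residues per strand.
#' @param strand_labels three strand labels; the central strand is listed
#'   second.
#' @param dissociating_strand label of the strand that dissociates.
#' @param strand_start named integer vector: first residue number per strand.
#' @param register_sum named integer vector (for the two neighbor strands):
#'   residue `j` of a neighbor is cross-strand aligned with residue
#'   `register_sum - j` of the dissociating strand.
#' @param radius barrel radius (angstrom).
#' @param spacing CA-CA spacing along a strand (angstrom).
#' @param theta named numeric: angular position (degrees) of each strand on
#'   the barrel circle.
#' @param residue_names named character vector of 3-letter residue names
#'   overriding the default `ALA`.
#' @param orientation_parity named character (`"odd"` or `"even"`) per
#'   strand: which residue-number parity points *into* the barrel.
#' @param backbone_hbonds `"ladder"` for the ideal alternating double-bond
#'   ladder, or a data.frame with columns `donor`, `acceptor` (residue
#'   numbers; donor N to acceptor O).
#' @param backbone_exclude optional data.frame (`donor`, `acceptor`) of
#'   ladder bonds to omit.
#' @param ladder_offset 0 or 1: which residue parity of the dissociating
#'   strand pairs with the first neighbor strand in the ladder.
#' @param sidechain_interactions data.frame with columns `res_a`, `res_b`,
#'   `kind` (`hbond`, `salt_bridge`, `stacking`), `phase` (`all`, `odd`,
#'   `even`: frames in which the interaction is present), `mc_b` (logical:
#'   partner b participates through its mainchain O), `breaker` (`a` or
#'   `b`: whose atom is displaced when the interaction is broken by a
#'   planted event).
#' @param chromophore_contacts data.frame with columns `res`, `atom` (a
#'   chromophore atom, `OH` or `O2`), `lo`, `hi`: the residue's sidechain
#'   contacts that chromophore atom whenever the fixture's `phi_I` lies in
#'   `[lo, hi]` degrees.
#' @param extra_residues data.frame with columns `resno`, `resid`, `label`,
#'   `x`, `y`, `z`, `dx`, `dy`, `dz` (CA position and sidechain direction)
#'   for off-strand residues such as a chromophore-adjacent loop asparagine.
#' @param stub loop residues appended past the cleavage site of the
#'   dissociating strand (the cut linker stub).
#' @param cleavage_site residue pair flanking the proteolytic cut.
#' @param phi_I,phi_P chromophore twisting dihedrals (degrees) of the
#'   generated state (cis = 0, trans = 180).
#' @param solvate_terminus logical: displace the cleaved end of the
#'   dissociating strand off the sheet (the solvated-terminus state).
#' @param solvation_shift displacement (angstrom) of the solvated terminus.
#' @param seed integer seed controlling all randomness of the generator.
#' @return an object of class `barrel_fixture_spec`.
#' @export
barrel_fixture_spec <- function(n_residues_per_strand = 12,
                                strand_labels = c("7", "10", "11"),
                                dissociating_strand = "10",
                                strand_start = c("7" = 143, "10" = 198,
                                                 "11" = 214),
                                register_sum = c("7" = 352, "11" = 423),
                                radius = 9.274, spacing = 3.4,
                                theta = c("7" = 30, "10" = 0, "11" = -30),
                                residue_names = NULL,
                                orientation_parity = c("7" = "even",
                                                       "10" = "odd",
                                                       "11" = "odd"),
                                backbone_hbonds = "ladder",
                                backbone_exclude = NULL,
                                ladder_offset = 0,
                                sidechain_interactions = NULL,
                                chromophore_contacts = NULL,
                                extra_residues = NULL,
                                stub = 2,
                                cleavage_site = c(209, 214),
                                phi_I = 0, phi_P = 0,
                                solvate_terminus = FALSE,
                                solvation_shift = 8,
                                seed = 1) {
  if (!dissociating_strand %in% strand_labels)
    stop("fixture error: dissociating_strand not among strand_labels")
  spec <- structure(as.list(environment()), class = "barrel_fixture_spec")
  validate_fixture_spec(spec)
  spec
}

fixture_residue_table <- function(spec) {
  n <- spec$n_residues_per_strand
  d10 <- spec$dissociating_strand
  start10 <- spec$strand_start[[d10]]
  rows <- list()
  for (s in spec$strand_labels) {
    resno <- spec$strand_start[[s]] + seq_len(n) - 1
    if (s == d10) {
      u <- resno - start10
      dir <- 1
    } else {
      u <- spec$register_sum[[s]] - resno - start10
      dir <- -1
    }
    rows[[s]] <- data.frame(resno = resno, label = s, u = u, dir = dir,
                            theta = spec$theta[[s]], extra = FALSE)
  }
  if (spec$stub > 0) {
    resno <- spec$cleavage_site[1] + seq_len(spec$stub)
    rows$stub <- data.frame(resno = resno, label = "loop",
                            u = resno - start10, dir = 1,
                            theta = spec$theta[[d10]], extra = FALSE)
  }
  rt <- do.call(rbind, rows)
  rt$resid <- "ALA"
  if (!is.null(spec$residue_names)) {
    hit <- match(names(spec$residue_names), as.character(rt$resno))
    rt$resid[hit[!is.na(hit)]] <- spec$residue_names[!is.na(hit)]
  }
  if (!is.null(spec$extra_residues)) {
    ex <- spec$extra_residues
    rt <- rbind(rt, data.frame(resno = ex$resno, label = ex$label,
                               u = NA, dir = 1, theta = NA,
                               extra = TRUE, resid = ex$resid))
  }
  rownames(rt) <- NULL
  if (anyDuplicated(rt$resno)) stop("fixture error: duplicate residue number")
  rt
}

validate_fixture_spec <- function(spec) {
  rt <- fixture_residue_table(spec)
  known <- rt$resno
  si <- spec$sidechain_interactions
  if (!is.null(si)) {
    miss <- setdiff(c(si$res_a, si$res_b), known)
    if (length(miss))
      stop("fixture error: planted interaction references absent residue(s) ",
           paste(miss, collapse = ", "))
    bad <- rt$resid[match(si$res_a, rt$resno)] %in% c("GLY", "ALA", "PRO")
    if (any(bad))
      stop("fixture error: residue without functional sidechain planted: ",
           paste(si$res_a[bad], collapse = ", "))
  }
  cc <- spec$chromophore_contacts
  if (!is.null(cc)) {
    miss <- setdiff(cc$res, known)
    if (length(miss))
      stop("fixture error: chromophore contact references absent residue(s) ",
           paste(miss, collapse = ", "))
  }
  if (is.data.frame(spec$backbone_hbonds)) {
    miss <- setdiff(c(spec$backbone_hbonds$donor,
                      spec$backbone_hbonds$acceptor), known)
    if (length(miss))
      stop("fixture error: backbone hbond references absent residue(s) ",
           paste(miss, collapse = ", "))
  }
  invisible(spec)
}

# sidechain functional classes used both by the generator (element choice)
# and by the detector (donor/acceptor/charge/aromatic roles)
.sc_donor <- c("SER", "THR", "TYR", "CYS", "ASN", "GLN", "HIS", "LYS",
               "ARG", "TRP")
.sc_acceptor <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "ASP", "GLU")
.sc_positive <- c("LYS", "ARG", "HIS")
.sc_negative <- c("ASP", "GLU")
.sc_aromatic <- c("PHE", "TYR", "TRP", "HIS")
.no_sc <- c("GLY", "ALA", "PRO")

sc_element <- function(resid) {
  ifelse(resid %in% c("SER", "THR", "TYR", "ASP", "GLU"), "O",
         ifelse(resid %in% c("ASN", "GLN", "HIS", "LYS", "ARG", "TRP"), "N",
                "C"))
}

# ladder of paired backbone hydrogen bonds: cross-strand aligned residue
# pairs, alternating neighbor strand with residue parity, two bonds per pair
ladder_backbone <- function(spec, rt) {
  d10 <- spec$dissociating_strand
  neighbors <- setdiff(spec$strand_labels, d10)
  res10 <- rt$resno[rt$label == d10]
  off <- if (is.null(spec$ladder_offset)) 0 else spec$ladder_offset
  out <- list()
  for (i in res10) {
    s <- neighbors[1 + (i - rt$resno[rt$label == d10][1] + off) %% 2]
    j <- spec$register_sum[[s]] - i
    if (!j %in% rt$resno[rt$label == s]) next
    out[[length(out) + 1]] <- data.frame(donor = c(i, j), acceptor = c(j, i))
  }
  do.call(rbind, out)
}


# push direction u away from the antecedent direction so the planted proxy
# angle clears its cutoff with margin
away_from <- function(u, chat, min_comp = 0.8) {
  comp <- sum(u * chat)
  if (comp > -min_comp) u <- unitv(u - (comp + min_comp) * chat)
  u
}

# deterministic construction of the base (noise-free, frame-independent)
# geometry plus all planted-interaction positions and metadata
build_fixture <- function(spec, solvate = spec$solvate_terminus) {
  rt <- fixture_residue_table(spec)
  d10 <- spec$dissociating_strand
  xhat <- c(1, 0, 0)

  # CA positions
  ca <- matrix(NA_real_, nrow(rt), 3)
  radial <- matrix(NA_real_, nrow(rt), 3)
  for (k in seq_len(nrow(rt))) {
    if (rt$extra[k]) {
      ex <- spec$extra_residues
      m <- match(rt$resno[k], ex$resno)
      ca[k, ] <- c(ex$x[m], ex$y[m], ex$z[m])
      radial[k, ] <- unitv(c(ex$dx[m], ex$dy[m], ex$dz[m]))
    } else {
      th <- rt$theta[k] * pi / 180
      ca[k, ] <- c(spec$spacing * rt$u[k], spec$radius * sin(th),
                   spec$radius * cos(th))
      radial[k, ] <- c(0, sin(th), cos(th))
    }
  }

  solvate_set <- integer(0)
  if (solvate) {
    res_solv <- (spec$cleavage_site[1] - 2):(spec$cleavage_site[1] + spec$stub)
    solvate_set <- which(rt$resno %in% res_solv &
                           (rt$label == d10 | rt$label == "loop") &
                           !rt$extra)
    ca[solvate_set, ] <- ca[solvate_set, ] +
      rep(1, length(solvate_set)) %o% (spec$solvation_shift * c(0, 0, 1))
  }

  # backbone and sidechain pseudo-atoms
  pos <- list()   # named list "resno:atom" -> xyz
  put <- function(resno, atom, xyz) pos[[paste0(resno, ":", atom)]] <<- xyz
  get_pos <- function(resno, atom) {
    p <- pos[[paste0(resno, ":", atom)]]
    if (is.null(p)) stop("fixture error: atom ", resno, ":", atom,
                         " not present")
    p
  }
  cb_dir <- matrix(NA_real_, nrow(rt), 3)
  for (k in seq_len(nrow(rt))) {
    rn <- rt$resno[k]
    put(rn, "N", ca[k, ] - 0.6 * rt$dir[k] * xhat)
    put(rn, "CA", ca[k, ])
    cpos <- ca[k, ] + 1.2 * rt$dir[k] * xhat
    put(rn, "C", cpos)
    put(rn, "O", cpos + 1.0 * radial[k, ])
    if (rt$resid[k] != "GLY") {
      inward <- if (rt$extra[k]) FALSE else {
        par <- unname(spec$orientation_parity[rt$label[k]])
        if (is.na(par)) par <- "odd"
        (rn %% 2 == 1) == (par == "odd")
      }
      dirv <- if (inward) -radial[k, ] else radial[k, ]
      cb_dir[k, ] <- dirv
      put(rn, "CB", ca[k, ] + 1.5 * dirv)
      if (!rt$resid[k] %in% .no_sc) {
        # inward sidechains are staggered along the strand axis (by strand)
        # so tips of cross-strand aligned residues do not converge
        scdir <- if (inward && !rt$extra[k]) {
          sgn <- if (rt$label[k] == d10) 1 else -1
          unitv(dirv + 0.85 * sgn * xhat)
        } else dirv
        put(rn, "SC", ca[k, ] + 1.5 * dirv + 1.5 * scdir)
      }
    }
  }

  # chromophore: two conjugated ring anchors around the methine bridge
  # C2-C3; phi_I twists the imidazolinone side (C4, O2), phi_P the phenolate
  # side (C5, OH)
  cro_resno <- 66L
  ctr <- c(spec$spacing * 6, 0, 1.8)
  C2 <- ctr
  C3 <- ctr + c(1.4, 0, 0)
  C1 <- C2 + 1.4 * c(-0.5, sqrt(3) / 2, 0)
  C4 <- place_atom(C1, C2, C3, 1.4, 120, spec$phi_I)
  O2 <- place_atom(C2, C3, C4, 1.3, 120, 180)
  N2 <- place_atom(C1, C2, C3, 1.35, 120, spec$phi_I + 180)
  C5 <- place_atom(C3, C2, C1, 1.4, 120, spec$phi_P)
  OH <- place_atom(C2, C1, C5, 1.3, 120, 180)
  for (nm in c("C1", "C2", "C3", "C4", "C5", "OH", "O2", "N2"))
    put(cro_resno, nm, get(nm))

  # planted backbone hydrogen bonds
  bb <- spec$backbone_hbonds
  if (identical(bb, "ladder")) bb <- ladder_backbone(spec, rt)
  if (!is.null(spec$backbone_exclude) && !is.null(bb)) {
    drop <- paste(spec$backbone_exclude$donor, spec$backbone_exclude$acceptor)
    bb <- bb[!paste(bb$donor, bb$acceptor) %in% drop, , drop = FALSE]
  }
  if (solvate && !is.null(bb)) {
    res_solv <- rt$resno[solvate_set]
    bb <- bb[!(bb$donor %in% res_solv | bb$acceptor %in% res_solv), ,
             drop = FALSE]
  }
  if (!is.null(bb) && nrow(bb)) {
    if (anyDuplicated(bb$donor) || anyDuplicated(bb$acceptor))
      stop("fixture error: residue donates or accepts more than one ",
           "backbone hydrogen bond")
    for (i in seq_len(nrow(bb))) {
      kd <- match(bb$donor[i], rt$resno)
      kaidx <- match(bb$acceptor[i], rt$resno)
      u <- unitv(ca[kaidx, ] - ca[kd, ])
      npos <- ca[kd, ] - 0.6 * rt$dir[kd] * xhat + 0.95 * u
      put(bb$donor[i], "N", npos)
      put(bb$acceptor[i], "O", npos + 2.9 * u)
    }
  }

  # planted sidechain interactions; processed in order, a sidechain already
  # placed by an earlier interaction is not moved again
  si <- spec$sidechain_interactions
  sc_fixed <- character(0)
  sc_active <- list()  # per phased interaction: active position of SC res_a
  plant_target <- c(hbond = 2.8, salt_bridge = 3.4, stacking = 3.2)
  if (!is.null(si) && nrow(si)) {
    if (is.null(si$phase)) si$phase <- "all"
    if (is.null(si$mc_b)) si$mc_b <- FALSE
    if (is.null(si$breaker)) si$breaker <- "a"
    for (i in seq_len(nrow(si))) {
      ra <- si$res_a[i]; rb <- si$res_b[i]
      t <- plant_target[[si$kind[i]]]
      if (isTRUE(si$mc_b[i])) {
        # sidechain of a to mainchain O of b
        o <- get_pos(rb, "O")
        cpos <- get_pos(rb, "C")
        if (paste0(ra, ":SC") %in% sc_fixed) {
          # move the acceptor O toward the already-placed sidechain
          scp <- get_pos(ra, "SC")
          d <- vnorm(scp - cpos)
          o_new <- if (d < t + 1.23) cpos + 1.23 * unitv(scp - cpos)
                   else scp + t * unitv(cpos - scp)
          put(rb, "O", o_new)
        } else {
          u <- away_from(unitv(get_pos(ra, "CB") - o), unitv(cpos - o))
          put(ra, "SC", o + t * u)
          sc_fixed <- c(sc_fixed, paste0(ra, ":SC"))
        }
      } else {
        cba <- get_pos(ra, "CB"); cbb <- get_pos(rb, "CB")
        w <- unitv(cbb - cba)
        mid <- (cba + cbb) / 2
        pa <- mid - (t / 2) * w
        pb <- mid + (t / 2) * w
        if (!paste0(rb, ":SC") %in% sc_fixed) {
          put(rb, "SC", pb)
          sc_fixed <- c(sc_fixed, paste0(rb, ":SC"))
        } else pa <- get_pos(rb, "SC") - t * w
        if (si$phase[i] == "all") {
          if (!paste0(ra, ":SC") %in% sc_fixed) {
            put(ra, "SC", pa)
            sc_fixed <- c(sc_fixed, paste0(ra, ":SC"))
          }
        } else {
          sc_active[[i]] <- pa
        }
      }
    }
  }

  # chromophore contacts active at this spec's phi_I
  cc <- spec$chromophore_contacts
  cc_active <- logical(0)
  if (!is.null(cc) && nrow(cc)) {
    cc_active <- spec$phi_I >= cc$lo & spec$phi_I <= cc$hi
    for (i in which(cc_active)) {
      target <- get_pos(cro_resno, cc$atom[i])
      ante <- get_pos(cro_resno, switch(cc$atom[i], OH = "C5", O2 = "C4",
                                        N2 = "C3"))
      u <- away_from(unitv(get_pos(cc$res[i], "CB") - target),
                     unitv(ante - target))
      put(cc$res[i], "SC", target + 2.9 * u)
      sc_fixed <- c(sc_fixed, paste0(cc$res[i], ":SC"))
    }
  }

  # assemble atom table in residue order
  atoms <- list(); xyz <- list()
  add <- function(resno, resid, atom, element) {
    key <- paste0(resno, ":", atom)
    if (is.null(pos[[key]])) return()
    atoms[[length(atoms) + 1]] <<- data.frame(
      atom_name = atom, element = element, resno = resno, resid = resid,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- pos[[key]]
  }
  for (k in seq_len(nrow(rt))) {
    rn <- rt$resno[k]; rs <- rt$resid[k]
    add(rn, rs, "N", "N"); add(rn, rs, "CA", "C"); add(rn, rs, "C", "C")
    add(rn, rs, "O", "O"); add(rn, rs, "CB", "C")
    add(rn, rs, "SC", sc_element(rs))
  }
  for (nm in c("C1", "C2", "C3", "C4", "C5"))
    add(cro_resno, "CRO", nm, "C")
  add(cro_resno, "CRO", "OH", "O"); add(cro_resno, "CRO", "O2", "O")
  add(cro_resno, "CRO", "N2", "N")
  atoms <- do.call(rbind, atoms)
  atoms$chain <- "A"
  atoms$serial <- seq_len(nrow(atoms))
  base <- do.call(rbind, xyz)

  strand_map <- stats::setNames(rt$label, as.character(rt$resno))
  topo <- strand_topology(
    strand = strand_map,
    dissociating_strand = d10,
    cleavage_site = spec$cleavage_site,
    dihedral_specs = list(
      phi_I = paste("A", cro_resno, c("C1", "C2", "C3", "C4"), sep = ":"),
      phi_P = paste("A", cro_resno, c("C3", "C2", "C1", "C5"), sep = ":")),
    chromophore_residues = cro_resno)

  list(atoms = atoms, base = base, res_table = rt, topo = topo,
       sidechain = si, sc_active = sc_active, cc = cc, cc_active = cc_active,
       backbone = bb, solvate_set = solvate_set, radial10 = c(0, 0, 1))
}

#' Planted dissociation event
#'
#' Describes the ground truth planted into an annealing trajectory: the
#' ordered loss of anchor interactions, the dissociation onset and the drift
#' of the strand after onset.
#'
#' @param losses data.frame with columns `res_a`, `res_b`, `frame`: the
#'   planted sidechain interaction between the two residues is last present
#'   at `frame`. Rows must be ordered by increasing `frame` and each
#'   referenced interaction must exist in the fixture spec.
#' @param onset_frame first frame of strand drift; must be at least the
#'   second-largest loss frame (every anchor but the final one is lost
#'   strictly before onset).
#' @param drift displacement of the dissociating strand per frame after
#'   onset (angstrom).
#' @param solvation_frame frame from which the cleaved terminus is displaced
#'   off the sheet (1 = from the start).
#' @return an object of class `planted_dissociation`.
#' @export
planted_dissociation <- function(losses, onset_frame, drift = 1,
                                 solvation_frame = 1) {
  stopifnot(is.data.frame(losses),
            all(c("res_a", "res_b", "frame") %in% names(losses)))
  if (is.unsorted(losses$frame))
    stop("losses must be ordered by increasing frame")
  if (nrow(losses) > 1 &&
      onset_frame <= losses$frame[nrow(losses) - 1])
    stop("onset_frame must lie strictly after all but the final anchor loss")
  structure(list(losses = losses, onset_frame = onset_frame, drift = drift,
                 solvation_frame = solvation_frame),
            class = "planted_dissociation")
}

#' Generate a synthetic barrel trajectory with planted ground truth
#'
#' Produces an ensemble of frames of the fixture defined by `spec`:
#' isotropic Gaussian thermal noise per atom per frame, optional alternating
#' (odd/even frame) sidechain contacts, and, when `event` is given, ordered
#' anchor-interaction losses followed by rigid drift of the dissociating
#' strand. Identical `spec` (including its `seed`) and arguments give
#' byte-identical output.
#'
#' @param spec a [barrel_fixture_spec()].
#' @param n_frames number of frames (>= 1).
#' @param thermal_noise per-atom isotropic Gaussian displacement sd
#'   (angstrom).
#' @param event a [planted_dissociation()] or `NULL`.
#' @param schedule optional annealing schedule data.frame (`from`, `to`,
#'   `temp_K`).
#' @return list with `trajectory` (a [strand_trajectory()], with the planted
#'   ground truth in attribute `"planted"`) and `topology`.
#' @export
generate_barrel_trajectory <- function(spec, n_frames = 100,
                                       thermal_noise = 0, event = NULL,
                                       schedule = NULL) {
  stopifnot(n_frames >= 1, thermal_noise >= 0)
  solv_static <- spec$solvate_terminus ||
    (!is.null(event) && event$solvation_frame <= 1)
  fx <- build_fixture(spec, solvate = solv_static)
  atoms <- fx$atoms
  na <- nrow(atoms)
  si <- fx$sidechain

  # resolve planted-event losses against the planted interaction list
  loss <- NULL
  if (!is.null(event)) {
    if (is.null(si)) stop("fixture error: event without planted interactions")
    idx <- match(paste(event$losses$res_a, event$losses$res_b),
                 paste(si$res_a, si$res_b))
    if (anyNA(idx))
      stop("fixture error: event references non-planted interaction")
    loss <- data.frame(row = idx, frame = event$losses$frame)
  }

  atom_row <- function(resno, atom)
    which(atoms$resno == resno & atoms$atom_name == atom)
  mobile_of <- function(i) {
    side <- if (si$breaker[i] == "a") "a" else "b"
    rn <- if (side == "a") si$res_a[i] else si$res_b[i]
    nm <- if (side == "b" && isTRUE(si$mc_b[i])) "O" else "SC"
    atom_row(rn, nm)
  }
  partner_of <- function(i) {
    side <- if (si$breaker[i] == "a") "b" else "a"
    rn <- if (side == "a") si$res_a[i] else si$res_b[i]
    nm <- if (side == "b" && isTRUE(si$mc_b[i])) "O" else "SC"
    atom_row(rn, nm)
  }

  drift_res <- c(fx$res_table$resno[fx$res_table$label ==
                                      spec$dissociating_strand],
                 spec$cleavage_site[1] + seq_len(spec$stub))
  drift_rows <- which(atoms$resno %in% drift_res)

  coords <- array(NA_real_, c(na, 3, n_frames))
  with_seed(spec$seed, {
    for (f in seq_len(n_frames)) {
      xyz <- fx$base
      # alternating contacts: the shared sidechain sits at the planted
      # position on its phase frames, at its default position otherwise
      if (!is.null(si)) {
        for (i in seq_len(nrow(si))) {
          ph <- si$phase[i]
          if (ph == "all" || is.null(fx$sc_active[[i]])) next
          on <- (f %% 2 == 1) == (ph == "odd")
          if (on) xyz[atom_row(si$res_a[i], "SC"), ] <- fx$sc_active[[i]]
        }
      }
      if (!is.null(loss)) {
        for (j in seq_len(nrow(loss))) {
          if (f > loss$frame[j]) {
            i <- loss$row[j]
            m <- mobile_of(i); p <- partner_of(i)
            xyz[m, ] <- xyz[m, ] + 6 * unitv(fx$base[m, ] - fx$base[p, ])
          }
        }
      }
      if (!is.null(event) && !solv_static && f >= event$solvation_frame) {
        # dynamic solvation: displacement applied from solvation_frame on
        srows <- which(atoms$resno %in%
          ((spec$cleavage_site[1] - 2):(spec$cleavage_site[1] + spec$stub)))
        xyz[srows, ] <- xyz[srows, ] +
          rep(1, length(srows)) %o% (spec$solvation_shift * fx$radial10)
      }
      if (!is.null(event) && f > event$onset_frame)
        xyz[drift_rows, ] <- xyz[drift_rows, ] +
          rep(1, length(drift_rows)) %o%
            ((f - event$onset_frame) * event$drift * fx$radial10)
      if (thermal_noise > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * na, sd = thermal_noise), na, 3)
      coords[, , f] <- xyz
    }
  })

  traj <- strand_trajectory(atoms[, c("serial", "atom_name", "element",
                                      "resno", "resid", "chain")],
                            coords, schedule = schedule)
  planted <- list(spec = spec, sidechain = si, backbone = fx$backbone,
                  contacts = if (!is.null(fx$cc))
                    cbind(fx$cc, active = fx$cc_active) else NULL,
                  event = event)
  if (!is.null(event) && !is.null(si)) {
    planted$anchor_order <- data.frame(
      res_a = si$res_a[loss$row], res_b = si$res_b[loss$row],
      kind = si$kind[loss$row], mc_b = si$mc_b[loss$row],
      last_present_frame = loss$frame)
  }
  attr(traj, "planted") <- planted
  list(trajectory = traj, topology = fx$topo)
}

#' The split-GFP worked-example fixture
#'
#' Preset [barrel_fixture_spec()] encoding the interaction registry of the
#' circularly permuted split GFP around its dissociating strand 10: the
#' Tyr200-Tyr151 stacking, the Ser202 hydrogen bonds alternating between
#' Asn225 (strand 11) and Asn149 (strand 7), the Lys209 salt bridge with
#' Asp216 and hydrogen bond with the His217 mainchain, the strand-11 anchors
#' (Lys214, Arg215, His217) to the strand-10 mainchain near the cleavage
#' site, chromophore contacts (Thr203, Thr205, His148, and Asn121 on the far
#' side of the chromophore), and the cut between strands 10 and 11.
#'
#' @param state `"cis"` (ground state, chromophore at 0 deg),
#'   `"trans"` (isomerization endpoint at 180 deg: strand-10/7 sidechain
#'   contacts lost, none formed, cleaved end solvated),
#'   `"trans_anneal"` (trans complex entering heating: anchors still formed,
#'   used with a planted dissociation event), or
#'   `"trans_postheat"` (partially disordered: sidechain interactions
#'   reduced to Tyr200 and Ser202).
#' @param seed generator seed.
#' @param phi_I chromophore dihedral override (defaults: 0 for cis, 180 for
#'   the trans states).
#' @return list with `spec` (a `barrel_fixture_spec`) and `event` (a
#'   [planted_dissociation()] for `"trans_anneal"`, else `NULL`).
#' @export
split_gfp_fixture <- function(state = c("cis", "trans", "trans_anneal",
                                        "trans_postheat"),
                              seed = 1, phi_I = NULL) {
  state <- match.arg(state)
  trans <- state != "cis"
  if (is.null(phi_I)) phi_I <- if (trans) 180 else 0

  names <- c("200" = "TYR", "202" = "SER", "203" = "THR", "205" = "THR",
             "209" = "LYS", "147" = "SER", "148" = "HIS",
             "149" = "ASN", "151" = "TYR", "214" = "LYS", "215" = "ARG",
             "216" = "ASP", "217" = "HIS", "225" = "ASN")

  core <- data.frame(
    res_a = c(200, 202, 202, 209, 209),
    res_b = c(151, 225, 149, 216, 217),
    kind = c("stacking", "hbond", "hbond", "salt_bridge", "hbond"),
    phase = c("all", "odd", "even", "all", "all"),
    mc_b = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    breaker = c("a", "a", "a", "b", "a"),
    stringsAsFactors = FALSE)
  anchors <- data.frame(
    res_a = c(214, 215, 217),
    res_b = c(209, 208, 207),
    kind = "hbond", phase = "all", mc_b = TRUE, breaker = "a",
    stringsAsFactors = FALSE)

  si <- switch(state,
    cis = core,
    trans = core[core$res_b %in% c(225, 216, 217), ],
    trans_anneal = rbind(core, anchors),
    trans_postheat = core[core$res_a %in% c(200, 202), ])

  contacts <- data.frame(res = c(203, 205, 148, 121),
                         atom = c("OH", "O2", "N2", "O2"),
                         lo = c(-10, -20, -20, 55),
                         hi = c(10, 45, 45, 125))
  extra <- data.frame(resno = 121, resid = "ASN", label = "loop",
                      x = 20.4, y = 0, z = -7, dx = 0, dy = 0, dz = 1)

  spec <- barrel_fixture_spec(
    register_sum = c("7" = 351, "11" = 427),
    ladder_offset = 1,
    residue_names = names,
    sidechain_interactions = si,
    chromophore_contacts = contacts,
    extra_residues = extra,
    phi_I = phi_I,
    solvate_terminus = trans,
    seed = seed)

  event <- NULL
  if (state == "trans_anneal") {
    event <- planted_dissociation(
      losses = data.frame(res_a = c(214, 215, 217, 209, 209),
                          res_b = c(209, 208, 207, 216, 217),
                          frame = c(18, 26, 34, 42, 48)),
      onset_frame = 50, drift = 1, solvation_frame = 1)
  }
  list(spec = spec, event = event)
}

#' Default annealing schedule for trans-complex heating runs
#'
#' Room temperature, a ramp, then the high-temperature plateau at 600 K
#' where strand dissociation is observed.
#'
#' @param n_frames trajectory length.
#' @return data.frame with columns `from`, `to`, `temp_K`.
#' @export
annealing_schedule <- function(n_frames = 120) {
  data.frame(from = c(1, 31, 46),
             to = c(30, 45, n_frames),
             temp_K = c(300, 450, 600))
}

#' Generate umbrella-window trajectories along the isomerization coordinate
#'
#' One short trajectory per window center: the chromophore is fixed at the
#' window's phi_I and the chromophore-contact registry of the fixture is
#' evaluated at that angle, emulating structures sampled while gradually
#' rotating the chromophore.
#'
#' @param spec a [barrel_fixture_spec()].
#' @param centers window centers in degrees, sorted ascending.
#' @param n_frames frames per window.
#' @param thermal_noise per-atom noise sd (angstrom).
#' @return list of lists with elements `center`, `trajectory`, `topology`.
#' @export
generate_pathway_windows <- function(spec, centers = seq(0, 180, by = 20),
                                     n_frames = 20, thermal_noise = 0) {
  stopifnot(!is.unsorted(centers))
  lapply(seq_along(centers), function(i) {
    s <- spec
    s$phi_I <- centers[i]
    s$seed <- spec$seed + i
    g <- generate_barrel_trajectory(s, n_frames = n_frames,
                                    thermal_noise = thermal_noise)
    list(center = centers[i], trajectory = g$trajectory,
         topology = g$topology)
  })
}

# ---- umbrella sampling -----------------------------------------------------

#' Periodic potential on the dihedral circle
#'
#' @param type `"zero"`, `"sinsq"` (`height * sin(phi)^2`, barrier at
#'   +/-90 deg), or `"cosine"` (`sum a_n * (1 - cos(n*(phi - phase_n)))/2`).
#' @param height barrier height (kcal/mol) for `"sinsq"`.
#' @param terms for `"cosine"`: data.frame with columns `n`, `a`, `phase`.
#' @param temperature temperature (K) at which windows are sampled.
#' @return object of class `periodic_potential` with element `V`, a
#'   vectorized function of degrees.
#' @export
periodic_potential <- function(type = c("sinsq", "zero", "cosine"),
                               height = 10, terms = NULL,
                               temperature = 300) {
  type <- match.arg(type)
  V <- switch(type,
    zero = function(phi) rep(0, length(phi)),
    sinsq = function(phi) height * sin(phi * pi / 180)^2,
    cosine = function(phi) {
      out <- numeric(length(phi))
      for (i in seq_len(nrow(terms)))
        out <- out + terms$a[i] *
          (1 - cos(terms$n[i] * (phi - terms$phase[i]) * pi / 180)) / 2
      out
    })
  structure(list(type = type, height = height, terms = terms,
                 temperature = temperature, V = V),
            class = "periodic_potential")
}

#' Generate biased umbrella-window samples from a known potential
#'
#' Draws i.i.d. samples from the biased Boltzmann density
#' `exp(-(V(phi) + k/2 * d(phi, center)^2) / kT)` (minimal-image angular
#' distance `d`) by inverse-CDF sampling on a 0.1-degree grid, so window
#' contents are exact draws rather than correlated dynamics.
#'
#' @param potential a [periodic_potential()].
#' @param centers window centers (degrees).
#' @param k_bias harmonic bias constant (kcal mol^-1 deg^-2).
#' @param n_per_window samples per window (>= 100).
#' @param seed integer seed.
#' @return list of `umbrella_window` objects (fields `center`, `k_bias`,
#'   `samples`, `temperature`).
#' @export
generate_umbrella_samples <- function(potential, centers, k_bias = 0.025,
                                      n_per_window = 5000, seed = 1) {
  if (length(centers) == 0) stop("no umbrella windows requested")
  stopifnot(n_per_window >= 100, k_bias > 0)
  kT <- .R_KCAL * potential$temperature
  grid <- seq(-179.95, 179.95, by = 0.1)
  Vg <- potential$V(grid)
  with_seed(seed, {
    lapply(centers, function(c0) {
      e <- Vg + 0.5 * k_bias * angle_diff(grid, c0)^2
      w <- exp(-(e - min(e)) / kT)
      idx <- sample.int(length(grid), n_per_window, replace = TRUE,
                        prob = w)
      phi <- wrap_angle(grid[idx] + stats::runif(n_per_window, -0.05, 0.05))
      structure(list(center = c0, k_bias = k_bias, samples = phi,
                     temperature = potential$temperature),
                class = "umbrella_window")
    })
  })
}

# ---- exchange traces -------------------------------------------------------

#' Generate a synthetic pseudo-first-order strand-exchange trace
#'
#' `signal(t) = offset + amplitude * (1 - exp(-k t)) + N(0, noise_sd)`,
#' emulating the green-to-yellow absorbance shift as an excess labelled
#' strand replaces the photodissociated one.
#'
#' @param k exchange rate (1/min), >= 0.
#' @param amplitude,offset signal scale and baseline (a.u.).
#' @param times sampling times (min), non-negative and strictly increasing.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed integer seed.
#' @param light_on logical flag stored as metadata.
#' @param variant optional variant name stored as metadata.
#' @return an `exchange_trace`: data.frame with columns `t_min`, `signal`
#'   and attributes `light_on`, `variant`, `k_true`.
#' @export
generate_exchange_trace <- function(k, amplitude = 1, offset = 0, times,
                                    noise_sd = 0, seed = 1, light_on = TRUE,
                                    variant = NULL) {
  if (k < 0) stop("rate k must be non-negative")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly increasing")
  signal <- offset + amplitude * (1 - exp(-k * times))
  if (noise_sd > 0)
    signal <- with_seed(seed, signal + stats::rnorm(length(times),
                                                    sd = noise_sd))
  structure(data.frame(t_min = times, signal = signal),
            light_on = light_on, variant = variant, k_true = k,
            class = c("exchange_trace", "data.frame"))
}
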