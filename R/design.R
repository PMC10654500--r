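#' Bundle the structural evidence used for mutation-site nomination
#'
#' @param cis_occupancy [occupancy()] table of the cis complex.
#' @param trans_occupancy [occupancy()] table of the pre-dissociation
#'   segment of the trans complex.
#' @param pathway a [pathway_profile()] along phi_I.
#' @param orientation per-residue orientation labels
#'   ([classify_orientation()] of the trans state).
#' @param anchor_order an [anchor_loss_order()] result.
#' @return object of class `design_evidence`.
#' @export
design_evidence <- function(cis_occupancy, trans_occupancy, pathway,
                            orientation, anchor_order) {
  structure(list(cis = cis_occupancy, trans = trans_occupancy,
                 pathway = pathway, orientation = orientation,
                 anchor_order = anchor_order),
            class = "design_evidence")
}

# residues whose sidechain participates in an interaction row set
sc_residues_of <- function(tab, rows = seq_len(nrow(tab))) {
  unique(c(tab$res_a[rows][tab$side_a[rows] == "sc"],
           tab$res_b[rows][tab$side_b[rows] == "sc"]))
}

#' Nominate mutation candidates
#'
#' Implements three design rules. Dissociation candidates: residues on the
#' dissociating strand, pointing out of the barrel or solvent-exposed,
#' whose sidechain keeps an inter-strand interaction in the trans (i.e.
#' pre-dissociation) state at or above `trans_threshold` occupancy, or
#' which appear among the anchor losses. Isomerization candidates: residues
#' whose sidechain contacts the chromophore in an interior window of the
#' isomerization pathway (strictly between the cis and trans endpoint
#' windows). A residue qualifying for both classes - because it lies on the
#' dissociating strand or interacts with it - is flagged excluded, since
#' the contribution of its mutation to each step could not be untangled.
#'
#' @param evidence a [design_evidence()].
#' @param topo a `strand_topology`.
#' @param trans_threshold occupancy threshold in the trans state (lower
#'   than the cis persistence threshold because the trans complex has fewer
#'   stable inter-strand interactions).
#' @param pathway_threshold occupancy for a chromophore contact to count in
#'   a window.
#' @return a `mutation_candidates` data.frame: `residue`, `name`, `class`
#'   (`dissociation` or `isomerization`), `rank` (within class),
#'   `excluded`, `reason`, `evidence`.
#' @export
nominate <- function(evidence, topo, trans_threshold = 0.3,
                     pathway_threshold = 0.2) {
  tt <- evidence$trans
  ct <- evidence$cis
  if (is.null(tt) || nrow(tt) == 0)
    stop("empty trans-state evidence table")
  d <- topo$dissociating_strand
  res_d <- strand_residues(topo, d)

  # --- dissociation class -------------------------------------------------
  inter_sc <- which((tt$side_a == "sc" | tt$side_b == "sc") &
                      tt$strand_a != "chromophore" &
                      tt$strand_b != "chromophore" &
                      tt$occupancy >= trans_threshold)
  occ_sum <- function(r) {
    rows <- inter_sc[(tt$res_a[inter_sc] == r & tt$side_a[inter_sc] == "sc") |
                       (tt$res_b[inter_sc] == r & tt$side_b[inter_sc] == "sc")]
    sum(tt$occupancy[rows])
  }
  anch <- evidence$anchor_order
  anchor_res <- if (!is.null(anch) && nrow(anch))
    sc_residues_of(anch) else integer(0)
  anchor_pos <- function(r) {
    if (is.null(anch) || !nrow(anch)) return(NA_real_)
    rows <- which((anch$res_a == r & anch$side_a == "sc") |
                    (anch$res_b == r & anch$side_b == "sc"))
    if (!length(rows)) NA_real_ else max(rows)
  }
  diss <- integer(0)
  for (r in res_d) {
    ori <- evidence$orientation[as.character(r)]
    if (is.na(ori) || !ori %in% c("out", "exposed")) next
    if (occ_sum(r) > 0 || r %in% anchor_res) diss <- c(diss, r)
  }

  # --- isomerization class ------------------------------------------------
  pw <- evidence$pathway
  centers <- pw$centers
  interior <- centers > min(centers) & centers < max(centers)
  cro_rows <- which(pw$info$strand_a == "chromophore" |
                      pw$info$strand_b == "chromophore")
  iso <- integer(0)
  for (i in cro_rows) {
    r <- if (pw$info$strand_a[i] == "chromophore") pw$info$res_b[i]
         else pw$info$res_a[i]
    side <- if (pw$info$strand_a[i] == "chromophore") pw$info$side_b[i]
            else pw$info$side_a[i]
    if (side != "sc") next
    if (any(pw$profile[i, interior] >= pathway_threshold))
      iso <- unique(c(iso, r))
  }

  # dual-class exclusion: on the dissociating strand, or interacting with it
  links_dissociating <- function(r) {
    for (tab in list(ct, tt)) {
      if (is.null(tab) || !nrow(tab)) next
      rows <- which((tab$res_a == r & tab$strand_b == d) |
                      (tab$res_b == r & tab$strand_a == d))
      if (any(tab$occupancy[rows] >= trans_threshold)) return(TRUE)
    }
    FALSE
  }

  resname <- function(r) {
    for (tab in list(tt, ct, evidence$pathway$info)) {
      if (is.null(tab) || !nrow(tab)) next
      m <- match(r, tab$res_a)
      if (!is.na(m)) return(tab$name_a[m])
      m <- match(r, tab$res_b)
      if (!is.na(m)) return(tab$name_b[m])
    }
    "UNK"
  }

  rows <- list()
  if (length(diss)) {
    score <- vapply(diss, occ_sum, numeric(1))
    apos <- vapply(diss, anchor_pos, numeric(1))
    ord <- order(-score, -ifelse(is.na(apos), -Inf, apos), diss)
    for (k in seq_along(ord)) {
      r <- diss[ord[k]]
      rows[[length(rows) + 1]] <- data.frame(
        residue = r, name = resname(r), class = "dissociation",
        rank = k, excluded = FALSE, reason = "",
        evidence = sprintf("trans occupancy sum %.2f%s", score[ord[k]],
                           ifelse(is.na(apos[ord[k]]), "",
                                  sprintf("; anchor loss #%d",
                                          as.integer(apos[ord[k]])))))
    }
  }
  for (r in iso) {
    dual <- r %in% res_d || links_dissociating(r)
    both <- r %in% diss
    rows[[length(rows) + 1]] <- data.frame(
      residue = r, name = resname(r), class = "isomerization",
      rank = NA_integer_, excluded = dual || both,
      reason = if (both || dual)
        "affects both isomerization and dissociation" else "",
      evidence = "chromophore contact in interior windows")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(residue = integer(), name = character(),
                      class = character(), rank = integer(),
                      excluded = logical(), reason = character(),
                      evidence = character())
  # exclusivity: drop the dissociation listing of any dual-class residue
  dup <- out$residue[out$class == "isomerization" & out$excluded]
  flag <- out$class == "dissociation" & out$residue %in% dup
  out$excluded[flag] <- TRUE
  out$reason[flag] <- "affects both isomerization and dissociation"
  # re-rank the remaining dissociation candidates
  keep <- out$class == "dissociation" & !out$excluded
  out$rank[keep] <- rank(out$rank[keep], ties.method = "first")
  out$rank[out$class == "dissociation" & out$excluded] <- NA_integer_
  rownames(out) <- NULL
  class(out) <- c("mutation_candidates", "data.frame")
  out
}

#' @export
print.mutation_candidates <- function(x, ...) {
  cat("mutation candidates:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Propose substitutions for a nominated site
#'
#' Two substitution strategies: removal of polar sidechain interactions by
#' alanine, or introduction of steric clashes with bulky nonpolar residues.
#'
#' @param candidate one row of a [nominate()] result (or a list with
#'   `name` and `excluded`).
#' @param mode `"remove_polar"` or `"steric_clash"`.
#' @return character vector of 3-letter amino-acid codes (empty, with a
#'   `"note"` attribute, for sites already small/nonpolar).
#' @export
propose_substitutions <- function(candidate,
                                  mode = c("remove_polar", "steric_clash")) {
  mode <- match.arg(mode)
  if (isTRUE(candidate$excluded))
    stop("cannot propose substitutions for an excluded candidate")
  if (candidate$name %in% c("GLY", "ALA", "PRO"))
    return(structure(character(0),
                     note = "site already lacks a polar sidechain"))
  switch(mode,
         remove_polar = "ALA",
         steric_clash = c("ILE", "VAL", "LEU", "TRP"))
}

#' Name a variant by its mutated-position letters
#'
#' Variants are named by the one-letter amino acids at the named on-strand
#' positions, ordered N- to C-terminal (wild type letter where unmutated),
#' with off-strand additions appended after a hyphen.
#'
#' @param wildtype named character vector: names are residue positions,
#'   values the wild-type one-letter codes (default the Tyr200 / Ser202 /
#'   Lys209 reference, "YSK").
#' @param mutations named character vector position -> replacement amino
#'   acid (one- or three-letter).
#' @param off_strand named character vector of off-strand additions (e.g.
#'   `c("121" = "A")` for Asn121Ala).
#' @return the variant name string.
#' @export
#' @examples
#' name_variant()                                      # "YSK"
#' name_variant(mutations = c("200" = "A", "202" = "A", "209" = "A"))
#' name_variant(mutations = c("200" = "I", "202" = "W", "209" = "I"),
#'              off_strand = c("121" = "A"))           # "IWI-A"
name_variant <- function(wildtype = c("200" = "Y", "202" = "S",
                                      "209" = "K"),
                         mutations = NULL, off_strand = NULL) {
  to1 <- function(x) ifelse(nchar(x) == 3, aa_one(toupper(x)), toupper(x))
  pos <- names(wildtype)[order(as.integer(names(wildtype)))]
  letters <- stats::setNames(to1(wildtype), names(wildtype))[pos]
  if (!is.null(mutations)) {
    unknown <- setdiff(names(mutations), pos)
    if (length(unknown))
      stop("unknown mutated position(s): ", paste(unknown, collapse = ", "))
    letters[names(mutations)] <- to1(mutations)
  }
  name <- paste(letters, collapse = "")
  if (!is.null(off_strand) && length(off_strand))
    name <- paste0(name, "-",
                   paste(to1(off_strand)[order(as.integer(
                     names(off_strand)))], collapse = ""))
  name
}

#' Enumerate combination mutants of the nominated sites
#'
#' Single-site nominations do not predict combination effects (a site may
#' be unimproved alone yet essential in a triple mutant), so the engine
#' also emits all 1-, 2- and 3-site combinations of the non-excluded
#' dissociation candidates.
#'
#' @param candidates a [nominate()] result.
#' @param max_size largest combination size.
#' @return list of integer vectors of residue positions.
#' @export
candidate_combinations <- function(candidates, max_size = 3) {
  sites <- sort(candidates$residue[candidates$class == "dissociation" &
                                     !candidates$excluded])
  out <- list()
  for (k in seq_len(min(max_size, length(sites))))
    out <- c(out, utils::combn(sites, k, simplify = FALSE))
  out
}

#' Run the split-GFP design worked example end to end
#'
#' Generates the synthetic split-GFP states, computes the evidence the
#' design rules consume (cis and pre-dissociation trans occupancies, the
#' chromophore-contact pathway profile, trans-state orientations and the
#' anchor-loss order from an annealing run with a planted dissociation
#' event), and nominates mutation candidates.
#'
#' @param seed generator seed.
#' @param n_frames frames for the cis / trans occupancy segments.
#' @param noise thermal noise sd (angstrom).
#' @return list with `evidence`, `candidates`, `variants` (named combination
#'   mutants in both substitution modes), `topology`.
#' @export
split_gfp_design_demo <- function(seed = 1, n_frames = 40, noise = 0.15) {
  cis <- split_gfp_fixture("cis", seed = seed)
  gc <- generate_barrel_trajectory(cis$spec, n_frames = n_frames,
                                   thermal_noise = noise)
  cis_tab <- occupancy(gc$trajectory, gc$topology)

  anneal <- split_gfp_fixture("trans_anneal", seed = seed + 1)
  nf <- 120
  ga <- generate_barrel_trajectory(anneal$spec, n_frames = nf,
                                   thermal_noise = noise,
                                   event = anneal$event,
                                   schedule = annealing_schedule(nf))
  pre <- seq_len(anneal$event$onset_frame - 1)
  trans_tab <- occupancy(ga$trajectory, ga$topology, frame_range = pre)
  anchors <- anchor_loss_order(ga$trajectory, ga$topology)

  trans <- split_gfp_fixture("trans", seed = seed + 2)
  gt <- generate_barrel_trajectory(trans$spec, n_frames = 1)
  orientation <- classify_orientation(get_frame(gt$trajectory, 1),
                                      gt$topology)

  wins <- generate_pathway_windows(cis$spec, centers = seq(0, 180, by = 20),
                                   n_frames = 10, thermal_noise = noise)
  pw <- pathway_profile(wins)

  ev <- design_evidence(cis_tab, trans_tab, pw, orientation, anchors)
  cand <- nominate(ev, gc$topology)

  sites <- sort(cand$residue[cand$class == "dissociation" & !cand$excluded])
  wt <- stats::setNames(aa_one(cand$name[match(sites, cand$residue)]),
                        sites)
  variants <- list(reference = name_variant(wt))
  for (combo in candidate_combinations(cand)) {
    ala <- stats::setNames(rep("A", length(combo)), combo)
    variants[[name_variant(wt, ala)]] <- combo
  }
  list(evidence = ev, candidates = cand, variants = variants,
       topology = gc$topology, wildtype = wt)
}
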