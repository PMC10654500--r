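# Independent oracles and fixture builders used across the test files.
# These re-derive results with deliberately different code paths from the
# package implementation.

# brute-force all-pairs interaction detection: plain loops, own role logic
oracle_detect <- function(frame, topo, criteria = interaction_criteria()) {
  atoms <- frame$atoms
  xyz <- frame$xyz
  n <- nrow(atoms)
  barrel <- c("7", "10", "11")
  lab <- character(n)
  for (k in seq_len(n)) {
    rn <- as.character(atoms$resno[k])
    if (atoms$resno[k] %in% topo$chromophore_residues) lab[k] <- "chromophore"
    else if (rn %in% names(topo$strand)) lab[k] <- unname(topo$strand[rn])
    else lab[k] <- "loop"
  }
  donors <- c("SER", "THR", "TYR", "CYS", "ASN", "GLN", "HIS", "LYS",
              "ARG", "TRP")
  acceptors <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "ASP", "GLU")
  pos <- c("LYS", "ARG", "HIS"); neg <- c("ASP", "GLU")
  arom <- c("PHE", "TYR", "TRP", "HIS")
  is_cro <- lab == "chromophore"
  is_don <- (atoms$atom_name == "N" & !is_cro) |
    (atoms$atom_name == "SC" & atoms$resid %in% donors) |
    (is_cro & atoms$atom_name %in% c("OH", "N2"))
  is_acc <- (atoms$atom_name == "O" & !is_cro) |
    (atoms$atom_name == "SC" & atoms$resid %in% acceptors) |
    (is_cro & atoms$atom_name %in% c("OH", "O2", "N2"))
  antecedent <- function(k) {
    nm <- switch(atoms$atom_name[k], N = "CA", O = "C", SC = "CB",
                 OH = "C5", O2 = "C4", N2 = "C3", NA_character_)
    if (is.na(nm)) return(NA_integer_)
    w <- which(atoms$resno == atoms$resno[k] & atoms$atom_name == nm)
    if (length(w) == 1) w else NA_integer_
  }
  eligible <- function(i, j) {
    a <- lab[i]; b <- lab[j]
    (a %in% barrel && b %in% barrel && a != b) ||
      xor(a == "chromophore", b == "chromophore")
  }
  ang <- function(p, q, r) {
    v1 <- p - q; v2 <- r - q
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
      180 / pi
  }
  keys <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (atoms$resno[i] == atoms$resno[j]) next
      if (!eligible(i, j)) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sc_pair <- atoms$atom_name[i] == "SC" && atoms$atom_name[j] == "SC"
      kind <- NULL
      if (sc_pair && ((atoms$resid[i] %in% pos && atoms$resid[j] %in% neg) ||
                      (atoms$resid[i] %in% neg && atoms$resid[j] %in% pos))) {
        if (d <= criteria$salt_bridge_max) kind <- "salt_bridge"
      } else if (sc_pair && atoms$resid[i] %in% arom &&
                 atoms$resid[j] %in% arom) {
        if (d <= criteria$stacking_centroid_max) {
          ai <- antecedent(i); aj <- antecedent(j)
          v1 <- xyz[i, ] - xyz[ai, ]; v2 <- xyz[j, ] - xyz[aj, ]
          a12 <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (min(a12, 180 - a12) <= criteria$stacking_plane_angle_max)
            kind <- "stacking"
        }
      } else {
        hb <- function(don, acc) {
          if (!is_don[don] || !is_acc[acc]) return(FALSE)
          if (d > criteria$hbond_da_max) return(FALSE)
          aa <- antecedent(acc)
          if (is.na(aa)) return(TRUE)
          ang(xyz[don, ], xyz[acc, ], xyz[aa, ]) >= criteria$proxy_angle_min
        }
        if (hb(i, j) || hb(j, i)) kind <- "hbond"
      }
      if (!is.null(kind)) {
        side <- function(k) {
          if (is_cro[k] || !atoms$atom_name[k] %in% c("N", "CA", "C", "O"))
            "sc" else "mc"
        }
        keys <- c(keys, strandgate:::interaction_key(
          kind, atoms$resno[i], side(i), atoms$atom_name[i],
          atoms$resno[j], side(j), atoms$atom_name[j]))
      }
    }
  }
  sort(unique(keys))
}

# brute-force RMSD minimization over rotations: coarse Euler grid + refine
oracle_min_rmsd <- function(mobile, ref) {
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  f <- function(a) {
    M <- A %*% t(rotmat(a))
    sqrt(mean(rowSums((M - B)^2)))
  }
  grid <- expand.grid(z = seq(0, 2 * pi, length.out = 13)[-13],
                      y = seq(0, pi, length.out = 7),
                      x = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, f)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# random fixture with assorted residue chemistry, for detection property tests
random_fixture <- function(seed) {
  set.seed(seed)
  pool <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "LYS", "ARG",
            "ASP", "GLU", "TRP", "PHE", "ALA")
  resnos <- c(143:154, 198:209, 214:225)
  picks <- sample(resnos, 14)
  names <- stats::setNames(sample(pool, 14, replace = TRUE),
                           as.character(picks))
  barrel_fixture_spec(residue_names = names,
                      phi_I = stats::runif(1, -180, 180),
                      seed = seed)
}

make_frame <- function(atoms, xyz) {
  structure(list(atoms = atoms, xyz = xyz, frame_index = 1L),
            class = "strand_frame")
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(9), 3)
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
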