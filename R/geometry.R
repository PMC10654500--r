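#' Wrap angles into the principal interval
#'
#' Maps angles in degrees onto `(-180, 180]`, the convention used throughout
#' the package (cis = 0 deg, trans = 180 deg).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length in `(-180, 180]`.
#' @export
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Minimal-image difference between two angles
#'
#' @param a,b angles in degrees.
#' @return signed difference `a - b` wrapped into `(-180, 180]`.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector has no direction")
  v / n
}

#' Torsion angle of four points
#'
#' IUPAC sign convention: looking from b to c, the angle is positive for a
#' clockwise rotation of the far bond. Planar trans gives 180 deg, planar cis
#' gives 0 deg.
#'
#' @param p 4x3 numeric matrix of coordinates (rows a, b, c, d).
#' @return torsion angle in degrees in `(-180, 180]`.
#' @export
torsion_angle <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 4, ncol(p) == 3)
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate geometry: coincident atoms in torsion")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Place a fourth atom d given a, b, c, a bond length |c-d|, the bond angle
# b-c-d (deg) and the torsion a-b-c-d (deg).  Standard internal-coordinate
# (NeRF) construction; used by the fixture generator.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          -length * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  ab <- b - a
  n <- unitv(c(ab[2] * bc[3] - ab[3] * bc[2],
               ab[3] * bc[1] - ab[1] * bc[3],
               ab[1] * bc[2] - ab[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  M <- cbind(bc, m, n)
  c + as.vector(M %*% d2)
}

# Kabsch least-squares rigid superposition: returns rotation R and translation
# t minimizing || (mobile %*% R + t) - ref ||.
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3)
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cr - as.vector(cm %*% R)
  list(rotation = R, translation = t)
}

angle_between <- function(u, v) {
  cosang <- sum(unitv(u) * unitv(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}
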