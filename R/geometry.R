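# Low-level vector geometry shared by the energy model, restraint builders
# and metrics. All coordinates are Angstrom, matrices are n x 3.

vcross <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vdot <- function(a, b) rowSums(a * b)

vnorm <- function(a) sqrt(rowSums(a * a))

unit1 <- function(v) v / sqrt(sum(v * v))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation \code{R} and translation \code{t} minimizing
#' the RMSD between \code{mobile \%*\% R + t} and \code{target}. Reflections
#' are excluded, so chirality is always preserved.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param target n x 3 matrix of reference coordinates, row-matched.
#' @return List with \code{R} (3 x 3 rotation), \code{t} (length-3
#'   translation), \code{moved} (transformed mobile coordinates) and
#'   \code{rmsd}.
#' @keywords internal
kabsch_fit <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target))
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- P %*% R
  moved <- sweep(moved, 2, ct, `+`)
  list(R = R, t = ct - drop(cm %*% R), moved = moved,
       rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

# internal coordinate placement (natural extension reference frame): position
# a new atom at given bond length from c, bond angle a-b-c... placed relative
# to chain ... -> a -> b -> c, torsion about b-c.
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  bc <- unit1(c - b)
  n <- unit1(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dihedral_deg <- function(p0, p1, p2, p3) {
  b1 <- p1 - p0; b2 <- p2 - p1; b3 <- p3 - p2
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  -rad2deg(atan2(sum(m * n2), sum(n1 * n2)))
}

angle_deg3 <- function(p0, p1, p2) {
  a <- p0 - p1; b <- p2 - p1
  cth <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  rad2deg(acos(max(-1, min(1, cth))))
}

# orthonormal frame from three points: origin o, x towards p2, z normal to
# the (o, p2, p3) plane. Returns list(o, R) with world = o + R %*% local.
frame_from_atoms <- function(o, p2, p3) {
  x <- unit1(p2 - o)
  z <- unit1(pracma_cross(x, p3 - o))
  y <- pracma_cross(z, x)
  list(o = o, R = cbind(x, y, z))
}

# screw decomposition of a rigid transform x -> x %*% R + t (row vectors):
# rotation axis direction u (unit), a point p on the axis, rotation angle
# (radians) and translation h along the axis
screw_axis <- function(R, t) {
  # column-vector rotation is t(R)
  Rc <- t(R)
  ang <- acos(max(-1, min(1, (sum(diag(Rc)) - 1) / 2)))
  u <- c(Rc[3, 2] - Rc[2, 3], Rc[1, 3] - Rc[3, 1], Rc[2, 1] - Rc[1, 2])
  if (sqrt(sum(u^2)) < 1e-10) {
    ev <- eigen(Rc)
    u <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  } else u <- u / sqrt(sum(u^2))
  h <- sum(t * u)
  tp <- t - h * u
  # solve (I - Rc) p = tp for p in the plane perpendicular to u
  A <- diag(3) - Rc
  p <- tryCatch(drop(MASS_ginv(A) %*% tp), error = function(e) rep(0, 3))
  list(u = u, p = p, angle = ang, h = h)
}

# small local pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(A, tol = 1e-8) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

rotation_about_axis <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  c_ * diag(3) + s_ * ux + (1 - c_) * (u %o% u)
}

ortho_vec <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}
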