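# Internal vector-geometry primitives shared across modules.
# All coordinates are plain numeric length-3 vectors or k x 3 matrices in
# Angstrom; angles are radians internally, degrees at every public surface.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(a) sqrt(sum(a * a))

# Signed dihedral of four points, IUPAC convention, radians in (-pi, pi].
# Sign matches bio3d::torsion.xyz (cross-checked in the test suite).
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  denom <- .norm3(n1) * .norm3(n2)
  if (denom < 1e-12) return(NA_real_)
  m1 <- .cross3(n1, b2)
  -atan2(sum(m1 * n2) / .norm3(b2), sum(n1 * n2))
}

# Angle p1-p2-p3 at p2, radians in [0, pi].
.angle3 <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  d <- .norm3(v1) * .norm3(v2)
  if (d < 1e-12) return(NA_real_)
  acos(max(-1, min(1, sum(v1 * v2) / d)))
}

# Optimal proper-rotation least-squares superposition (Kabsch).
# Returns list(R, t, rmsd) such that moving %*% R + t best fits `fixed`.
# Reflections are excluded so chirality is always preserved.
.kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tr <- cf - as.vector(cm %*% R)
  fit <- sweep(P %*% R, 2, cf, "+")
  list(R = R, t = tr, rmsd = sqrt(mean(rowSums((fit - fixed)^2))))
}

.apply_rigid <- function(xyz, fit) {
  sweep(xyz %*% fit$R, 2, fit$t, "+")
}

# Extend a chain of atoms by one (NeRF / internal-coordinate placement):
# place D at distance `bond` from C, angle `ang` (B-C-D, degrees) and
# dihedral `dih` (A-B-C-D, degrees).
.place_atom <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- .norm3(n)
  if (nn < 1e-10) stop("degenerate internal-coordinate frame")
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Random rigid motion (used by fixtures and property tests).
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}
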