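# Small 3D geometry helpers shared across modules.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a, eps = 1e-12) a / max(vnorm(a), eps)

#' Torsion angle (degrees) defined by four points
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural-extension-reference-frame placement: given positions a, b, c, place
# the next atom at the stated bond length from c, bond angle at c (deg) and
# torsion a-b-c-new (deg).
nerf_place <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         -length * sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d)
}

# uniform random rotation matrix (via QR of a Gaussian matrix, det forced +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply rigid transform to an n x 3 coordinate matrix
rigid_transform <- function(X, R, t) {
  sweep(X %*% t(R), 2L, t, "+")
}
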