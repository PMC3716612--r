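# Low-level 3D geometry: vectors, internal-coordinate atom placement,
# bond/angle/dihedral values and their analytic derivatives, and the
# Kabsch least-squares superposition.  Coordinates are in Angstrom,
# angles in radians unless a function name says otherwise.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle defined by three points
#'
#' Returns the angle at `b` formed by points `a`-`b`-`c`, in radians.
#' @param a,b,c numeric 3-vectors.
#' @return angle in radians in \[0, pi\].
#' @keywords internal
angle_at <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang)))
}

#' Dihedral angle defined by four points
#'
#' Signed torsion a-b-c-d using the IUPAC convention (cis = 0, sign by
#' right-hand rule about b->c).
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral in radians in (-pi, pi].
#' @keywords internal
dihedral_at <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vec_norm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given reference positions `a`, `b`, `c`, returns the position `d` with
#' |c-d| = `bond`, angle b-c-d = `angle` and dihedral a-b-c-d = `dihedral`.
#' @param a,b,c numeric 3-vectors; `c` is the atom `d` bonds to.
#' @param bond bond length in Angstrom.
#' @param angle angle in radians.
#' @param dihedral dihedral in radians.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  d2 <- bond * c(-cos(angle), sin(angle) * cos(dihedral),
                 -sin(angle) * sin(dihedral))
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d2)
}

# ---- analytic derivatives ---------------------------------------------------

# Derivative of the distance |ri - rj| w.r.t. ri is the unit vector from j to i.
dist_grad <- function(ri, rj) {
  d <- ri - rj
  r <- vec_norm(d)
  list(value = r, gi = d / r, gj = -d / r)
}

# Gradient of the angle at j (i-j-k) w.r.t. the three positions.
angle_grad <- function(ri, rj, rk) {
  u <- ri - rj
  v <- rk - rj
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  uh <- u / nu
  vh <- v / nv
  cosang <- max(-1, min(1, sum(uh * vh)))
  theta <- acos(cosang)
  sinang <- sqrt(max(1e-12, 1 - cosang^2))
  gi <- (cosang * uh - vh) / (nu * sinang)
  gk <- (cosang * vh - uh) / (nv * sinang)
  list(value = theta, gi = gi, gj = -(gi + gk), gk = gk)
}

# Gradient of the dihedral i-j-k-l w.r.t. the four positions
# (Blondel-Karplus form; validated against finite differences).
dihedral_grad <- function(ri, rj, rk, rl) {
  b1 <- rj - ri
  b2 <- rk - rj
  b3 <- rl - rk
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- vec_norm(b2)
  m1 <- cross3(n1, b2 / nb2)
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  n1sq <- sum(n1 * n1)
  n2sq <- sum(n2 * n2)
  gi <- nb2 / n1sq * n1
  gl <- -nb2 / n2sq * n2
  f1 <- sum(b1 * b2) / (nb2 * nb2)
  f3 <- sum(b3 * b2) / (nb2 * nb2)
  gj <- -(1 + f1) * gi + f3 * gl
  gk <- f1 * gi - (1 + f3) * gl
  list(value = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

# ---- rigid-body superposition ----------------------------------------------

#' Kabsch optimal superposition
#'
#' Least-squares rigid superposition of point set `P` onto `Q` (both n x 3),
#' optionally weighted.  Reflections are excluded by the determinant
#' correction, so the returned rotation is always proper.
#'
#' @param P,Q numeric matrices, n x 3, row i of P paired with row i of Q.
#' @param w optional non-negative weights of length n.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd`
#'   (weighted RMSD after superposition), and `transform(X)` applying the
#'   fit to an arbitrary m x 3 matrix.
#' @export
kabsch <- function(P, Q, w = NULL) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("need at least 3 paired points for superposition")
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  H <- t(P0 * w) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  Pfit <- sweep(P %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(sum(w * rowSums((Pfit - Q)^2)))
  list(
    R = R, t = t_vec, rmsd = rmsd,
    transform = function(X) sweep(as.matrix(X) %*% t(R), 2, t_vec, `+`)
  )
}

# Quasi-uniform points on the unit sphere (spherical Fibonacci lattice).
# Deterministic; used for surface sampling in contact-area calculations.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation matrix about a (unit) axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  a <- unit_vec(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
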