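# 3-D geometry helpers shared by the pharmacophore and pose modules.
# Coordinates are N x 3 matrices in Angstrom throughout.

vec_norm <- function(v) sqrt(sum(v^2))

# minimum Euclidean distance between two coordinate sets
min_pair_dist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# all pairwise distances between rows of a and rows of b
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# rotation matrix for a rotation by `angle` (degrees) about the axis through
# p1 -> p2 (Rodrigues)
axis_rotation <- function(p1, p2, angle) {
  k <- (p2 - p1) / vec_norm(p2 - p1)
  th <- angle * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotate the subset `idx` of xyz about the p1->p2 axis by `angle` degrees
rotate_about_bond <- function(xyz, idx, p1, p2, angle) {
  R <- axis_rotation(p1, p2, angle)
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2L, p1) %*% t(R),
                      2L, p1, `+`)
  xyz
}

# Kabsch: least-squares rigid superposition of P onto Q (both n x 3).
# Returns list(R, t) such that P %*% R + t approximates Q, plus the rmsd.
kabsch <- function(P, Q) {
  P <- matrix(P, ncol = 3L); Q <- matrix(Q, ncol = 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cq - as.vector(cp %*% R)
  fitted <- sweep(P %*% R, 2L, t, `+`)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

apply_rigid <- function(xyz, R, t) {
  sweep(matrix(xyz, ncol = 3L) %*% R, 2L, t, `+`)
}

# best-fit RMSD between two conformations of the same atom set
rmsd_fit <- function(A, B) kabsch(A, B)$rmsd

# an arbitrary (deterministic, parameterized) rigid transform for invariance
# tests and scene construction
rigid_transform <- function(xyz, angles = c(30, 45, 60), shift = c(1, -2, 3)) {
  Rx <- axis_rotation(c(0, 0, 0), c(1, 0, 0), angles[1])
  Ry <- axis_rotation(c(0, 0, 0), c(0, 1, 0), angles[2])
  Rz <- axis_rotation(c(0, 0, 0), c(0, 0, 1), angles[3])
  sweep(matrix(xyz, ncol = 3L) %*% t(Rz %*% Ry %*% Rx), 2L, shift, `+`)
}

# angle (degrees) at vertex b for points a-b-c
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}
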