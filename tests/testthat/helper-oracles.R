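# Independent brute-force oracles, kept deliberately distinct from the
# package's implementations (different algebra / decompositions).

oracle_distance <- function(a, b) {
  s <- 0
  for (k in 1:3) s <- s + (a[k] - b[k])^2
  sqrt(s)
}

oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# torsion via in-plane projections: project the outer bonds onto the plane
# perpendicular to the central bond and measure the signed angle between the
# projections in an explicit orthonormal frame.
oracle_torsion <- function(a, b, c, d) {
  e <- (c - b); e <- e / sqrt(sum(e^2))
  u <- (a - b) - sum((a - b) * e) * e
  v <- (d - c) - sum((d - c) * e) * e
  u <- u / sqrt(sum(u^2))
  # frame: x = u, y = e x u
  y <- c(e[2] * u[3] - e[3] * u[2], e[3] * u[1] - e[1] * u[3], e[1] * u[2] - e[2] * u[1])
  atan2(sum(v * y), sum(v * u)) * 180 / pi
}

# plane normal via eigen-decomposition of the covariance matrix
oracle_plane_normal <- function(pos) {
  m <- sweep(pos, 2, colMeans(pos))
  ev <- eigen(crossprod(m), symmetric = TRUE)
  ev$vectors[, 3]
}

# Horn's quaternion method for optimal superposition RMSD
oracle_superpose_rmsd <- function(fixed, moving) {
  pf <- sweep(fixed, 2, colMeans(fixed))
  pm <- sweep(moving, 2, colMeans(moving))
  S <- crossprod(pm, pf)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
              3, 3, byrow = TRUE)
  sqrt(mean(rowSums((pm %*% t(R) - pf)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}

# apply a random proper rigid motion to an n x 3 matrix (row convention)
rigid_motion <- function(pos, rot = random_rotation(), shift = stats::rnorm(3, sd = 5)) {
  sweep(pos %*% t(rot), 2, shift, `+`)
}

expect_circ_close <- function(actual, expected, tol) {
  expect_lt(abs(uoxgeom::circ_diff(actual, expected)), tol)
}
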