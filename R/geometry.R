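# Exact vector geometry on Cartesian coordinates (angstrom / degrees).
# All operations accept single positions (length-3 numeric) or n x 3 matrices
# of paired positions and are vectorized over rows.

.as_mat3 <- function(x, arg = deparse(substitute(x))) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns", arg), call. = FALSE)
    storage.mode(x) <- "double"
    return(x)
  }
  if (length(x) != 3L) stop(sprintf("'%s' must be a 3-vector or n x 3 matrix", arg), call. = FALSE)
  matrix(as.numeric(x), ncol = 3L)
}

.check_finite <- function(...) {
  for (m in list(...)) if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
}

.vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.vdot  <- function(u, v) rowSums(u * v)
.vnorm <- function(u) sqrt(rowSums(u * u))
.vunit <- function(u) u / .vnorm(u)

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' Euclidean distance between paired positions
#'
#' @param a,b positions: length-3 vectors or n x 3 matrices (angstrom).
#' @return numeric vector of distances in angstrom.
#' @export
distance <- function(a, b) {
  a <- .as_mat3(a); b <- .as_mat3(b)
  .check_finite(a, b)
  .vnorm(a - b)
}

#' Bond angle a-b-c
#'
#' Angle at vertex `b`, in degrees in \[0, 180\]. Computed via
#' `atan2(|u x v|, u.v)` which is numerically stable near 0 and 180 degrees.
#'
#' @param a,b,c positions (vertex is `b`).
#' @return angle(s) in degrees.
#' @export
angle <- function(a, b, c) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c)
  .check_finite(a, b, c)
  u <- a - b; v <- c - b
  if (any(.vnorm(u) < 1e-12) || any(.vnorm(v) < 1e-12))
    stop("zero-length arm in angle()", call. = FALSE)
  .deg(atan2(.vnorm(.vcross(u, v)), .vdot(u, v)))
}

#' Signed torsion (dihedral) angle a-b-c-d
#'
#' IUPAC sign convention: looking from `b` towards `c`, a clockwise rotation
#' of `d` relative to `a` is positive. Values lie in (-180, 180]. The torsion
#' is invariant under sequence reversal (`torsion(a,b,c,d) == torsion(d,c,b,a)`)
#' and under any proper rigid motion; it changes sign under mirror reflection.
#'
#' @param a,b,c,d positions.
#' @return signed torsion(s) in degrees in (-180, 180].
#' @export
torsion <- function(a, b, c, d) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c); d <- .as_mat3(d)
  .check_finite(a, b, c, d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  nb2 <- .vnorm(b2)
  if (any(nb2 < 1e-12)) stop("coincident central atoms in torsion()", call. = FALSE)
  if (any(.vnorm(n1) < 1e-9 * .vnorm(b1) * nb2) ||
      any(.vnorm(n2) < 1e-9 * .vnorm(b3) * nb2))
    stop("undefined torsion: three collinear atoms", call. = FALSE)
  ang <- .deg(atan2(.vdot(.vcross(n1, n2), b2 / nb2), .vdot(n1, n2)))
  ifelse(ang <= -180, ang + 360, ang)
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given reference atoms `a`, `b`, `c`, returns position `d` such that
#' `distance(c, d) == bond`, `angle(b, c, d) == ang` and
#' `torsion(a, b, c, d) == tor` (all exactly, up to floating point).
#' This is the standard natural-extension reference-frame construction used
#' to realize structures with exactly specified internal geometry; vectorized
#' over rows so whole ensembles can be built in one call.
#'
#' @param a,b,c reference positions.
#' @param bond bond length c-d in angstrom.
#' @param ang angle b-c-d in degrees.
#' @param tor torsion a-b-c-d in degrees.
#' @return position(s) `d` as an n x 3 matrix (or length-3 vector for scalar input).
#' @export
place_internal <- function(a, b, c, bond, ang, tor) {
  scalar <- !is.matrix(a) && !is.matrix(b) && !is.matrix(c)
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c)
  n <- max(nrow(a), nrow(b), nrow(c), length(bond), length(ang), length(tor))
  rep_rows <- function(m) if (nrow(m) == n) m else m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
  a <- rep_rows(a); b <- rep_rows(b); c <- rep_rows(c)
  bond <- rep_len(bond, n); th <- .rad(rep_len(ang, n)); ph <- .rad(rep_len(tor, n))
  bc <- .vunit(c - b)
  nrm <- .vunit(.vcross(b - a, bc))
  m <- .vcross(nrm, bc)
  d2 <- cbind(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  d <- c + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * nrm
  if (scalar && n == 1L) drop(d) else d
}

#' Least-squares ring plane
#'
#' Fits the plane minimizing the sum of squared out-of-plane distances over
#' at least three non-collinear atoms (total least squares via SVD of the
#' centered coordinates). The centroid is the arithmetic mean of the member
#' positions -- for an aromatic ring this is the ring midpoint *m* used in
#' X-H...pi parametrization.
#'
#' @param pos n x 3 matrix of member atom positions (n >= 3).
#' @return an object of class `ring_plane`: list with `centroid`, `normal`
#'   (unit vector; sign is arbitrary, consumers orient it as needed),
#'   `rms` (root-mean-square out-of-plane deviation, angstrom) and `atoms`.
#' @export
fit_ring_plane <- function(pos) {
  pos <- .as_mat3(pos)
  .check_finite(pos)
  if (nrow(pos) < 3L) stop("fit_ring_plane() needs >= 3 atoms", call. = FALSE)
  ctr <- colMeans(pos)
  m <- sweep(pos, 2, ctr)
  s <- svd(m, nu = 0)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300))
    stop("fit_ring_plane(): atoms are collinear", call. = FALSE)
  nrm <- s$v[, 3]
  structure(list(centroid = ctr, normal = nrm,
                 rms = sqrt(mean((m %*% nrm)^2)), atoms = pos),
            class = "ring_plane")
}

#' @export
print.ring_plane <- function(x, ...) {
  cat(sprintf("ring plane: %d atoms, centroid (%.3f, %.3f, %.3f), planarity RMS %.4f A\n",
              nrow(x$atoms), x$centroid[1], x$centroid[2], x$centroid[3], x$rms))
  invisible(x)
}

#' Acute angle between two planes
#'
#' @param p,q `ring_plane` objects (or unit normals).
#' @return tilt in degrees in \[0, 90\].
#' @export
plane_tilt <- function(p, q) {
  np <- if (inherits(p, "ring_plane")) p$normal else .vunit(.as_mat3(p))[1, ]
  nq <- if (inherits(q, "ring_plane")) q$normal else .vunit(.as_mat3(q))[1, ]
  .deg(acos(min(1, abs(sum(np * nq)))))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation + translation mapping `moving` onto `fixed`.
#' Reflections are never returned: the smallest singular direction is flipped
#' when needed, so `det(rotation) == +1` even for chiral-mismatched inputs.
#'
#' @param fixed,moving paired n x 3 coordinate matrices, n >= 3 non-collinear.
#' @return object of class `superposition`: `rotation` (3 x 3, applied as
#'   `x %*% rotation`), `translation` (length 3), `rmsd` (angstrom), `n`
#'   (atom-pair count).
#' @export
superpose <- function(fixed, moving) {
  fixed <- .as_mat3(fixed); moving <- .as_mat3(moving)
  .check_finite(fixed, moving)
  if (nrow(fixed) != nrow(moving)) stop("superpose(): unpaired coordinate sets", call. = FALSE)
  if (nrow(fixed) < 3L) stop("superpose(): need >= 3 atom pairs", call. = FALSE)
  cf <- colMeans(fixed); cm <- colMeans(moving)
  pf <- sweep(fixed, 2, cf); pm <- sweep(moving, 2, cm)
  if (svd(pm, nu = 0)$d[2] < 1e-9) stop("superpose(): degenerate (collinear) geometry", call. = FALSE)
  s <- svd(crossprod(pm, pf))
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cf - drop(cm %*% rot)
  moved <- pm %*% rot
  structure(list(rotation = rot, translation = tr,
                 rmsd = sqrt(mean(rowSums((moved - pf)^2))), n = nrow(fixed)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atom pairs: RMSD %.3f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sp `superposition` object.
#' @param pos positions to transform.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, pos) {
  pos <- .as_mat3(pos)
  sweep(pos %*% sp$rotation, 2, sp$translation, `+`)
}

#' Main-chain RMSD between two structure models
#'
#' Pairs residues by (chain, author residue number, insertion code) and atoms
#' N, CA, C, O by name; missing atoms are dropped pairwise; for alternate
#' conformations the highest-occupancy location is used. Superposition is
#' performed before the RMSD ("common main-chain atoms" implies pair-then-fit).
#'
#' @param a,b `structure_model` objects (frame 1 is used).
#' @param atoms main-chain atom names to pair.
#' @return object of class `mainchain_rmsd`: `rmsd` (angstrom), `n_pairs`,
#'   and the underlying `superposition`.
#' @export
mainchain_rmsd <- function(a, b, atoms = c("N", "CA", "C", "O")) {
  key_tab <- function(m) {
    at <- m$atoms
    keep <- at$name %in% atoms
    at <- at[keep, , drop = FALSE]
    xyz <- coords(m, frame = 1L)[keep, , drop = FALSE]
    key <- paste(at$chain, at$resno, at$inscode, at$name, sep = "|")
    # highest-occupancy altloc per key
    ord <- order(key, -at$occupancy)
    first <- !duplicated(key[ord])
    list(key = key[ord][first], xyz = xyz[ord, , drop = FALSE][first, , drop = FALSE])
  }
  ta <- key_tab(a); tb <- key_tab(b)
  common <- intersect(ta$key, tb$key)
  if (length(common) < 3L) stop("mainchain_rmsd(): no common main-chain atoms", call. = FALSE)
  pa <- ta$xyz[match(common, ta$key), , drop = FALSE]
  pb <- tb$xyz[match(common, tb$key), , drop = FALSE]
  sp <- superpose(pa, pb)
  structure(list(rmsd = sp$rmsd, n_pairs = length(common), superposition = sp),
            class = "mainchain_rmsd")
}

#' @export
print.mainchain_rmsd <- function(x, ...) {
  cat(sprintf("main-chain RMSD %.3f A over %d atom pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}
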