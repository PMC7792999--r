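# Periodic kernel density estimation for torsion angles: von Mises kernels
# on the circle (1D) and product-von-Mises kernels on the torus (2D).
# Densities are per-degree (1D) / per-square-degree (2D), renormalized on the
# grid so that sum(density) * bin measure == 1 exactly.

.circ_grid <- function(step) seq(-180 + step, 180, by = step) - step / 2

.bin_index <- function(x, step) {
  nbin <- as.integer(round(360 / step))
  (as.integer(round((wrap_deg(x) + 180 - step / 2) / step)) %% nbin) + 1L
}

#' 1D circular kernel density of a torsion series
#'
#' von Mises kernel density on a regular periodic grid covering the full
#' circle. For large samples the data are binned on the grid and convolved
#' with the kernel by circular FFT; for small samples the kernel sum is
#' evaluated exactly. The result is renormalized on the grid.
#'
#' @param x angles in degrees (a numeric vector or a `torsion_series`).
#' @param concentration kernel concentration; default: Taylor plug-in rule
#'   ([kappa_plugin()]).
#' @param grid_step grid spacing in degrees (default 1).
#' @return object of class `circular_density`: `grid` (bin centers, degrees),
#'   `density` (per degree), `concentration`, `n`, `ndim = 1`.
#' @export
circular_density_1d <- function(x, concentration = NULL, grid_step = 1) {
  if (inherits(x, "torsion_series")) x <- x$values
  if (!length(x)) stop("need >= 1 observation", call. = FALSE)
  if (!is.null(concentration) && concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  nu <- if (is.null(concentration)) kappa_plugin(x) else concentration
  grid <- .circ_grid(grid_step)
  nbin <- length(grid)
  n <- length(x)
  if (n * nbin <= 4e6) {
    dens <- rowMeans(dvonmises(outer(grid, x, `-`), 0, nu))
  } else {
    counts <- tabulate(.bin_index(x, grid_step), nbins = nbin)
    kern <- dvonmises(wrap_deg((seq_len(nbin) - 1L) * grid_step), 0, nu)
    dens <- Re(stats::fft(stats::fft(counts) * stats::fft(kern), inverse = TRUE)) / (nbin * n)
  }
  dens <- pmax(dens, 0)
  dens <- dens / (sum(dens) * grid_step)
  structure(list(grid = grid, density = dens, concentration = nu, n = n, ndim = 1L),
            class = "circular_density")
}

#' 2D toroidal kernel density of a torsion-angle pair
#'
#' Product von Mises kernel on a (grid x grid) torus, computed by binning
#' and 2D circular FFT convolution; periodic in both axes.
#'
#' @param a,b paired angle series in degrees (vectors or `torsion_series`).
#' @param concentration length-2 kernel concentrations (default: per-axis
#'   plug-in rule).
#' @param grid_step grid spacing in degrees (default 1).
#' @return object of class `circular_density` with `ndim = 2`: `grid` (shared
#'   axis bin centers) and `density` (matrix, per square degree; rows = axis
#'   `a`, columns = axis `b`).
#' @export
torsion_density_2d <- function(a, b, concentration = NULL, grid_step = 1) {
  if (inherits(a, "torsion_series")) a <- a$values
  if (inherits(b, "torsion_series")) b <- b$values
  if (length(a) != length(b)) stop("series length mismatch", call. = FALSE)
  if (!length(a)) stop("need >= 1 observation", call. = FALSE)
  nu <- if (is.null(concentration)) c(kappa_plugin(a), kappa_plugin(b))
        else rep_len(concentration, 2L)
  if (any(nu <= 0)) stop("concentration must be > 0", call. = FALSE)
  grid <- .circ_grid(grid_step)
  nbin <- length(grid)
  n <- length(a)
  counts <- matrix(0, nbin, nbin)
  idx <- cbind(.bin_index(a, grid_step), .bin_index(b, grid_step))
  tab <- table(factor(idx[, 1], levels = seq_len(nbin)),
               factor(idx[, 2], levels = seq_len(nbin)))
  counts[] <- as.numeric(tab)
  off <- wrap_deg((seq_len(nbin) - 1L) * grid_step)
  kern <- outer(dvonmises(off, 0, nu[1]), dvonmises(off, 0, nu[2]))
  dens <- Re(stats::fft(stats::fft(counts) * stats::fft(kern), inverse = TRUE)) /
    (nbin^2 * n)
  dens <- pmax(dens, 0)
  dens <- dens / (sum(dens) * grid_step^2)
  structure(list(grid = grid, density = dens, concentration = nu, n = n, ndim = 2L),
            class = "circular_density")
}

#' @export
print.circular_density <- function(x, ...) {
  cat(sprintf("%dD circular density: %d grid points/axis, kernel concentration %s, n = %d\n",
              x$ndim, length(x$grid), paste(signif(x$concentration, 4), collapse = "/"),
              x$n))
  invisible(x)
}

#' Local maxima of a circular density
#'
#' Strict local maxima on the periodic grid, sorted by density (descending;
#' ties broken by angle ascending). A flat (e.g. uniform) density has no
#' strict mode and is flagged via the `flat` attribute.
#'
#' @param d a 1D `circular_density`.
#' @return data.frame with columns `angle` (degrees) and `density`, with
#'   attribute `flat = TRUE` when no strict mode exists.
#' @export
density_modes <- function(d) {
  stopifnot(inherits(d, "circular_density"), d$ndim == 1L)
  v <- d$density
  nb <- length(v)
  up <- v[c(2:nb, 1)]; dn <- v[c(nb, 1:(nb - 1))]
  is_mode <- v > up & v > dn
  out <- data.frame(angle = d$grid[is_mode], density = v[is_mode])
  out <- out[order(-out$density, out$angle), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flat") <- nrow(out) == 0L
  out
}
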