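# Density-peak clustering of torsion-angle pairs on the torus. Clusters are
# the basins of attraction of local maxima of the smoothed toroidal density
# (peaks above a configurable floor); frames are assigned by steepest ascent
# on the density grid. Seedless and deterministic.

.torus_shift <- function(m, di, dj) {
  n <- nrow(m)
  m[((seq_len(n) - 1L + di) %% n) + 1L, ((seq_len(n) - 1L + dj) %% n) + 1L]
}

#' Cluster a torsion-angle pair series on the torus
#'
#' Computes the 2D toroidal kernel density of the pair, finds density peaks
#' above `peak_floor` (a fraction of the maximum density), and assigns every
#' grid cell to the peak reached by steepest ascent over its 8-neighborhood
#' (with torus wrap-around). Frames inherit the label of their grid cell;
#' frames whose cell density falls below `assign_floor` x max are left
#' unassigned (label 0). Cluster centers are the circular means of member
#' frames. Deterministic; clusters are numbered by decreasing population.
#'
#' @param a,b paired angle series in degrees (vectors or `torsion_series`).
#' @param concentration,grid_step passed to [torsion_density_2d()].
#' @param peak_floor minimum peak height as a fraction of the density maximum.
#' @param assign_floor cells below this fraction of the maximum are unassigned.
#' @return object of class `torsion_clusters`: `clusters` (data.frame with
#'   `cluster`, `center_a`, `center_b`, `peak_a`, `peak_b`, `fraction`),
#'   `labels` (per frame; 0 = unassigned), and the `density` object.
#' @export
cluster_torsions_2d <- function(a, b, concentration = NULL, grid_step = 1,
                                peak_floor = 0.05, assign_floor = 0) {
  if (inherits(a, "torsion_series")) a <- a$values
  if (inherits(b, "torsion_series")) b <- b$values
  if (length(unique(paste(a, b))) == 1L) {
    # degenerate: all frames identical -> a single cluster at that point
    cl <- data.frame(cluster = 1L, center_a = wrap_deg(a[1]), center_b = wrap_deg(b[1]),
                     peak_a = wrap_deg(a[1]), peak_b = wrap_deg(b[1]), fraction = 1)
    return(structure(list(clusters = cl, labels = rep(1L, length(a)), density = NULL),
                     class = "torsion_clusters"))
  }
  d <- torsion_density_2d(a, b, concentration = concentration, grid_step = grid_step)
  dens <- d$density
  nb <- nrow(dens)
  # steepest-ascent pointer for every cell over its 8 torus neighbors
  best <- dens
  ptr <- matrix(seq_len(nb * nb), nb, nb)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbr <- .torus_shift(dens, di, dj)
    nbr_idx <- .torus_shift(matrix(seq_len(nb * nb), nb, nb), di, dj)
    upd <- nbr > best
    best[upd] <- nbr[upd]
    ptr[upd] <- nbr_idx[upd]
  }
  # pointer jumping to basin roots
  p <- as.integer(ptr)
  repeat {
    p2 <- p[p]
    if (identical(p2, p)) break
    p <- p2
  }
  roots <- unique(p)
  peak_ok <- dens[roots] >= peak_floor * max(dens)
  keep <- roots[peak_ok]
  if (!length(keep)) keep <- roots[which.max(dens[roots])]
  # basins of suppressed minor peaks are merged into the nearest kept peak
  if (length(keep) < length(roots)) {
    gi <- ((roots - 1L) %% nb) + 1L; gj <- ((roots - 1L) %/% nb) + 1L
    ki <- ((keep - 1L) %% nb) + 1L; kj <- ((keep - 1L) %/% nb) + 1L
    remap <- vapply(seq_along(roots), function(r) {
      if (roots[r] %in% keep) return(roots[r])
      dd <- circ_diff(d$grid[gi[r]], d$grid[ki])^2 + circ_diff(d$grid[gj[r]], d$grid[kj])^2
      keep[which.min(dd)]
    }, integer(1))
    p <- remap[match(p, roots)]
  }
  # frames -> cells -> roots
  fi <- .bin_index(a, grid_step); fj <- .bin_index(b, grid_step)
  cell <- (fj - 1L) * nb + fi
  lab_root <- p[cell]
  unass <- dens[cell] < assign_floor * max(dens)
  counts <- table(factor(lab_root[!unass], levels = keep))
  ord <- order(-as.integer(counts))
  keep <- keep[ord]
  labels <- match(lab_root, keep)
  labels[unass] <- 0L
  labels[is.na(labels)] <- 0L
  centers <- t(vapply(seq_along(keep), function(k) {
    sel <- labels == k
    c(circ_mean(a[sel]), circ_mean(b[sel]))
  }, numeric(2)))
  cl <- data.frame(cluster = seq_along(keep),
                   center_a = centers[, 1], center_b = centers[, 2],
                   peak_a = d$grid[((keep - 1L) %% nb) + 1L],
                   peak_b = d$grid[((keep - 1L) %/% nb) + 1L],
                   fraction = as.numeric(table(factor(labels, levels = seq_along(keep)))) /
                     length(labels))
  structure(list(clusters = cl, labels = labels, density = d),
            class = "torsion_clusters")
}

#' @export
print.torsion_clusters <- function(x, ...) {
  cat(sprintf("%d torsion cluster(s) over %d frames (%.1f%% assigned)\n",
              nrow(x$clusters), length(x$labels), 100 * mean(x$labels > 0)))
  print(x$clusters, digits = 4)
  invisible(x)
}
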