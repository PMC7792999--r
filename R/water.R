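# Radial (r, theta) water-site coordinates and residence analysis.
# r = distance from the ligand C5 to the water oxygen; theta = torsion
# C4-C5-Ow-midpoint(H1, H2), which places the water H-midpoint relative to
# the ligand frame. The "peroxo hole" residence criterion is r <= threshold.

#' Radial water-site coordinates over ensemble frames
#'
#' @param ensemble a [structure_model()].
#' @param c4,c5 ligand atom roles (`"chain:resno:name"` or selection strings).
#' @param o,h1,h2 water atom roles; both hydrogens are required (no
#'   heavy-atom fallback: the H-midpoint defines theta).
#' @return data.frame of class `water_site_coords`: `frame`, `r` (angstrom),
#'   `theta` (degrees on (-180, 180]).
#' @export
water_site_coordinates <- function(ensemble, c4, c5, o, h1, h2) {
  roles <- c(c4 = c4, c5 = c5, o = o, h1 = h1, h2 = h2)
  idx <- vapply(roles, function(r) .resolve_role(ensemble, r), integer(1))
  p_c4 <- t(ensemble$xyz[idx["c4"], , , drop = TRUE])
  p_c5 <- t(ensemble$xyz[idx["c5"], , , drop = TRUE])
  p_o  <- t(ensemble$xyz[idx["o"],  , , drop = TRUE])
  mid  <- (t(ensemble$xyz[idx["h1"], , , drop = TRUE]) +
           t(ensemble$xyz[idx["h2"], , , drop = TRUE])) / 2
  if (n_frames(ensemble) == 1L) {
    p_c4 <- matrix(p_c4, 1); p_c5 <- matrix(p_c5, 1)
    p_o <- matrix(p_o, 1); mid <- matrix(mid, 1)
  }
  out <- data.frame(frame = seq_len(n_frames(ensemble)),
                    r = distance(p_c5, p_o),
                    theta = torsion(p_c4, p_c5, p_o, mid))
  class(out) <- c("water_site_coords", "data.frame")
  out
}

#' Residence trace of a water site
#'
#' Classifies each frame as inside (`r <= r_threshold`) or outside the
#' peroxo hole and summarizes occupancy and dwell segments.
#'
#' @param coords a `water_site_coords` data.frame (or any data.frame with an
#'   `r` column).
#' @param r_threshold residence threshold in angstrom (default 4.0, sitting
#'   between the in-hole and displaced distance ranges).
#' @return object of class `residence_trace`: `inside` (logical per frame),
#'   `r_threshold`, `occupancy` (mean of `inside`), `segments` (data.frame
#'   `state`, `length`), `mean_inside_segment` (frames).
#' @export
residence_trace <- function(coords, r_threshold = 4.0) {
  if (r_threshold <= 0) stop("r_threshold must be > 0", call. = FALSE)
  r <- coords$r
  if (!length(r)) stop("need >= 1 frame", call. = FALSE)
  inside <- r <= r_threshold
  seg <- rle(inside)
  segments <- data.frame(state = ifelse(seg$values, "in", "out"), length = seg$lengths)
  structure(list(inside = inside, r_threshold = r_threshold,
                 occupancy = mean(inside), segments = segments,
                 mean_inside_segment = if (any(seg$values))
                   mean(seg$lengths[seg$values]) else NA_real_),
            class = "residence_trace")
}

#' @export
print.residence_trace <- function(x, ...) {
  cat(sprintf("residence trace: occupancy %.3f at r <= %.2f A (%d frames, mean in-segment %.1f)\n",
              x$occupancy, x$r_threshold, length(x$inside), x$mean_inside_segment))
  invisible(x)
}

#' Coupling between conformational clusters and water residence
#'
#' Cross-tabulates the in/out residence state against per-frame cluster
#' labels and reports the 2 x 2 odds ratio (reference cluster vs the rest)
#' and Cramer's V over the full 2 x k table. A zero cell makes the odds
#' ratio infinite; this is reported and flagged as degenerate rather than
#' continuity-corrected.
#'
#' @param labels per-frame cluster labels (0 = unassigned, dropped).
#' @param trace a [residence_trace()] over the same frames.
#' @param reference cluster treated as the 2 x 2 reference (default: the most
#'   populous label).
#' @return object of class `state_coupling`: `table` (in/out x cluster),
#'   `odds_ratio`, `cramers_v`, `reference`, `degenerate`.
#' @export
state_coupling <- function(labels, trace, reference = NULL) {
  stopifnot(inherits(trace, "residence_trace"))
  if (length(labels) != length(trace$inside))
    stop("labels and residence trace cover different frame sets", call. = FALSE)
  keep <- labels > 0
  if (!any(keep)) stop("no assigned frames in common", call. = FALSE)
  lab <- labels[keep]
  inside <- factor(ifelse(trace$inside[keep], "in", "out"), levels = c("in", "out"))
  tab <- table(residence = inside, cluster = lab)
  if (is.null(reference)) reference <- as.integer(names(which.max(table(lab))))
  ref <- factor(ifelse(lab == reference, "ref", "other"), levels = c("ref", "other"))
  t22 <- table(inside, ref)
  or <- (t22["in", "ref"] * t22["out", "other"]) /
        (t22["in", "other"] * t22["out", "ref"])
  v <- if (ncol(tab) >= 2L && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    sqrt(chi$statistic / (sum(tab) * (min(dim(tab)) - 1)))
  } else NA_real_
  structure(list(table = tab, odds_ratio = as.numeric(or),
                 cramers_v = as.numeric(v), reference = reference,
                 degenerate = !is.finite(or) || or == 0),
            class = "state_coupling")
}

#' @export
print.state_coupling <- function(x, ...) {
  cat(sprintf("residence/cluster coupling: odds ratio %.3g (reference cluster %s), Cramer's V %.3f%s\n",
              x$odds_ratio, x$reference, x$cramers_v,
              if (x$degenerate) " [degenerate: zero cell]" else ""))
  print(x$table)
  invisible(x)
}
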