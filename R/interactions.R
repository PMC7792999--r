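# Hydrogen-bond and X-H...pi contact detection and the active-site geometry
# report. Deuterium (element "D") plays every hydrogen role; it is chemically
# hydrogen and is never renamed.

.is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

#' Default hydrogen-bond criteria
#'
#' d(H...A) <= 2.5 angstrom and angle(D-H...A) >= 120 degrees: common
#' practice for neutron structures with resolved H/D positions. Fully
#' configurable; every report echoes the criteria used.
#' @export
hbond_criteria <- function(max_d_ha = 2.5, min_angle = 120)
  list(max_d_ha = max_d_ha, min_angle = min_angle)

#' Default X-H...pi classification thresholds
#'
#' d(X...m) <= 4.3 angstrom, omega(X) <= 30 degrees, angle(X-H...m) >= 120
#' degrees, bracketing the geometries commonly tabulated for N-H/O-H...pi
#' interactions in proteins. Configuration, not ground truth.
#' @export
pi_thresholds <- function(max_d_xm = 4.3, max_omega = 30, min_angle = 120)
  list(max_d_xm = max_d_xm, max_omega = max_omega, min_angle = min_angle)

#' Detect hydrogen bonds
#'
#' Explicit-hydrogen geometric criterion: for every hydrogen (H or D)
#' covalently bonded to a heavy donor (within `covalent_max`), every
#' acceptor atom (N, O by default) outside the donor residue with
#' d(H...A) <= `criteria$max_d_ha` and angle(donor-H...A) >=
#' `criteria$min_angle` is reported. Donors without an attached hydrogen are
#' skipped. Output is sorted by d(H...A) and is independent of atom order.
#'
#' @param model a [structure_model()] (frame 1 is analyzed).
#' @param criteria see [hbond_criteria()].
#' @param donor_sel,acceptor_sel optional selection expressions restricting
#'   the donor-side hydrogens and the acceptors.
#' @param acceptor_elements elements allowed as acceptors.
#' @param covalent_max maximum covalent D-H bond length (angstrom).
#' @param frame frame index.
#' @return data.frame of class `hbond_set`: one row per bond with donor,
#'   hydrogen and acceptor identifiers, `d_ha`, `d_da` and `angle_dha`.
#' @export
detect_hbonds <- function(model, criteria = hbond_criteria(),
                          donor_sel = NULL, acceptor_sel = NULL,
                          acceptor_elements = c("N", "O"),
                          covalent_max = 1.3, frame = 1L) {
  at <- model$atoms
  xyz <- coords(model, frame)
  lab <- function(i) sprintf("%s/%s%d%s/%s%s", at$chain[i], at$resname[i], at$resno[i],
                             at$inscode[i], at$name[i],
                             ifelse(nzchar(at$altloc[i]), paste0(".", at$altloc[i]), ""))
  hyd <- which(.is_hydrogen(at$element))
  if (!is.null(donor_sel)) hyd <- intersect(hyd, select_atoms(model, donor_sel))
  acc <- which(toupper(at$element) %in% acceptor_elements)
  if (!is.null(acceptor_sel)) acc <- intersect(acc, select_atoms(model, acceptor_sel))
  heavy <- which(!.is_hydrogen(at$element))
  res_id <- paste(at$chain, at$resno, at$inscode, sep = "|")
  rows <- list()
  for (h in hyd) {
    # covalent donor: nearest heavy atom in the same residue within reach
    cand <- heavy[res_id[heavy] == res_id[h]]
    if (!length(cand)) next
    dd <- distance(xyz[rep(h, length(cand)), , drop = FALSE], xyz[cand, , drop = FALSE])
    if (min(dd) > covalent_max) {
      message("detect_hbonds: hydrogen ", lab(h), " has no covalent donor; skipped")
      next
    }
    don <- cand[which.min(dd)]
    # altloc consistency: donor and hydrogen must share a conformer
    if (nzchar(at$altloc[h]) && nzchar(at$altloc[don]) && at$altloc[h] != at$altloc[don])
      next
    a_ok <- acc[res_id[acc] != res_id[h]]
    if (!length(a_ok)) next
    dha <- distance(xyz[rep(h, length(a_ok)), , drop = FALSE], xyz[a_ok, , drop = FALSE])
    hit <- a_ok[dha <= criteria$max_d_ha]
    for (a in hit) {
      ang <- angle(xyz[don, ], xyz[h, ], xyz[a, ])
      if (ang < criteria$min_angle) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = lab(don), hydrogen = lab(h), acceptor = lab(a),
        d_ha = distance(xyz[h, ], xyz[a, ]),
        d_da = distance(xyz[don, ], xyz[a, ]),
        angle_dha = ang, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = character(), hydrogen = character(), acceptor = character(),
               d_ha = numeric(), d_da = numeric(), angle_dha = numeric())
  out <- out[order(out$d_ha, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  class(out) <- c("hbond_set", "data.frame")
  out
}

#' Characterize an X-H...pi contact
#'
#' Computes the classical parametrization of a hydrogen bond to an aromatic
#' ring face: `d_xm` -- distance from the donor heavy atom X to the ring
#' midpoint m; `omega` -- acute angle between the X...m line and the ring
#' normal; `angle_xhm` -- the X-H...m angle at the hydrogen.
#'
#' @param x_pos donor heavy-atom position.
#' @param h_pos hydrogen position (must be within `covalent_max` of X).
#' @param ring_pos >= 3 ring atom positions (n x 3 matrix).
#' @param covalent_max maximum covalent X-H distance (angstrom).
#' @return object of class `pi_contact`: `d_xm`, `omega`, `angle_xhm`,
#'   `ring` (the fitted [fit_ring_plane()]), `passes` (NA until classified).
#' @export
characterize_pi_contact <- function(x_pos, h_pos, ring_pos, covalent_max = 1.3) {
  if (distance(x_pos, h_pos) > covalent_max)
    stop("characterize_pi_contact(): H is not bonded to X (d > ",
         covalent_max, " A)", call. = FALSE)
  ring <- fit_ring_plane(ring_pos)
  xm <- ring$centroid - as.numeric(x_pos)
  d_xm <- sqrt(sum(xm^2))
  if (d_xm <= 0) stop("donor coincides with ring midpoint", call. = FALSE)
  cosw <- abs(sum(xm / d_xm * ring$normal))          # acute by construction
  omega <- .deg(acos(min(1, cosw)))
  structure(list(d_xm = d_xm, omega = omega,
                 angle_xhm = angle(x_pos, h_pos, ring$centroid),
                 ring = ring, x_pos = as.numeric(x_pos), h_pos = as.numeric(h_pos),
                 passes = NA),
            class = "pi_contact")
}

#' @export
print.pi_contact <- function(x, ...) {
  cat(sprintf("X-H...pi contact: d(X...m) %.2f A, omega(X) %.1f deg, angle(X-H...m) %.0f deg%s\n",
              x$d_xm, x$omega, x$angle_xhm,
              if (is.na(x$passes)) "" else if (x$passes) " [classified: yes]" else " [classified: no]"))
  invisible(x)
}

#' Classify an X-H...pi contact against thresholds
#'
#' Pure predicate; monotone in each threshold (relaxing any threshold never
#' flips a passing contact to failing).
#'
#' @param contact a [characterize_pi_contact()] result.
#' @param thresholds see [pi_thresholds()].
#' @return logical.
#' @export
classify_pi_contact <- function(contact, thresholds = pi_thresholds()) {
  stopifnot(inherits(contact, "pi_contact"))
  contact$d_xm <= thresholds$max_d_xm &&
    contact$omega <= thresholds$max_omega &&
    contact$angle_xhm >= thresholds$min_angle
}
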