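# Synthetic conformational ensembles: torsion channels drawn from von Mises
# mixtures, a 2-state (major/minor) Markov chain for the Pro253-Lys255-like
# conformational switch, and a water position coupled to the discrete state.
# Frames are realized as actual 3D coordinates (anchor atoms + exact internal
# -coordinate placement), so the analysis path is exercised end-to-end.

#' Specification of a synthetic ensemble
#'
#' Defaults are the study conditions the analysis targets: the Thr-like
#' hydroxyl torsion follows the broad asymmetric profile with a dominant
#' mode at -72 deg and a smaller shoulder at -135 deg (weights 0.8/0.2); the
#' Asn-like (chi1, chi2) pair samples four clusters, two of them at the
#' crystallographic major (179, 192) and minor (272, 81) rotamers, with the
#' cluster weights coupled to the discrete state; the water site follows the
#' state: major -- r ~ N(3.6, 0.2^2) A with a narrow dihedral distribution
#' centred at 10 deg; minor -- r ~ N(4.3, 0.15^2) A (displaced from the
#' peroxo hole) with a broader dihedral distribution centred at 240 deg
#' (225-255 band). The state chain has persistence 0.99 for the major state
#' with stationary major fraction 0.75 (the crystallographic 75:25 ratio).
#'
#' @param n number of frames.
#' @param seed RNG seed (all randomness flows through one seeded generator).
#' @param thr_components data.frame (`weight`, `mean`, `kappa`) for the
#'   Thr-like torsion mixture.
#' @param asn_components data.frame (`mean1`, `mean2`, `kappa`, `w_major`,
#'   `w_minor`): component centers (degrees) of the (chi1, chi2) pair and
#'   their per-state weights (each weight column sums to 1).
#' @param p_major_to_minor,p_minor_to_major Markov transition probabilities.
#' @param water_major,water_minor lists (`r_mean`, `r_sd`, `theta_mean`,
#'   `theta_kappa`) for the state-coupled water distribution.
#' @param noise_sd isotropic Gaussian jitter applied to anchor atoms (A).
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n = 1000, seed = 1,
                          thr_components = data.frame(weight = c(0.8, 0.2),
                                                      mean = c(-72, -135),
                                                      kappa = c(8, 15)),
                          asn_components = data.frame(mean1 = c(179, 272, 60, 300),
                                                      mean2 = c(192, 81, 300, 170),
                                                      kappa = 50,
                                                      w_major = c(0.70, 0.00, 0.15, 0.15),
                                                      w_minor = c(0.00, 0.90, 0.05, 0.05)),
                          p_major_to_minor = 0.01, p_minor_to_major = 0.03,
                          water_major = list(r_mean = 3.6, r_sd = 0.2,
                                             theta_mean = 10, theta_kappa = 45),
                          water_minor = list(r_mean = 4.3, r_sd = 0.15,
                                             theta_mean = 240, theta_kappa = 14),
                          noise_sd = 0.02) {
  stopifnot(n >= 1,
            abs(sum(thr_components$weight) - 1) < 1e-9,
            abs(sum(asn_components$w_major) - 1) < 1e-9,
            abs(sum(asn_components$w_minor) - 1) < 1e-9,
            p_major_to_minor >= 0, p_major_to_minor <= 1,
            p_minor_to_major >= 0, p_minor_to_major <= 1)
  structure(list(n = as.integer(n), seed = seed,
                 thr_components = thr_components, asn_components = asn_components,
                 p_major_to_minor = p_major_to_minor,
                 p_minor_to_major = p_minor_to_major,
                 water_major = water_major, water_minor = water_minor,
                 noise_sd = noise_sd),
            class = "ensemble_spec")
}

#' Sample angles from a von Mises mixture
#'
#' @param components data.frame with columns `weight`, `mean` (degrees),
#'   `kappa`.
#' @param n sample size.
#' @param seed optional seed (omit to use the current RNG state).
#' @return angles in degrees on (-180, 180].
#' @export
sample_torsion_mixture <- function(components, n, seed = NULL) {
  if (!nrow(components)) stop("empty component table", call. = FALSE)
  if (abs(sum(components$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE, prob = components$weight)
  out <- numeric(n)
  for (k in seq_len(nrow(components))) {
    idx <- comp == k
    if (any(idx)) out[idx] <- rvonmises(sum(idx), components$mean[k], components$kappa[k])
  }
  attr(out, "component") <- comp
  out
}

.markov_states <- function(n, a, b) {
  # 2-state chain: 1 = major, 2 = minor; started from the stationary law
  stat_major <- if (a + b > 0) b / (a + b) else 1
  s <- integer(n)
  u <- stats::runif(n)
  s[1] <- if (u[1] < stat_major) 1L else 2L
  if (n > 1L) for (i in 2:n)
    s[i] <- if (s[i - 1] == 1L) (if (u[i] < a) 2L else 1L) else (if (u[i] < b) 1L else 2L)
  s
}

#' Generate a synthetic conformational ensemble
#'
#' Realizes an [ensemble_spec()] as a multi-frame [structure_model()] whose
#' per-frame 3D coordinates encode the sampled torsions and water-site
#' coordinates exactly (anchor atoms are jittered first, dependent atoms are
#' then placed from exact internal coordinates), plus a per-frame manifest of
#' the ground truth.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `model` (frames as a [structure_model()]) and `manifest`
#'   (data.frame: `frame`, `state` (`"major"`/`"minor"`), `asn_component`,
#'   `thr_torsion`, `asn_chi1`, `asn_chi2`, `water_r`, `water_theta`).
#' @export
generate_ensemble <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n <- spec$n

  state <- .markov_states(n, spec$p_major_to_minor, spec$p_minor_to_major)
  is_min <- state == 2L

  # per-frame ground-truth draws
  thr_t <- sample_torsion_mixture(spec$thr_components, n)
  ac <- spec$asn_components
  comp <- integer(n)
  if (any(!is_min)) comp[!is_min] <- sample.int(nrow(ac), sum(!is_min), replace = TRUE,
                                                prob = ac$w_major)
  if (any(is_min)) comp[is_min] <- sample.int(nrow(ac), sum(is_min), replace = TRUE,
                                              prob = ac$w_minor)
  chi1 <- chi2 <- numeric(n)
  for (k in seq_len(nrow(ac))) {
    idx <- comp == k
    if (!any(idx)) next
    chi1[idx] <- rvonmises(sum(idx), ac$mean1[k], ac$kappa[k])
    chi2[idx] <- rvonmises(sum(idx), ac$mean2[k], ac$kappa[k])
  }
  wr <- wth <- numeric(n)
  for (st in 1:2) {
    w <- if (st == 1) spec$water_major else spec$water_minor
    idx <- state == st
    if (!any(idx)) next
    wr[idx] <- pmax(stats::rnorm(sum(idx), w$r_mean, w$r_sd), 1.5)
    wth[idx] <- rvonmises(sum(idx), w$theta_mean, w$theta_kappa)
  }
  spin <- stats::runif(n, 0, 360)

  # anchor coordinates from the toy site scaffold
  toy <- build_toy_active_site(toy_site_spec())
  tat <- toy$model$atoms
  txyz <- coords(toy$model)
  pick <- function(resname, name, alt = "") {
    i <- which(tat$resname == resname & tat$name == name & tat$altloc %in% c("", alt))
    txyz[i[1], ]
  }
  anchors <- list(
    lig = lapply(c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "N8", "N9", "D9"),
                 function(nm) pick("AZA", nm)),
    thr = lapply(c("CA", "CB", "OG1"), function(nm) pick("THR", nm)),
    asn = lapply(c("N", "CA", "CB"), function(nm) pick("ASN", nm)))
  lig_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "N8", "N9", "D9")

  jit <- function(p) matrix(p, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3L * n, 0, spec$noise_sd), n, 3)
  A <- c(lapply(anchors$lig, jit), lapply(anchors$thr, jit), lapply(anchors$asn, jit))
  names(A) <- c(lig_names, paste0("thr_", c("CA", "CB", "OG1")),
                paste0("asn_", c("N", "CA", "CB")))

  # dependent atoms realize the sampled internal coordinates exactly
  dg1 <- place_internal(A$thr_CA, A$thr_CB, A$thr_OG1, .WATER_OH, 109.47, thr_t)
  cg <- place_internal(A$asn_N, A$asn_CA, A$asn_CB, 1.52, 113, chi1)
  nd2 <- place_internal(A$asn_CA, A$asn_CB, cg, 1.33, 116, chi2)
  od1 <- place_internal(A$asn_CA, A$asn_CB, cg, 1.23, 121, wrap_deg(chi2 + 180))
  pl <- toy_site_spec()$placement
  ow <- place_internal(A$N3, A$C4, A$C5, wr, pl$ang_c4c5o, pl$tor_n3c4c5o)
  wmid <- place_internal(A$C4, A$C5, ow, .WATER_DMID, pl$ang_c5_o_mid, wth)
  u <- .vunit(wmid - ow)
  w0 <- A$C5 - ow; w0 <- .vunit(w0 - .vdot(w0, u) * u)
  sp <- .rad(spin)
  v <- w0 * cos(sp) + .vcross(u, w0) * sin(sp)
  half <- .rad(.WATER_HOH / 2)
  h1 <- ow + .WATER_OH * (cos(half) * u + sin(half) * v)
  h2 <- ow + .WATER_OH * (cos(half) * u - sin(half) * v)

  frame_atoms <- c(A[lig_names], list(thr_CA = A$thr_CA, thr_CB = A$thr_CB,
                                      thr_OG1 = A$thr_OG1, thr_DG1 = dg1,
                                      asn_N = A$asn_N, asn_CA = A$asn_CA,
                                      asn_CB = A$asn_CB, asn_CG = cg,
                                      asn_OD1 = od1, asn_ND2 = nd2,
                                      w_O = ow, w_D1 = h1, w_D2 = h2))
  natoms <- length(frame_atoms)
  xyz <- array(NA_real_, dim = c(natoms, 3L, n))
  for (i in seq_len(natoms)) xyz[i, , ] <- t(frame_atoms[[i]])

  atoms <- data.frame(
    serial = seq_len(natoms),
    name = c(lig_names, "CA", "CB", "OG1", "DG1", "N", "CA", "CB", "CG", "OD1",
             "ND2", "O", "D1", "D2"),
    altloc = "",
    resname = c(rep("AZA", 10), rep("THR", 4), rep("ASN", 6), rep("HOH", 3)),
    chain = c(rep("A", 10), rep("B", 4), rep("A", 6), rep("S", 3)),
    resno = c(rep(301L, 10), rep(57L, 4), rep(254L, 6), rep(401L, 3)),
    inscode = "",
    element = c(substr(lig_names, 1, 1), "C", "C", "O", "D", "N", "C", "C", "C",
                "O", "N", "O", "D", "D"),
    occupancy = 1, b = 10,
    hetatm = c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 3)),
    stringsAsFactors = FALSE)
  model <- structure_model(atoms, xyz, source = sprintf("synthetic_ensemble(seed=%s)", spec$seed))
  manifest <- data.frame(frame = seq_len(n),
                         state = c("major", "minor")[state],
                         asn_component = comp,
                         thr_torsion = as.numeric(thr_t),
                         asn_chi1 = chi1, asn_chi2 = chi2,
                         water_r = wr, water_theta = wth)
  list(model = model, manifest = manifest, spec = spec)
}

#' Write the canonical fixture corpus
#'
#' Writes the toy active-site PDB + JSON manifest and a small synthetic
#' ensemble as a frame table + CSV manifest. Regeneration with the same seeds
#' is byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed ensemble seed.
#' @param n_frames ensemble size.
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_set <- function(outdir, seed = 1, n_frames = 250) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  toy <- build_toy_active_site(toy_site_spec())
  p_pdb <- file.path(outdir, "toy_active_site.pdb")
  write_structure(toy$model, p_pdb)
  p_man <- file.path(outdir, "toy_active_site_manifest.json")
  jsonlite::write_json(toy$manifest, p_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ens <- generate_ensemble(ensemble_spec(n = n_frames, seed = seed))
  p_ft <- file.path(outdir, "synthetic_ensemble.csv")
  write_frame_table(ens$model, p_ft)
  p_em <- file.path(outdir, "synthetic_ensemble_manifest.csv")
  utils::write.csv(format(ens$manifest, digits = 10, trim = TRUE), p_em,
                   row.names = FALSE, quote = FALSE)
  invisible(c(toy_pdb = p_pdb, toy_manifest = p_man,
              ensemble = p_ft, ensemble_manifest = p_em))
}
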