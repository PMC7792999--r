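# Orchestration: one-call structure and ensemble analyses with config echo
# into every output (provenance), plus small self-contained calculations.

#' Role map for the UOX-8AZA active site (toy scaffold naming)
#'
#' Distances, torsions, pi contacts and plane tilts for the catalytic-water
#' site: the Thr*DG1...W1, Lys*DZ1...Thr*OG1, ligand D9...W2 and per-altloc
#' Asn DD21...W1 hydrogen bonds; the Thr CA-CB-OG1-DG1 torsion; the
#' W1 O-D2...pi contact with the six-membered (pyrimidine) ring; the
#' DG1...N7 distance of the second O-H...pi interaction; and the W1/ring
#' plane tilt. Roles are `"chain:resno:name"` strings resolved against the
#' model; edit or replace for structures with other naming.
#'
#' @return roles list for [active_site_report()].
#' @export
uox_site_roles <- function() {
  list(
    distances = list(
      "Thr57*DG1...W1O" = c("B:57:DG1", "S:401:O"),
      "Lys10*DZ1...Thr57*OG1" = c("B:10:DZ1", "B:57:OG1"),
      "Thr57*DG1...AZA N7" = c("B:57:DG1", "A:301:N7"),
      "AZA D9...W2O" = c("A:301:D9", "S:402:O"),
      "Asn254 DD21...W1O" = c("A:254:DD21", "S:401:O")),
    torsions = list(
      "Thr57* CA-CB-OG1-DG1" = c("B:57:CA", "B:57:CB", "B:57:OG1", "B:57:DG1")),
    pi_contacts = list(
      "W1 O-D2...pyrimidine" = list(x = "S:401:O", h = "S:401:D2",
                                    ring = "resname AZA and name N1,C2,N3,C4,C5,C6")),
    plane_tilts = list(
      "W1 plane vs AZA ring" = list(a = "resname HOH and resno 401",
                                    b = "resname AZA and name N1,C2,N3,C4,C5,C6")),
    hbonds = list(criteria = hbond_criteria()))
}

#' Run the structure-analysis stage
#'
#' Reads (or takes) a structure, computes the [active_site_report()] for the
#' configured roles and writes it as JSON + CSV with the full configuration
#' echoed into the output header.
#'
#' @param config list: `input` (path or [structure_model()]), `roles`
#'   (default [uox_site_roles()]), `pi_thresholds`, `outdir`, `stem`.
#' @return the [active_site_report()], invisibly.
#' @export
run_structure_analysis <- function(config) {
  model <- if (inherits(config$input, "structure_model")) config$input
           else read_structure(config$input)
  roles <- config$roles %||% uox_site_roles()
  rep <- active_site_report(model, roles,
                            pi_thresholds = config$pi_thresholds %||% pi_thresholds())
  if (!is.null(config$outdir))
    write_report(rep, config$outdir, stem = config$stem %||% "active_site")
  invisible(rep)
}

#' Run the ensemble-analysis stage
#'
#' Computes, for a conformational ensemble: the Thr-like torsion series and
#' its 1D circular density with modes; the Asn-like (chi1, chi2) pair, its
#' 2D toroidal density and density-peak clusters; the water-site (r, theta)
#' coordinates, residence trace and cluster/residence coupling. Writes
#' per-frame CSV, density grids and a JSON summary; deterministic given the
#' inputs.
#'
#' @param config list: `input` (path or multi-frame [structure_model()]);
#'   optional `thr_spec` ([torsion_spec()]), `asn_specs` (list of 2),
#'   `water_roles` (list c4, c5, o, h1, h2), `r_threshold`, `grid_step`,
#'   `concentration`, `outdir`.
#' @return list with `thr_series`, `thr_density`, `thr_modes`, `asn_pair`,
#'   `clusters`, `water`, `residence`, `coupling`, invisibly.
#' @export
run_ensemble_analysis <- function(config) {
  ens <- if (inherits(config$input, "structure_model")) config$input
         else read_ensemble(config$input)
  if (n_frames(ens) < 2L)
    warning("ensemble has a single frame: densities are degenerate", call. = FALSE)
  thr_spec <- config$thr_spec %||%
    torsion_spec("Thr57* CA-CB-OG1-DG1", "B:57:CA", "B:57:CB", "B:57:OG1", "B:57:DG1")
  asn_specs <- config$asn_specs %||% list(
    torsion_spec("Asn254 chi1 (N-CA-CB-CG)", "A:254:N", "A:254:CA", "A:254:CB", "A:254:CG"),
    torsion_spec("Asn254 chi2' (CA-CB-CG-ND2)", "A:254:CA", "A:254:CB", "A:254:CG", "A:254:ND2"))
  wroles <- config$water_roles %||% list(c4 = "A:301:C4", c5 = "A:301:C5",
                                         o = "S:401:O", h1 = "S:401:D1", h2 = "S:401:D2")
  gs <- config$grid_step %||% 1

  thr <- torsion_series(ens, thr_spec)
  thr_d <- circular_density_1d(thr, concentration = config$concentration, grid_step = gs)
  thr_m <- density_modes(thr_d)
  s1 <- torsion_series(ens, asn_specs[[1]])
  s2 <- torsion_series(ens, asn_specs[[2]])
  cl <- cluster_torsions_2d(s1, s2, concentration = config$concentration, grid_step = gs)
  wat <- water_site_coordinates(ens, wroles$c4, wroles$c5, wroles$o, wroles$h1, wroles$h2)
  res <- residence_trace(wat, r_threshold = config$r_threshold %||% 4.0)
  coup <- tryCatch(state_coupling(cl$labels, res), error = function(e) NULL)

  out <- list(thr_series = thr, thr_density = thr_d, thr_modes = thr_m,
              asn_pair = list(s1, s2), clusters = cl, water = wat,
              residence = res, coupling = coup)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    per_frame <- data.frame(frame = wat$frame,
                            thr_torsion = thr$values,
                            asn_chi1 = s1$values, asn_chi2 = s2$values,
                            cluster = cl$labels,
                            r = wat$r, theta = wat$theta,
                            inside = res$inside)
    utils::write.csv(per_frame, file.path(config$outdir, "per_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(angle = thr_d$grid, density = thr_d$density),
                     file.path(config$outdir, "thr_density_1d.csv"), row.names = FALSE)
    d2 <- cl$density
    if (!is.null(d2)) {
      grid2 <- expand.grid(chi1 = d2$grid, chi2 = d2$grid)
      grid2$density <- as.vector(d2$density)
      utils::write.csv(grid2, file.path(config$outdir, "asn_density_2d.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(cl$clusters, file.path(config$outdir, "clusters.csv"),
                     row.names = FALSE)
    summary <- list(
      config = list(r_threshold = res$r_threshold, grid_step = gs,
                    concentration_1d = thr_d$concentration,
                    concentration_2d = if (!is.null(cl$density)) cl$density$concentration,
                    n_frames = n_frames(ens), source = ens$source,
                    package = "uoxgeom",
                    version = as.character(utils::packageVersion("uoxgeom"))),
      thr_modes = thr_m,
      clusters = cl$clusters,
      residence = list(occupancy = res$occupancy,
                       mean_inside_segment = res$mean_inside_segment),
      coupling = if (!is.null(coup)) list(odds_ratio = coup$odds_ratio,
                                          cramers_v = coup$cramers_v,
                                          reference = coup$reference,
                                          degenerate = coup$degenerate,
                                          table = as.data.frame(coup$table)))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Deuteration level from mass-spectrometry mass differences
#'
#' `100 * observed / calculated` percent, reported to one decimal place:
#' the observed protiated-vs-deuterated mass difference over the mass
#' difference calculated for complete deuteration.
#'
#' @param observed_mass_difference observed mass difference (a.m.u.).
#' @param calculated_mass_difference calculated mass difference for complete
#'   deuteration (a.m.u., > 0).
#' @return deuteration level in percent (1 d.p.).
#' @export
deuteration_level <- function(observed_mass_difference, calculated_mass_difference) {
  if (calculated_mass_difference <= 0)
    stop("calculated mass difference must be > 0", call. = FALSE)
  round(100 * observed_mass_difference / calculated_mass_difference, 1)
}
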