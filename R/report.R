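# The active-site geometry report: named distances, torsions, pi contacts,
# plane tilts and detected hydrogen bonds, with per-altloc expansion and
# full provenance. Machine-readable (JSON + CSV).

.role_atoms <- function(model, role) {
  expr <- if (grepl(":", role, fixed = TRUE)) {
    p <- strsplit(role, ":", fixed = TRUE)[[1]]
    paste(c(if (nzchar(p[1])) paste("chain", p[1]),
            paste("resno", p[2]), paste("name", p[3])), collapse = " and ")
  } else role
  select_atoms(model, expr, on_missing = "error")
}

#' Active-site geometry report
#'
#' Emits every named quantity of a role configuration for one structure:
#' distances and torsions (one row per alternate-location combination when a
#' role resolves to several conformers -- values are never averaged over
#' altlocs), X-H...pi contacts with classification, inter-plane tilts, and a
#' hydrogen-bond scan. Every row records the atom indices it was computed
#' from, so each value is exactly recomputable.
#'
#' @param model a [structure_model()].
#' @param roles list with any of:
#'   \describe{
#'     \item{distances}{named list of 2 atom roles (`"chain:resno:name"` or
#'       selection expressions).}
#'     \item{torsions}{named list of 4 atom roles.}
#'     \item{pi_contacts}{named list of `list(x =, h =, ring =)` roles.}
#'     \item{plane_tilts}{named list of `list(a =, b =)` selection roles
#'       (each resolving to >= 3 atoms).}
#'     \item{hbonds}{`list(criteria =, donor_sel =, acceptor_sel =)` or
#'       `NULL` to skip the scan.}
#'   }
#' @param pi_thresholds thresholds for [classify_pi_contact()].
#' @param frame frame index.
#' @return object of class `active_site_report` with data.frame sections
#'   `distances`, `torsions`, `pi_contacts`, `plane_tilts`, `hbonds` and a
#'   `provenance` list.
#' @export
active_site_report <- function(model, roles, pi_thresholds = uoxgeom::pi_thresholds(),
                               frame = 1L) {
  xyz <- coords(model, frame)
  at <- model$atoms
  tag_of <- function(idx) ifelse(nzchar(at$altloc[idx]), at$altloc[idx], "-")

  expand_combo <- function(idx_list) {
    # one row per combination of matched atoms across the roles
    grid <- do.call(expand.grid, c(lapply(idx_list, seq_along), KEEP.OUT.ATTRS = FALSE))
    lapply(seq_len(nrow(grid)), function(r)
      mapply(function(ix, k) ix[k], idx_list, as.integer(grid[r, ])))
  }

  dist_rows <- list()
  for (lbl in names(roles$distances %||% list())) {
    pair <- roles$distances[[lbl]]
    combos <- expand_combo(lapply(pair, .role_atoms, model = model))
    for (cb in combos) {
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        label = lbl, altloc = paste(tag_of(cb), collapse = "/"),
        value = distance(xyz[cb[1], ], xyz[cb[2], ]),
        atoms = paste(cb, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  tor_rows <- list()
  for (lbl in names(roles$torsions %||% list())) {
    quad <- roles$torsions[[lbl]]
    combos <- expand_combo(lapply(quad, .role_atoms, model = model))
    for (cb in combos) {
      tor_rows[[length(tor_rows) + 1L]] <- data.frame(
        label = lbl, altloc = paste(tag_of(cb), collapse = "/"),
        value = torsion(xyz[cb[1], ], xyz[cb[2], ], xyz[cb[3], ], xyz[cb[4], ]),
        atoms = paste(cb, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  pi_rows <- list()
  for (lbl in names(roles$pi_contacts %||% list())) {
    pc <- roles$pi_contacts[[lbl]]
    ring_idx <- .role_atoms(model, pc$ring)
    for (xi in .role_atoms(model, pc$x)) for (hi in .role_atoms(model, pc$h)) {
      ct <- characterize_pi_contact(xyz[xi, ], xyz[hi, ], xyz[ring_idx, , drop = FALSE])
      pi_rows[[length(pi_rows) + 1L]] <- data.frame(
        label = lbl, altloc = paste(tag_of(c(xi, hi)), collapse = "/"),
        d_xm = ct$d_xm, omega = ct$omega, angle_xhm = ct$angle_xhm,
        passes = classify_pi_contact(ct, pi_thresholds),
        atoms = paste(c(xi, hi), collapse = ","), stringsAsFactors = FALSE)
    }
  }
  tilt_rows <- list()
  for (lbl in names(roles$plane_tilts %||% list())) {
    pl <- roles$plane_tilts[[lbl]]
    pa <- fit_ring_plane(xyz[.role_atoms(model, pl$a), , drop = FALSE])
    pb <- fit_ring_plane(xyz[.role_atoms(model, pl$b), , drop = FALSE])
    tilt_rows[[length(tilt_rows) + 1L]] <- data.frame(
      label = lbl, value = plane_tilt(pa, pb), stringsAsFactors = FALSE)
  }
  hb <- NULL
  if (!is.null(roles$hbonds)) {
    hb <- detect_hbonds(model,
                        criteria = roles$hbonds$criteria %||% hbond_criteria(),
                        donor_sel = roles$hbonds$donor_sel,
                        acceptor_sel = roles$hbonds$acceptor_sel,
                        frame = frame)
  }
  bindf <- function(rows, empty) if (length(rows)) do.call(rbind, rows) else empty
  structure(list(
    distances = bindf(dist_rows, data.frame(label = character(), altloc = character(),
                                            value = numeric(), atoms = character())),
    torsions = bindf(tor_rows, data.frame(label = character(), altloc = character(),
                                          value = numeric(), atoms = character())),
    pi_contacts = bindf(pi_rows, data.frame(label = character(), altloc = character(),
                                            d_xm = numeric(), omega = numeric(),
                                            angle_xhm = numeric(), passes = logical(),
                                            atoms = character())),
    plane_tilts = bindf(tilt_rows, data.frame(label = character(), value = numeric())),
    hbonds = hb,
    provenance = list(source = model$source, frame = frame,
                      pi_thresholds = pi_thresholds,
                      hbond_criteria = if (!is.null(roles$hbonds))
                        roles$hbonds$criteria %||% hbond_criteria(),
                      package = "uoxgeom",
                      version = as.character(utils::packageVersion("uoxgeom")))),
    class = "active_site_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.active_site_report <- function(x, digits = 3, ...) {
  cat("active-site geometry report [", x$provenance$source, "]\n", sep = "")
  if (nrow(x$distances)) {
    cat("distances (A):\n")
    print(x$distances[, c("label", "altloc", "value")], digits = digits, row.names = FALSE)
  }
  if (nrow(x$torsions)) {
    cat("torsions (deg):\n")
    print(x$torsions[, c("label", "altloc", "value")], digits = 4, row.names = FALSE)
  }
  if (nrow(x$pi_contacts)) {
    cat("X-H...pi contacts:\n")
    print(x$pi_contacts[, c("label", "altloc", "d_xm", "omega", "angle_xhm", "passes")],
          digits = digits, row.names = FALSE)
  }
  if (nrow(x$plane_tilts)) {
    cat("plane tilts (deg):\n")
    print(x$plane_tilts, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$hbonds) && nrow(x$hbonds)) {
    cat("hydrogen bonds:\n")
    print(as.data.frame(x$hbonds), digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Self-consistency check of a report
#'
#' Recomputes every distance/torsion row from its stored atom indices and
#' returns the maximum absolute discrepancy (should be exactly 0).
#'
#' @param report an [active_site_report()].
#' @param model the model the report was computed from.
#' @return maximum absolute discrepancy.
#' @export
report_self_check <- function(report, model) {
  xyz <- coords(model, report$provenance$frame)
  err <- 0
  for (i in seq_len(nrow(report$distances))) {
    cb <- as.integer(strsplit(report$distances$atoms[i], ",")[[1]])
    err <- max(err, abs(report$distances$value[i] - distance(xyz[cb[1], ], xyz[cb[2], ])))
  }
  for (i in seq_len(nrow(report$torsions))) {
    cb <- as.integer(strsplit(report$torsions$atoms[i], ",")[[1]])
    err <- max(err, abs(circ_diff(report$torsions$value[i],
                                  torsion(xyz[cb[1], ], xyz[cb[2], ], xyz[cb[3], ], xyz[cb[4], ]))))
  }
  err
}

#' Write a report as JSON (+ CSV tables)
#'
#' @param report an [active_site_report()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return paths of written files, invisibly.
#' @export
write_report <- function(report, dir, stem = "active_site") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(provenance = report$provenance,
         distances = report$distances, torsions = report$torsions,
         pi_contacts = report$pi_contacts, plane_tilts = report$plane_tilts,
         hbonds = if (is.null(report$hbonds)) NULL else as.data.frame(report$hbonds)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- js
  for (sec in c("distances", "torsions", "pi_contacts", "plane_tilts")) {
    if (nrow(report[[sec]])) {
      p <- file.path(dir, paste0(stem, "_", sec, ".csv"))
      utils::write.csv(report[[sec]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$hbonds) && nrow(report$hbonds)) {
    p <- file.path(dir, paste0(stem, "_hbonds.csv"))
    utils::write.csv(as.data.frame(report$hbonds), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
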