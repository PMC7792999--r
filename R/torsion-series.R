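# Torsion-angle traces over ensemble frames.

#' Define a torsion by four atom roles
#'
#' Each role is `"chain:resno:name"` (chain may be empty: `":57:CA"`), or a
#' selection expression understood by [select_atoms()] resolving to exactly
#' one atom per altloc.
#'
#' @param label series label (e.g. `"Thr57 CA-CB-OG1-DG1"`).
#' @param a,b,c,d atom roles.
#' @return object of class `torsion_spec`.
#' @export
torsion_spec <- function(label, a, b, c, d) {
  structure(list(label = label, roles = c(a, b, c, d)), class = "torsion_spec")
}

.resolve_role <- function(model, role, altloc = NULL) {
  expr <- if (grepl(":", role, fixed = TRUE)) {
    p <- strsplit(role, ":", fixed = TRUE)[[1]]
    paste(c(if (nzchar(p[1])) paste("chain", p[1]),
            paste("resno", p[2]), paste("name", p[3])), collapse = " and ")
  } else role
  idx <- select_atoms(model, expr, on_missing = "error")
  if (!is.null(altloc)) {
    alt <- model$atoms$altloc[idx]
    idx <- idx[alt == "" | alt == altloc]
  }
  if (length(idx) > 1L) {
    # prefer the highest-occupancy alternate location
    idx <- idx[order(-model$atoms$occupancy[idx], model$atoms$altloc[idx])][1]
  }
  idx
}

#' Torsion-angle series over all frames of an ensemble
#'
#' @param ensemble a [structure_model()] with >= 1 frames.
#' @param spec a [torsion_spec()].
#' @param altloc optional altloc tag used to resolve alternate conformations.
#' @return object of class `torsion_series`: `label`, `values` (degrees on
#'   (-180, 180], one per frame), `frames`.
#' @export
torsion_series <- function(ensemble, spec, altloc = NULL) {
  stopifnot(inherits(spec, "torsion_spec"))
  idx <- vapply(spec$roles, function(r) .resolve_role(ensemble, r, altloc), integer(1))
  val <- torsion(t(ensemble$xyz[idx[1], , ]), t(ensemble$xyz[idx[2], , ]),
                 t(ensemble$xyz[idx[3], , ]), t(ensemble$xyz[idx[4], , ]))
  structure(list(label = spec$label, values = val, frames = seq_len(n_frames(ensemble))),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("torsion series '%s': %d frames, circular mean %.1f deg\n",
              x$label, length(x$values), circ_mean(x$values)))
  invisible(x)
}
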