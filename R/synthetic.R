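# Synthetic fixtures: a toy active site with exactly known internal geometry
# and conformational ensembles with planted statistical structure, each with
# a ground-truth manifest so every analysis stage is verifiable end-to-end.
#
# Scaffolding geometry (ideal bond lengths/angles below) is fixed documented
# constants emulating the UOX-8AZA site; it makes no claim about 8AZA
# chemistry. Water internal geometry: O-H 0.96 A, H-O-H 104.5 deg.

.WATER_OH <- 0.96
.WATER_HOH <- 104.5
.WATER_DMID <- .WATER_OH * cos(.WATER_HOH / 2 * pi / 180)  # O -> H-midpoint

# Placement constants of the toy site, calibrated once so that the realized
# fixture reproduces the deposited-model geometry (pi triple 3.64 A / 23.8
# deg / 141 deg, DG1...N7 2.77 A, W1 plane tilt ~45 deg) when the planted
# parameters take their default values. See toy_site_spec().
.TOY <- list(
  ang_c4c5o    = 101.34965129,  # angle C4-C5-Ow placing the water over the ring
  tor_n3c4c5o  = 78.21705706,   # torsion N3-C4-C5-Ow
  ang_c5_o_mid = 70.30654808,   # angle C5-Ow-mid(H1,H2)
  spin         = 123.93717568,  # water rotation about the O->mid axis
  ang_c5_o_dg1 = 64.22700400,   # angle C5-Ow-DG1 (Thr deuteron placement)
  tor_c4c5o_dg1 = 111.79554000, # torsion C4-C5-Ow-DG1
  ang_asn_A    = 107.61743,  # angle C5-Ow-DD21 for Asn altloc A
  tor_asn_A    = -126.33406,
  ang_asn_B    = 133.16272,
  tor_asn_B    = -63.32906,
  ang_dz1      = 126.01752,  # free Lys placement angles (clash-avoiding)
  tor_dz1      = 114.20296,
  tor_nz       = -118.74151,
  lys_rot      = 160.09932)

#' Specification of the toy active site
#'
#' Defaults are the study conditions: the planted internal geometry matches
#' the values printed for the deposited room-temperature model (water-site
#' coordinates (3.47 A, 6 deg), Thr CA-CB-OG1-DG1 torsion -110.4 deg,
#' hydrogen-bond distances 2.16 / 1.97 / 1.84 / 2.23-2.25 A), and the
#' secondary placement angles are calibrated so the realized X-H...pi
#' geometry reproduces the printed (3.64 A, 23.8 deg, 141 deg) triple, the
#' DG1...N7 distance of 2.77 A and the ~45 deg water/ring plane tilt.
#'
#' @param water_r,water_theta water-site radial coordinates: distance
#'   C5-Ow (angstrom) and torsion C4-C5-Ow-mid(H1,H2) (degrees).
#' @param thr_torsion planted CA-CB-OG1-DG1 torsion (degrees).
#' @param d_thr_dg1_w1 planted Thr DG1...W1 O distance (angstrom).
#' @param ang_og1_dg1_w1 planted O-D...O hydrogen-bond angle at DG1 (degrees).
#' @param d_lys_dz1_og1,ang_nz_dz1_og1 planted Lys DZ1...Thr OG1 bond.
#' @param d_aza_d9_w2,ang_n9_d9_w2 planted ligand D9...W2 O bond.
#' @param d_asn_dd21_w1 named per-altloc planted Asn DD21...W1 O distances.
#' @param asn_occupancies named altloc occupancies for the Asn side chain.
#' @param placement list of secondary placement angles (see `.TOY`); override
#'   for non-default constructions.
#' @param water_override optional list(o =, h1 =, h2 =) of explicit water
#'   positions, bypassing the (r, theta) construction (used e.g. to put the
#'   water on the ring normal).
#' @return object of class `toy_site_spec`.
#' @export
toy_site_spec <- function(water_r = 3.47, water_theta = 6,
                          thr_torsion = -110.4,
                          d_thr_dg1_w1 = 2.16, ang_og1_dg1_w1 = 160,
                          d_lys_dz1_og1 = 1.97, ang_nz_dz1_og1 = 165,
                          d_aza_d9_w2 = 1.84, ang_n9_d9_w2 = 170,
                          d_asn_dd21_w1 = c(A = 2.23, B = 2.25),
                          asn_occupancies = c(A = 0.75, B = 0.25),
                          placement = list(), water_override = NULL) {
  pl <- utils::modifyList(.TOY, placement)
  structure(list(water_r = water_r, water_theta = water_theta,
                 thr_torsion = thr_torsion,
                 d_thr_dg1_w1 = d_thr_dg1_w1, ang_og1_dg1_w1 = ang_og1_dg1_w1,
                 d_lys_dz1_og1 = d_lys_dz1_og1, ang_nz_dz1_og1 = ang_nz_dz1_og1,
                 d_aza_d9_w2 = d_aza_d9_w2, ang_n9_d9_w2 = ang_n9_d9_w2,
                 d_asn_dd21_w1 = d_asn_dd21_w1, asn_occupancies = asn_occupancies,
                 placement = pl, water_override = water_override),
            class = "toy_site_spec")
}

# ligand scaffold: purine-like fused rings in the z = 0 plane, hexagon
# circumradius 1.39 A (ideal aromatic bond), centered at the origin.
.toy_ligand <- function() {
  hex_names <- c("C5", "C4", "N3", "C2", "N1", "C6")
  hex <- t(vapply(0:5, function(k)
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  rownames(hex) <- hex_names
  c4 <- hex["C4", ]; c5 <- hex["C5", ]
  s <- sqrt(sum((c4 - c5)^2))
  mid <- (c4 + c5) / 2
  out_dir <- mid / sqrt(sum(mid^2))
  apo <- s / (2 * tan(pi / 5)); circ <- s / (2 * sin(pi / 5))
  ctr <- mid + apo * out_dir
  phi5 <- atan2(c5[2] - ctr[2], c5[1] - ctr[1])
  phi4 <- atan2(c4[2] - ctr[2], c4[1] - ctr[1])
  step <- if (sin(phi4 - phi5) > 0) 2 * pi / 5 else -2 * pi / 5
  pent <- t(vapply(1:3, function(k)
    ctr + circ * c(cos(phi5 - k * step), sin(phi5 - k * step), 0), numeric(3)))
  rownames(pent) <- c("N7", "N8", "N9")
  sub <- function(at, bond) at * (1 + bond / 1.39)   # radially outward, z = 0
  rbind(hex, pent,
        O6 = sub(hex["C6", ], 1.23), O2 = sub(hex["C2", ], 1.23),
        D1 = sub(hex["N1", ], 1.01),
        D9 = pent["N9", ] + 1.01 * (pent["N9", ] - ctr) / sqrt(sum((pent["N9", ] - ctr)^2)))
}

.water_from_mid <- function(o, mid, ref, spin_deg) {
  # H1/H2 from the O->mid axis, the in-plane reference direction and a spin
  u <- (mid - o) / sqrt(sum((mid - o)^2))
  w <- ref - o; w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w * w))
  sp <- spin_deg * pi / 180
  v <- w * cos(sp) + c(u[2] * w[3] - u[3] * w[2],
                       u[3] * w[1] - u[1] * w[3],
                       u[1] * w[2] - u[2] * w[1]) * sin(sp)
  half <- .WATER_HOH / 2 * pi / 180
  list(h1 = o + .WATER_OH * (cos(half) * u + sin(half) * v),
       h2 = o + .WATER_OH * (cos(half) * u - sin(half) * v))
}

#' Build the toy active site
#'
#' Realizes a [toy_site_spec()] as a [structure_model()] (ligand ring system,
#' Thr-like and Lys-like side chains, an Asn-like amide in two alternate
#' conformations, catalytic water W1 and a second water W2) together with a
#' ground-truth manifest listing every plantable quantity. All planted
#' internal coordinates are realized exactly (to floating point) before any
#' file rounding.
#'
#' @param spec a [toy_site_spec()].
#' @return list with `model` (a [structure_model()]) and `manifest` (list of
#'   `planted` and `realized` quantities plus atom bookkeeping).
#' @export
build_toy_active_site <- function(spec = toy_site_spec()) {
  stopifnot(inherits(spec, "toy_site_spec"))
  pl <- spec$placement
  lig <- .toy_ligand()
  n3 <- lig["N3", ]; c4 <- lig["C4", ]; c5 <- lig["C5", ]; n7 <- lig["N7", ]

  # --- W1: planted (r, theta) water-site coordinates -------------------------
  if (is.null(spec$water_override)) {
    ow <- place_internal(n3, c4, c5, spec$water_r, pl$ang_c4c5o, pl$tor_n3c4c5o)
    wmid <- place_internal(c4, c5, ow, .WATER_DMID, pl$ang_c5_o_mid, spec$water_theta)
    hh <- .water_from_mid(ow, wmid, c5, pl$spin)
  } else {
    ow <- spec$water_override$o
    hh <- list(h1 = spec$water_override$h1, h2 = spec$water_override$h2)
    wmid <- (hh$h1 + hh$h2) / 2
  }

  # --- Thr-like side chain: planted DG1...W1 bond and CA-CB-OG1-DG1 torsion --
  dg1 <- place_internal(c4, c5, ow, spec$d_thr_dg1_w1, pl$ang_c5_o_dg1, pl$tor_c4c5o_dg1)
  og1 <- place_internal(c5, ow, dg1, .WATER_OH, spec$ang_og1_dg1_w1, 60)
  cb_t <- place_internal(ow, dg1, og1, 1.43, 109.47, 180)
  ca_t <- place_internal(dg1, og1, cb_t, 1.53, 109.47, spec$thr_torsion)
  n_t <- place_internal(og1, cb_t, ca_t, 1.46, 110, 60)
  c_t <- place_internal(og1, cb_t, ca_t, 1.52, 110, -175)
  o_t <- place_internal(cb_t, ca_t, c_t, 1.23, 120, 0)

  # --- Lys-like ammonium: planted DZ1...OG1 bond -----------------------------
  dz1 <- place_internal(dg1, cb_t, og1, spec$d_lys_dz1_og1, pl$ang_dz1, pl$tor_dz1)
  nz <- place_internal(cb_t, og1, dz1, 1.02, spec$ang_nz_dz1_og1, pl$tor_nz)
  dz2 <- place_internal(og1, dz1, nz, 1.02, 109.47, pl$lys_rot)
  dz3 <- place_internal(og1, dz1, nz, 1.02, 109.47, pl$lys_rot + 120)
  ce <- place_internal(og1, dz1, nz, 1.49, 109.47, pl$lys_rot - 120)

  # --- Asn-like amide in two conformers: planted DD21...W1 distances ---------
  asn <- list()
  for (tg in names(spec$asn_occupancies)) {
    dd21 <- place_internal(c4, c5, ow, spec$d_asn_dd21_w1[[tg]],
                           pl[[paste0("ang_asn_", tg)]], pl[[paste0("tor_asn_", tg)]])
    nd2 <- place_internal(c5, ow, dd21, 1.01, 150, 40)
    dd22 <- place_internal(ow, dd21, nd2, 1.01, 120, 180)
    cg <- place_internal(ow, dd21, nd2, 1.33, 120, 0)
    od1 <- place_internal(dd21, nd2, cg, 1.23, 122, 180)
    cb <- place_internal(dd22, nd2, cg, 1.52, 116, 0)
    asn[[tg]] <- rbind(CG = cg, OD1 = od1, ND2 = nd2, DD21 = dd21, DD22 = dd22, CB = cb)
  }
  cb_a <- (asn[[1]]["CB", ] + asn[[2]]["CB", ]) / 2    # shared backbone stub
  ca_a <- place_internal(asn[[1]]["ND2", ], asn[[1]]["CG", ], cb_a, 1.53, 113, 150)
  n_a <- place_internal(asn[[1]]["CG", ], cb_a, ca_a, 1.46, 110, -60)

  # --- W2: planted ligand D9...W2 bond ---------------------------------------
  w2o <- place_internal(lig["N8", ], lig["N9", ], lig["D9", ],
                        spec$d_aza_d9_w2, spec$ang_n9_d9_w2, 0)

  row <- function(name, resname, chain, resno, el, pos, alt = "", occ = 1, het = FALSE)
    list(name = name, resname = resname, chain = chain, resno = resno,
         element = el, pos = pos, alt = alt, occ = occ, het = het)
  lig_el <- substr(rownames(lig), 1, 1)
  rows <- c(
    lapply(seq_len(nrow(lig)), function(i)
      row(rownames(lig)[i], "AZA", "A", 301L, lig_el[i], lig[i, ], het = TRUE)),
    list(row("N", "THR", "B", 57L, "N", n_t), row("CA", "THR", "B", 57L, "C", ca_t),
         row("C", "THR", "B", 57L, "C", c_t), row("O", "THR", "B", 57L, "O", o_t),
         row("CB", "THR", "B", 57L, "C", cb_t), row("OG1", "THR", "B", 57L, "O", og1),
         row("DG1", "THR", "B", 57L, "D", dg1, occ = 0.78),
         row("CE", "LYS", "B", 10L, "C", ce), row("NZ", "LYS", "B", 10L, "N", nz),
         row("DZ1", "LYS", "B", 10L, "D", dz1), row("DZ2", "LYS", "B", 10L, "D", dz2),
         row("DZ3", "LYS", "B", 10L, "D", dz3),
         row("N", "ASN", "A", 254L, "N", n_a), row("CA", "ASN", "A", 254L, "C", ca_a),
         row("CB", "ASN", "A", 254L, "C", cb_a)),
    unlist(lapply(names(asn), function(tg) {
      m <- asn[[tg]][c("CG", "OD1", "ND2", "DD21", "DD22"), , drop = FALSE]
      el <- substr(rownames(m), 1, 1)
      lapply(seq_len(nrow(m)), function(i)
        row(rownames(m)[i], "ASN", "A", 254L, el[i], m[i, ],
            alt = tg, occ = spec$asn_occupancies[[tg]]))
    }), recursive = FALSE),
    list(row("O", "HOH", "S", 401L, "O", ow, occ = 0.93),
         row("D1", "HOH", "S", 401L, "D", hh$h1, occ = 0.93),
         row("D2", "HOH", "S", 401L, "D", hh$h2, occ = 0.93),
         row("O", "HOH", "S", 402L, "O", w2o)))
  atoms <- data.frame(serial = seq_along(rows),
                      name = vapply(rows, `[[`, "", "name"),
                      altloc = vapply(rows, `[[`, "", "alt"),
                      resname = vapply(rows, `[[`, "", "resname"),
                      chain = vapply(rows, `[[`, "", "chain"),
                      resno = vapply(rows, function(r) as.integer(r$resno), 1L),
                      inscode = "",
                      element = vapply(rows, `[[`, "", "element"),
                      occupancy = vapply(rows, function(r) r$occ, 1),
                      b = 10,
                      hetatm = vapply(rows, function(r) r$het || r$resname == "HOH", TRUE),
                      stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(rows, `[[`, "pos"))
  model <- structure_model(atoms, xyz, cell = c(80, 96, 105, 90, 90, 90),
                           spacegroup = "I 2 2 2", source = "toy_active_site")

  # realized (emergent) geometry, recorded from the coordinates
  ringp <- fit_ring_plane(lig[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
  wplane <- fit_ring_plane(rbind(ow, hh$h1, hh$h2))
  pi_ct <- characterize_pi_contact(ow, hh$h2, lig[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
  manifest <- list(
    planted = list(
      water_r = spec$water_r, water_theta = spec$water_theta,
      thr_torsion = spec$thr_torsion,
      d_thr_dg1_w1 = spec$d_thr_dg1_w1, ang_og1_dg1_w1 = spec$ang_og1_dg1_w1,
      d_lys_dz1_og1 = spec$d_lys_dz1_og1, ang_nz_dz1_og1 = spec$ang_nz_dz1_og1,
      d_aza_d9_w2 = spec$d_aza_d9_w2,
      d_asn_dd21_w1 = as.list(spec$d_asn_dd21_w1),
      asn_occupancies = as.list(spec$asn_occupancies)),
    realized = list(
      pi_d_om = pi_ct$d_xm, pi_omega = pi_ct$omega, pi_angle_ohm = pi_ct$angle_xhm,
      w1_plane_tilt = plane_tilt(wplane, ringp),
      d_thr_dg1_n7 = distance(dg1, n7)),
    n_atoms = nrow(atoms))
  if (!is.null(spec$water_override)) {
    manifest$planted$water_r <- distance(c5, ow)
    manifest$planted$water_theta <- torsion(c4, c5, ow, wmid)
  }
  list(model = model, manifest = manifest)
}
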