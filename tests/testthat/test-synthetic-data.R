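# Generators: exact manifest realization, determinism, estimator recovery.

test_that("every toy-site manifest entry is reproduced by independent recomputation", {
  toy <- build_toy_active_site()
  at <- toy$model$atoms; xyz <- coords(toy$model)
  g <- function(name, resno, alt = "") xyz[at$name == name & at$resno == resno &
                                             at$altloc %in% c("", alt), , drop = FALSE][1, ]
  man <- toy$manifest
  # planted internal coordinates, recomputed with the independent oracles
  expect_lt(abs(oracle_distance(g("C5", 301), g("O", 401)) - man$planted$water_r), 1e-6)
  mid <- (g("D1", 401) + g("D2", 401)) / 2
  expect_lt(abs(circ_diff(oracle_torsion(g("C4", 301), g("C5", 301), g("O", 401), mid),
                          man$planted$water_theta)), 1e-6)
  expect_lt(abs(circ_diff(oracle_torsion(g("CA", 57), g("CB", 57), g("OG1", 57), g("DG1", 57)),
                          man$planted$thr_torsion)), 1e-6)
  expect_lt(abs(oracle_distance(g("DG1", 57), g("O", 401)) - man$planted$d_thr_dg1_w1), 1e-6)
  expect_lt(abs(oracle_distance(g("DZ1", 10), g("OG1", 57)) - man$planted$d_lys_dz1_og1), 1e-6)
  expect_lt(abs(oracle_distance(g("D9", 301), g("O", 402)) - man$planted$d_aza_d9_w2), 1e-6)
  for (tg in c("A", "B"))
    expect_lt(abs(oracle_distance(g("DD21", 254, tg), g("O", 401)) -
                    man$planted$d_asn_dd21_w1[[tg]]), 1e-6)
  # realized (emergent) geometry, recomputed with the oracles
  ring <- xyz[select_atoms(toy$model, "resname AZA and name N1,C2,N3,C4,C5,C6"), ]
  m <- colMeans(ring)
  nor <- oracle_plane_normal(ring)
  expect_lt(abs(oracle_distance(g("O", 401), m) - man$realized$pi_d_om), 1e-6)
  om <- oracle_angle(m + nor, m, g("O", 401)); om <- min(om, 180 - om)
  expect_lt(abs(om - man$realized$pi_omega), 1e-6)
  expect_lt(abs(oracle_angle(g("O", 401), g("D2", 401), m) - man$realized$pi_angle_ohm), 1e-6)
  expect_lt(abs(oracle_distance(g("DG1", 57), g("N7", 301)) - man$realized$d_thr_dg1_n7), 1e-6)
  wn <- oracle_plane_normal(rbind(g("O", 401), g("D1", 401), g("D2", 401)))
  tilt <- oracle_angle(wn, c(0, 0, 0), nor); tilt <- min(tilt, 180 - tilt)
  expect_lt(abs(tilt - man$realized$w1_plane_tilt), 1e-6)
})

test_that("a water placed on the ring normal gives the axial pi signature", {
  # toy ring is centered at the origin in the z = 0 plane; put the water
  # oxygen on the ring normal with D2 pointing straight at the midpoint
  o <- c(0, 0, 3.4)
  full <- 104.5 * pi / 180
  h2 <- o + 0.96 * c(0, 0, -1)
  h1 <- o + 0.96 * c(sin(full), 0, -cos(full))
  toy <- build_toy_active_site(toy_site_spec(water_override = list(o = o, h1 = h1, h2 = h2)))
  expect_lt(abs(toy$manifest$realized$pi_d_om - 3.4), 1e-9)
  expect_lt(abs(toy$manifest$realized$pi_omega - 0), 1e-9)
  expect_lt(abs(toy$manifest$realized$pi_angle_ohm - 180), 1e-6)
})

test_that("infeasible toy geometry is rejected", {
  expect_error(build_toy_active_site(toy_site_spec(water_r = 0)), "")
})

test_that("von Mises mixture sampling is seeded, consistent and concentrated", {
  comp <- data.frame(weight = 1, mean = 37, kappa = 1e6)
  x <- sample_torsion_mixture(comp, 200, seed = 5)
  expect_lt(max(abs(circ_diff(x, 37))), 0.5)          # huge kappa -> all near mean
  # same seed -> identical, different seed -> different
  two <- data.frame(weight = c(0.6, 0.4), mean = c(-72, 100), kappa = c(20, 20))
  a <- sample_torsion_mixture(two, 500, seed = 9)
  b <- sample_torsion_mixture(two, 500, seed = 9)
  c <- sample_torsion_mixture(two, 500, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # component means recovered by circular mean within +/- 2 degrees
  big <- sample_torsion_mixture(two, 2e4, seed = 11)
  comp_id <- attr(big, "component")
  expect_lt(abs(circ_diff(circ_mean(big[comp_id == 1]), -72)), 2)
  expect_lt(abs(circ_diff(circ_mean(big[comp_id == 2]), 100)), 2)
  expect_error(sample_torsion_mixture(two[0, ], 10), "empty component")
  expect_error(sample_torsion_mixture(data.frame(weight = c(.5, .4), mean = 0:1,
                                                 kappa = 1), 10), "sum to 1")
})

test_that("von Mises sampler matches the closed-form distribution", {
  set.seed(33)
  x <- rvonmises(5e4, 20, 5)
  # Kuiper-style check via histogram vs closed form
  br <- seq(-180, 180, by = 10)
  obs <- hist(x, breaks = br, plot = FALSE)$counts / length(x)
  expb <- vapply(seq_len(length(br) - 1), function(i)
    integrate(function(t) dvonmises(t, 20, 5), br[i], br[i + 1])$value, numeric(1))
  expect_lt(max(abs(obs - expb)), 0.01)
  expect_equal(sd(rvonmises(1000, 0, 0)) > 80, TRUE)  # kappa 0 -> uniform spread
})

test_that("ensembles realize their manifests through actual 3D coordinates", {
  ens <- generate_ensemble(ensemble_spec(n = 400, seed = 12))
  expect_equal(nrow(ens$manifest), 400L)
  w <- water_site_coordinates(ens$model, "A:301:C4", "A:301:C5",
                              "S:401:O", "S:401:D1", "S:401:D2")
  expect_lt(max(abs(w$r - ens$manifest$water_r)), 1e-9)
  expect_lt(max(abs(circ_diff(w$theta, ens$manifest$water_theta))), 1e-6)
  for (nm in list(c("asn_chi1", "A:254:N", "A:254:CA", "A:254:CB", "A:254:CG"),
                  c("asn_chi2", "A:254:CA", "A:254:CB", "A:254:CG", "A:254:ND2"))) {
    s <- torsion_series(ens$model, torsion_spec(nm[1], nm[2], nm[3], nm[4], nm[5]))
    expect_lt(max(abs(circ_diff(s$values, ens$manifest[[nm[1]]]))), 1e-6)
  }
  # determinism: same spec -> identical coordinates and manifest
  ens2 <- generate_ensemble(ensemble_spec(n = 400, seed = 12))
  expect_identical(ens$model$xyz, ens2$model$xyz)
  expect_identical(ens$manifest, ens2$manifest)
  ens3 <- generate_ensemble(ensemble_spec(n = 400, seed = 13))
  expect_false(identical(ens$model$xyz, ens3$model$xyz))
  # n = 1 degenerate case
  one <- generate_ensemble(ensemble_spec(n = 1, seed = 1))
  expect_equal(nrow(one$manifest), 1L)
  expect_equal(n_frames(one$model), 1L)
})

test_that("single-state ensembles echo the planted water statistics", {
  major <- generate_ensemble(ensemble_spec(n = 3000, seed = 14,
                                           p_major_to_minor = 0, p_minor_to_major = 1))
  w <- water_site_coordinates(major$model, "A:301:C4", "A:301:C5",
                              "S:401:O", "S:401:D1", "S:401:D2")
  expect_gte(residence_trace(w, 4.0)$occupancy, 0.9)
  minor <- generate_ensemble(ensemble_spec(n = 3000, seed = 15,
                                           p_major_to_minor = 1, p_minor_to_major = 0))
  expect_true(all(minor$manifest$state == "minor"))
  wm <- water_site_coordinates(minor$model, "A:301:C4", "A:301:C5",
                               "S:401:O", "S:401:D1", "S:401:D2")
  md <- density_modes(circular_density_1d(wm$theta))
  # dominant dihedral mode inside the displaced-water 225-255 degree band
  expect_lt(abs(circ_diff(md$angle[1], 240)), 15)
})

test_that("the fixture corpus is byte-stable and parses cleanly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_set(d1, seed = 4, n_frames = 40)
  p2 <- write_fixture_set(d2, seed = 4, n_frames = 40)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  expect_no_warning(m <- read_structure(p1[["toy_pdb"]]))
  expect_equal(n_atoms(m), 42L)
  expect_no_warning(e <- read_ensemble(p1[["ensemble"]]))
  expect_equal(n_frames(e), 40L)
  # manifest values verified through the pipeline on the re-read ensemble
  man <- utils::read.csv(p1[["ensemble_manifest"]])
  w <- water_site_coordinates(e, "A:301:C4", "A:301:C5", "S:401:O", "S:401:D1", "S:401:D2")
  expect_lt(max(abs(w$r - man$water_r)), 1e-3)        # file rounding at 1e-4 A
  expect_lt(max(abs(circ_diff(w$theta, man$water_theta))), 0.1)
})
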