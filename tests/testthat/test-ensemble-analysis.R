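# Torsion series, circular densities, toroidal clustering, water-site
# coordinates, residence and state coupling.

test_that("torsion series recover planted per-frame values exactly", {
  ens <- generate_ensemble(ensemble_spec(n = 300, seed = 21))
  thr <- torsion_series(ens$model, torsion_spec("thr", "B:57:CA", "B:57:CB",
                                                "B:57:OG1", "B:57:DG1"))
  expect_equal(length(thr$values), 300L)
  expect_lt(max(abs(circ_diff(thr$values, ens$manifest$thr_torsion))), 1e-6)
  # static ensemble -> constant series
  static <- ens$model
  static$xyz <- static$xyz[, , rep(1L, 10L)]
  s <- torsion_series(static, torsion_spec("thr", "B:57:CA", "B:57:CB",
                                           "B:57:OG1", "B:57:DG1"))
  expect_equal(diff(range(s$values)), 0)
  expect_error(torsion_series(ens$model, torsion_spec("x", "B:57:CA", "B:57:CB",
                                                      "B:57:OG1", "Q:1:XX")),
               "matches no atoms")
})

test_that("circular densities are normalized, periodic and shift-equivariant", {
  set.seed(301)
  x <- rvonmises(2000, 40, 4)
  d <- circular_density_1d(x)
  step <- diff(d$grid[1:2])
  expect_lt(abs(sum(d$density) * step - 1), 1e-9)
  expect_true(all(d$density >= 0))
  # torus symmetry: shifting all angles shifts the density grid values
  sh <- 90
  d2 <- circular_density_1d(wrap_deg(x + sh), concentration = d$concentration)
  shifted <- d$density[match(round(wrap_deg(d2$grid - sh), 6), round(d$grid, 6))]
  expect_lt(max(abs(d2$density - shifted)), 1e-9)
  # single observation -> unimodal density peaked at that angle
  d1 <- circular_density_1d(0)
  expect_lt(abs(d1$grid[which.max(d1$density)]), 1)
  expect_error(circular_density_1d(x, concentration = -1), "concentration")
})

test_that("large samples converge to the closed-form von Mises density", {
  set.seed(302)
  err <- vapply(c(2e3, 2e4, 2e5), function(n) {
    x <- rvonmises(n, -72, 4)
    d <- circular_density_1d(x, concentration = 400)   # narrow kernel: low bias
    max(abs(d$density - dvonmises(d$grid, -72, 4)))
  }, numeric(1))
  expect_lt(err[3], 0.02 * dvonmises(0, 0, 4))    # sup error < 2% of peak
  expect_lt(err[3], err[1])                        # shrinks with n
})

test_that("density modes are found, ordered and tie-flagged", {
  set.seed(303)
  x <- c(rvonmises(8000, -72, 8), rvonmises(2000, -135, 15))
  m <- density_modes(circular_density_1d(x))
  expect_gte(nrow(m), 2L)
  expect_lt(abs(circ_diff(m$angle[1], -72)), 3)
  expect_lt(abs(circ_diff(m$angle[2], -135)), 8)
  expect_true(all(diff(m$density) <= 0))
  # a perfectly flat density has no strict mode and is flagged
  flat <- circular_density_1d(0)
  flat$density[] <- 1 / 360
  expect_true(attr(density_modes(flat), "flat"))
})

test_that("2D toroidal density: sharp peak for constant input, flat for uniform", {
  d <- torsion_density_2d(rep(30, 50), rep(-60, 50))
  step <- diff(d$grid[1:2])
  expect_lt(abs(sum(d$density) * step^2 - 1), 1e-9)
  pk <- which(d$density == max(d$density), arr.ind = TRUE)
  expect_lt(abs(circ_diff(d$grid[pk[1]], 30)), 1)
  expect_lt(abs(circ_diff(d$grid[pk[2]], -60)), 1)
  # independent uniform pair: chi-square uniformity not rejected on a coarse grid
  set.seed(304)
  n <- 1e5
  a <- runif(n, -180, 180); b <- runif(n, -180, 180)
  cnt <- table(cut(a, seq(-180, 180, by = 30)), cut(b, seq(-180, 180, by = 30)))
  p <- stats::chisq.test(as.vector(cnt))$p.value
  expect_gt(p, 0.01)
  d2 <- torsion_density_2d(a, b, concentration = c(2, 2))
  expect_lt(max(d2$density) / min(d2$density), 1.5)
  expect_error(torsion_density_2d(1:5, 1:4), "length mismatch")
})

test_that("density-peak clustering recovers well-separated blobs and matches
          nearest-center assignment on separable data", {
  set.seed(305)
  truth <- rep(1:2, each = 1500)
  a <- c(rvonmises(1500, -60, 40), rvonmises(1500, 100, 40))
  b <- c(rvonmises(1500, 20, 40), rvonmises(1500, -150, 40))
  cl <- cluster_torsions_2d(a, b)
  expect_equal(nrow(cl$clusters), 2L)
  # brute-force oracle: assign to the nearest planted center on the torus
  cen <- rbind(c(-60, 20), c(100, -150))
  oracle <- apply(cbind(a, b), 1, function(p)
    which.min(circ_diff(p[1], cen[, 1])^2 + circ_diff(p[2], cen[, 2])^2))
  # identify cluster ids with planted ids via their centers
  map <- vapply(seq_len(2), function(k)
    which.min(circ_diff(cl$clusters$center_a[k], cen[, 1])^2 +
              circ_diff(cl$clusters$center_b[k], cen[, 2])^2), integer(1))
  expect_equal(unname(map[cl$labels]), unname(oracle))
  expect_equal(unname(map[truth]), unname(map[truth]))  # sanity: map is a bijection
  expect_setequal(map, 1:2)
})

test_that("degenerate all-identical input collapses to a single cluster", {
  cl <- cluster_torsions_2d(rep(10, 20), rep(-20, 20))
  expect_equal(nrow(cl$clusters), 1L)
  expect_true(all(cl$labels == 1L))
  expect_equal(cl$clusters$center_a, 10)
})

test_that("water-site coordinates are exact and rigid-motion invariant", {
  # planted placement at (4.30 A, 240 deg)
  spec <- toy_site_spec(water_r = 4.30, water_theta = 240)
  toy <- build_toy_active_site(spec)
  w <- water_site_coordinates(toy$model, "A:301:C4", "A:301:C5",
                              "S:401:O", "S:401:D1", "S:401:D2")
  expect_equal(w$r, 4.30, tolerance = 1e-9)
  expect_lt(abs(circ_diff(w$theta, 240)), 1e-9)
  set.seed(306)
  moved <- toy$model
  moved$xyz[, , 1] <- rigid_motion(coords(toy$model))
  w2 <- water_site_coordinates(moved, "A:301:C4", "A:301:C5",
                               "S:401:O", "S:401:D1", "S:401:D2")
  expect_equal(w2$r, w$r, tolerance = 1e-9)
  expect_lt(abs(circ_diff(w2$theta, w$theta)), 1e-9)
  # missing hydrogen -> error, no heavy-atom fallback
  expect_error(water_site_coordinates(toy$model, "A:301:C4", "A:301:C5",
                                      "S:401:O", "S:401:D1", "S:402:D9"),
               "matches no atoms")
})

test_that("residence occupancy equals the brute-force count and segments match rle", {
  w <- data.frame(r = c(3.5, 3.5, 4.5, 4.5, 4.5, 3.2, 4.8, 3.0, 3.0, 3.0))
  tr <- residence_trace(w, 4.0)
  expect_equal(tr$occupancy, sum(w$r <= 4) / nrow(w))
  expect_equal(tr$segments$length, c(2, 3, 1, 1, 3))
  expect_equal(tr$segments$state, c("in", "out", "in", "out", "in"))
  expect_equal(tr$mean_inside_segment, mean(c(2, 1, 3)))
  expect_equal(residence_trace(data.frame(r = rep(3.5, 7)), 4.0)$occupancy, 1)
  expect_error(residence_trace(w, -1), "r_threshold")
})

test_that("planted two-state dwell segments are recovered from coordinates", {
  spec <- ensemble_spec(n = 2000, seed = 22, p_major_to_minor = 0.02,
                        p_minor_to_major = 0.06)
  ens <- generate_ensemble(spec)
  w <- water_site_coordinates(ens$model, "A:301:C4", "A:301:C5",
                              "S:401:O", "S:401:D1", "S:401:D2")
  tr <- residence_trace(w, 4.0)
  manifest_occ <- mean(ens$manifest$water_r <= 4.0)
  expect_equal(tr$occupancy, manifest_occ, tolerance = 1e-12)
  man_seg <- rle(ens$manifest$water_r <= 4.0)
  expect_equal(tr$segments$length, man_seg$lengths)
})

test_that("state coupling: null case is near OR = 1, perfect coupling is flagged", {
  set.seed(307)
  n <- 4000
  lab <- sample(1:2, n, replace = TRUE)
  tr0 <- residence_trace(data.frame(r = ifelse(runif(n) < 0.5, 3.5, 4.5)), 4.0)
  sc0 <- state_coupling(lab, tr0)
  expect_gt(sc0$odds_ratio, 0.8); expect_lt(sc0$odds_ratio, 1.25)
  expect_false(sc0$degenerate)
  # perfectly coupled
  tr1 <- residence_trace(data.frame(r = ifelse(lab == 1, 3.5, 4.5)), 4.0)
  sc1 <- state_coupling(lab, tr1)
  expect_true(sc1$degenerate)
  # zero cells drive the odds ratio to 0 or Inf depending on the reference
  expect_true(is.infinite(sc1$odds_ratio) || sc1$odds_ratio == 0)
  # counts match a brute-force table exactly
  expect_equal(as.vector(sc1$table),
               c(sum(lab == 1), 0, 0, sum(lab == 2)))
  expect_error(state_coupling(rep(0L, n), tr0), "no assigned frames")
})
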