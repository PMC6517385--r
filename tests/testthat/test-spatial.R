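test_that("gaussian diffusion conserves mass and has semigroup structure", {
  set.seed(3)
  field <- matrix(stats::runif(50 * 10), 50, 10)
  out <- diffuse_field(field, 1.5)
  expect_equal(sum(out), sum(field), tolerance = 1e-12)
  expect_true(all(out >= 0))
  # sigma = 0 is the identity
  expect_equal(diffuse_field(field, 0), field)
  # a uniform field is a fixed point (reflecting walls)
  unif <- matrix(2, 30, 8)
  expect_equal(diffuse_field(unif, 2), unif, tolerance = 1e-12)
  # n steps of width sigma equal one kernel of width sqrt(n)*sigma on a
  # point mass away from the walls
  pm <- matrix(0, 81, 81); pm[41, 41] <- 1
  four <- pm
  for (i in 1:4) four <- diffuse_field(four, 1.2)
  once <- diffuse_field(pm, sqrt(4) * 1.2)
  expect_lt(max(abs(four - once)), 1e-3)
})

test_that("reaction step produces on the reservoir and decays globally", {
  cfg <- spatial_config(nx = 20, ny = 5, reservoir_cols = 1:4,
                        prod_rate = 10, mu = 0.1, lambda = 0, seed = 1)
  f0 <- matrix(1, 20, 5)
  f1 <- react_field(f0, cfg, t = 0)
  added <- matrix(0, 20, 5); added[1:4, ] <- 10 * cfg$dt
  expect_equal(f1, (f0 + added) * exp(-0.1 * cfg$dt), tolerance = 1e-12)
  # no production: pure exponential decay of total mass
  cfg0 <- spatial_config(nx = 20, ny = 5, reservoir_cols = integer(0),
                         prod_rate = 0, mu = 0.1, lambda = 0, seed = 1)
  expect_equal(sum(react_field(f0, cfg0)), sum(f0) * exp(-0.1 * cfg0$dt))
  # fuel factor kills production at late times
  cfgf <- spatial_config(nx = 20, ny = 5, reservoir_cols = 1:4,
                         prod_rate = 10, mu = 0, lambda = 0.01, seed = 1)
  late <- react_field(matrix(0, 20, 5), cfgf, t = 2000)
  expect_lt(sum(late), 10 * cfgf$dt * 4 * 5 * exp(-15))
})

test_that("colloids never bind without RNA and stop rebinding at high exposure", {
  cfg <- spatial_config(nx = 30, ny = 6, n_colloids = 100, seed = 2)
  state <- list(x = sample.int(30, 100, TRUE), y = sample.int(6, 100, TRUE),
                bound = rep(FALSE, 100), h = rep(0, 100))
  zero <- matrix(0, 30, 6)
  set.seed(7)
  for (i in 1:20) state <- update_colloids(state, zero, cfg)
  expect_false(any(state$bound))
  expect_true(all(state$h == 0))
  # saturating RNA binds colloids in contact when history is clean ...
  rich <- matrix(1e4, 30, 6)
  packed <- list(x = rep(1:10, each = 10), y = rep(1:5, 20),
                 bound = rep(FALSE, 100), h = rep(0, 100))
  s1 <- update_colloids(packed, rich, cfg)
  expect_true(any(s1$bound))
  # ... but an enormous exposure keeps them detached
  burned <- packed
  burned$h <- rep(1e9, 100)
  s2 <- update_colloids(burned, rich, cfg)
  expect_false(any(s2$bound))
})

test_that("chamber runs are seed-deterministic and need a reservoir", {
  cfg <- spatial_config(nx = 60, ny = 8, n_colloids = 300, t_end = 40,
                        seed = 4)
  r1 <- run_chamber(cfg)
  r2 <- run_chamber(cfg)
  expect_identical(r1$agg, r2$agg)
  expect_identical(r1$rna_mean, r2$rna_mean)
  none <- spatial_config(nx = 60, ny = 8, reservoir_cols = integer(0),
                         n_colloids = 300, t_end = 40, seed = 4)
  r0 <- run_chamber(none)
  expect_true(all(r0$agg == 0))
  expect_true(all(r0$rna_mean == 0))
})

test_that("aggregation front reaches near columns before far ones", {
  cfg <- spatial_config(t_end = 120, lambda = 0, seed = 1)
  rec <- run_chamber(cfg)
  fr <- front_direction(rec, c(40, 80))
  expect_lt(fr$probes$onset[1], fr$probes$onset[2])
})

test_that("history gain flips the disintegration front direction", {
  fr0 <- front_direction(run_chamber(spatial_config(beta = 0, seed = 1)),
                         c(40, 80))
  expect_equal(fr0$direction, "backward")
  fr1 <- front_direction(run_chamber(spatial_config(beta = 0.05, seed = 1)),
                         c(40, 80))
  expect_equal(fr1$direction, "forward")
})

test_that("front classification follows the offset ordering rule", {
  fake <- structure(list(times = seq(4, 400, by = 4),
                         agg = NULL, rna_mean = NULL,
                         config = NULL), class = "spacetime_record")
  mk <- function(on1, off1, on2, off2) {
    agg <- matrix(0, 100, 120)
    agg[fake$times >= on1 & fake$times <= off1, 60] <- 1
    agg[fake$times >= on2 & fake$times <= off2, 100] <- 1
    fake$agg <- agg
    fake
  }
  expect_equal(front_direction(mk(20, 100, 40, 140), c(60, 100))$direction,
               "forward")
  expect_equal(front_direction(mk(20, 140, 40, 100), c(60, 100))$direction,
               "backward")
  expect_equal(front_direction(mk(20, 100, 40, 100), c(60, 100))$direction,
               "simultaneous")
  empty <- mk(20, 100, 40, 140)
  empty$agg[] <- 0
  expect_error(front_direction(empty, c(60, 100)), "aggregates")
})

test_that("uniform production reduces to the well-mixed kinetics", {
  cfg <- spatial_config(nx = 40, ny = 10, reservoir_cols = 1:40,
                        prod_rate = 5, dt = 0.05, n_colloids = 0,
                        t_end = 100, record_every = 20, seed = 1)
  rec <- run_chamber(cfg)
  p <- kinetic_params(k1 = 5 / (2 * 5 * 100), k2 = cfg$mu / 0.19,
                      k3 = cfg$lambda / (2 * 5))
  cf <- closed_form_rna(p, rec$times)
  latt <- rowMeans(rec$rna_mean)
  expect_lt(max(abs(latt - cf)) / max(cf), 0.02)
})

test_that("configuration guards reject unstable settings", {
  expect_error(spatial_config(D = 0.1), "0.3")
  expect_error(spatial_config(mu = 0.5, dt = 0.5), "0.2")
  expect_error(spatial_config(theta_on = 10, theta_off = 20), "theta_off")
  expect_error(spatial_config(reservoir_cols = 500), "range")
})
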