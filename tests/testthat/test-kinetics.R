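test_that("rate functions evaluate the mass-action balance exactly", {
  p <- kinetic_params(k1 = 1, k2 = 1, k3 = 1, t7 = 1, temp = 1, rnaseh = 1,
                      ntp0 = 2)
  expect_equal(rna_rate(conc_state(0, rna = 0, ntp = 0), p), 0)
  expect_equal(rna_rate(conc_state(0, rna = 1, ntp = 2), p), 1)
  # steady-state balance: production = degradation
  rna_ss <- 1 * 1 * 1 * 2 / (1 * 1)
  expect_equal(rna_rate(conc_state(0, rna = rna_ss, ntp = 2), p), 0)
  expect_equal(ntp_rate(conc_state(0, rna = 0, ntp = 4), p), -4)
  expect_equal(ntp_rate(conc_state(0, rna = 5, ntp = 0), p), 0)
  p0 <- kinetic_params(k3 = 0)
  expect_equal(ntp_rate(conc_state(0, rna = 1, ntp = 50), p0), 0)
  expect_error(conc_state(0, rna = -1, ntp = 0), ">= 0")
})

test_that("closed form matches its special cases and limits", {
  expect_equal(closed_form_rna(params_from_lumped(1, 0, 0, ntp0 = 1), 0), 0)
  p <- kinetic_params(rna0 = 7)
  expect_equal(closed_form_rna(p, 0), 7)
  # pure production: linear ramp
  expect_equal(closed_form_rna(params_from_lumped(2, 0, 0), 3), 6)
  # distinct rates: A=1, lam=1, mu=2 at t = ln 2 gives exactly 1/4
  expect_equal(closed_form_rna(params_from_lumped(1, 1, 2), log(2)), 0.25,
               tolerance = 1e-12)
  # confluent limit mu = lambda = 1: A*t*exp(-t) = exp(-1) at t = 1
  expect_equal(closed_form_rna(params_from_lumped(1, 1, 1), 1), exp(-1),
               tolerance = 1e-9)
  expect_error(closed_form_rna(p, -1), ">= 0")
})

test_that("numerical integration agrees with the closed form on a rate sweep", {
  grid <- seq(0, 120, by = 1)
  vals <- c(0, 0.01, 0.1, 1)
  set.seed(11)
  combos <- expand.grid(A = vals, lam = vals, mu = vals)
  combos <- combos[sample(nrow(combos), 24), ]
  for (i in seq_len(nrow(combos))) {
    p <- params_from_lumped(combos$A[i], combos$lam[i], combos$mu[i])
    traj <- simulate_pulse(p, grid)
    cf <- closed_form_rna(p, grid)
    scale <- max(cf, 1e-12)
    expect_lt(max(abs(traj$rna - cf)) / scale, 1e-6)
    expect_true(all(diff(traj$ntp) <= 1e-8))   # solver round-off at lam = 0
    expect_true(all(traj$rna >= 0))
  }
})

test_that("simulate_pulse validates its grid and rejects bad input", {
  p <- kinetic_params()
  expect_error(simulate_pulse(p, c(0, 1, 1)), "strictly increasing")
  expect_error(simulate_pulse(p, c(5, 6)), "start at 0")
  expect_error(kinetic_params(k1 = -1), ">= 0")
  expect_error(kinetic_params(k1 = NaN), "finite")
})

test_that("steady state and peak time match fine-grid numerical search", {
  expect_equal(steady_state(params_from_lumped(1, 0, 1)), 1)
  expect_equal(steady_state(params_from_lumped(0, 0, 0)), 0)
  expect_equal(steady_state(params_from_lumped(3, 0, 0.5)), 6)
  expect_true(is.na(steady_state(params_from_lumped(2, 0, 0))))
  # peak times against brute-force argmax of the closed form
  for (rates in list(c(1, 2), c(1, 1), c(0.02, 0.05))) {
    p <- params_from_lumped(1, rates[1], rates[2])
    tp <- peak_time(p)
    tgrid <- seq(0, 10 / min(rates), length.out = 1e5)
    tp_num <- tgrid[which.max(closed_form_rna(p, tgrid))]
    expect_equal(tp, tp_num, tolerance = 1e-3)
  }
  expect_true(is.na(peak_time(params_from_lumped(1, 0, 1))))
  expect_true(is.na(peak_time(params_from_lumped(1, 0.1, 0))))
})

test_that("initial production slope is proportional to the NTP pool", {
  base <- kinetic_params(ntp0 = 50)
  doubled <- kinetic_params(ntp0 = 100)
  s1 <- rna_rate(conc_state(0, 0, base$ntp0), base)
  s2 <- rna_rate(conc_state(0, 0, doubled$ntp0), doubled)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("pulse metrics interpolate crossings linearly", {
  flat <- rna_trajectory(0:10, rep(0.5, 11), rep(NA_real_, 11))
  pm <- pulse_metrics(flat, 1)
  expect_false(pm$crossed)
  expect_equal(pm$lifetime, 0)
  tri <- rna_trajectory(c(0, 1, 2), c(0, 2, 0), rep(NA_real_, 3))
  pm <- pulse_metrics(tri, 1)
  expect_true(pm$crossed)
  expect_equal(pm$onset_time, 0.5)
  expect_equal(pm$offset_time, 1.5)
  expect_equal(pm$lifetime, 1)
  expect_equal(pm$peak_value, 2)
  expect_error(pulse_metrics(tri, 0), "> 0")
  expect_error(pulse_metrics(tri[0, ], 1), "empty")
})

test_that("lifetime on a working grid matches a dense-grid oracle within 1%", {
  p <- params_from_lumped(1, 0.02, 0.05)
  dense <- seq(0, 400, length.out = 1e5)
  dense_traj <- rna_trajectory(dense, closed_form_rna(p, dense),
                               rep(NA_real_, length(dense)))
  thr <- max(dense_traj$rna) / 2
  life_oracle <- pulse_metrics(dense_traj, thr)$lifetime
  work <- simulate_pulse(p, seq(0, 400, by = 1))
  life <- pulse_metrics(work, thr)$lifetime
  expect_lt(abs(life - life_oracle) / life_oracle, 0.01)
})

test_that("fuel bookkeeping closes and improves with grid refinement", {
  p <- kinetic_params()
  fine <- simulate_pulse(p, seq(0, 180, length.out = 1000))
  expect_lt(ntp_mass_balance(fine, p), 1e-6)
  p0 <- kinetic_params(k3 = 0)
  traj0 <- simulate_pulse(p0, seq(0, 60, by = 1))
  expect_equal(ntp_mass_balance(traj0, p0), 0)
  coarse <- simulate_pulse(p, seq(0, 180, length.out = 10))
  expect_gte(ntp_mass_balance(coarse, p), ntp_mass_balance(fine, p))
  expect_error(ntp_mass_balance(fine, kinetic_params(k1 = 0)), "k1")
})

test_that("pulse family is monotone in the degradation rate", {
  mus <- 0.02 * 10^seq(0, 1, length.out = 5)
  peak_v <- peak_t <- life <- numeric(length(mus))
  for (i in seq_along(mus)) {
    p <- params_from_lumped(5, 0.01, mus[i], ntp0 = 100)
    traj <- simulate_pulse(p, seq(0, 600, by = 0.5))
    pm <- pulse_metrics(traj, 10)
    peak_v[i] <- pm$peak_value; peak_t[i] <- pm$peak_time
    life[i] <- pm$lifetime
  }
  expect_true(all(diff(peak_v) < 0))
  expect_true(all(diff(peak_t) < 0))
  expect_true(all(diff(life) < 0))
})

test_that("fuel limitation makes the pulse transient", {
  p <- kinetic_params()
  lr <- lumped_rates(p)
  long <- seq(0, 2000, by = 2)
  with_fuel <- simulate_pulse(p, long, consume_fuel = TRUE)
  expect_lt(with_fuel$rna[length(long)], 0.01 * max(with_fuel$rna))
  without <- simulate_pulse(p, long, consume_fuel = FALSE)
  expect_equal(without$rna[length(long)], lr[["A"]] / lr[["mu"]],
               tolerance = 1e-3)
})
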