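# Fuel-limited production/degradation kinetics of the RNA linker.
#
# The model is a pair of linear ODEs:
#   d[RNA]/dt = k1 * T7 * Temp * [NTP] - k2 * RNaseH * [RNA]
#   d[NTP]/dt = -k3 * [NTP] * T7 * Temp
# with RNA (and template) in nM, NTP in uM, enzyme activities in U/ul and
# time in min.  Lumping the constant factors gives
#   A      = k1 * t7 * temp * ntp0   (initial production rate, nM/min)
#   lambda = k3 * t7 * temp          (fuel consumption rate, 1/min)
#   mu     = k2 * rnaseh             (degradation rate, 1/min)
# so that rna'(t) = A * exp(-lambda t) - mu * rna(t), which admits the
# double-exponential closed form used throughout as the reference solution.

#' Kinetic parameters of the enzymatic production/degradation system
#'
#' Bundles the rate constants and experimental settings of the linker
#' synthesis (T7 RNA polymerase acting on a dsDNA template, consuming NTP
#' fuel) and degradation (RNaseH acting on DNA-bound RNA).
#'
#' The default rate constants are illustrative: the published model curves
#' were fitted to fluorescence data whose fitted constants are not printed,
#' so defaults here are chosen to place the transient pulse peak near 60 min
#' at `rnaseh = 0.19` U/ul with a peak concentration near 100 nM, matching
#' the reported qualitative behaviour of the system.
#'
#' @param k1 Production rate constant, nM RNA per min per (U/ul T7) per
#'   (nM template) per (uM NTP).
#' @param k2 Degradation rate constant, 1/min per (U/ul RNaseH).
#' @param k3 Fuel consumption rate constant, 1/min per (U/ul T7) per
#'   (nM template).  Proportional to the number of nucleotides built into
#'   one linker strand.
#' @param t7 T7 RNA polymerase activity (U/ul).
#' @param temp dsDNA template concentration (nM).
#' @param rnaseh RNaseH activity (U/ul).
#' @param ntp0 Initial NTP fuel concentration (uM).
#' @param rna0 Initial RNA linker concentration (nM).
#' @return An object of class `kinetic_params`.
#' @seealso [lumped_rates()], [simulate_pulse()], [closed_form_rna()]
#' @examples
#' p <- kinetic_params()
#' lumped_rates(p)
#' @export
kinetic_params <- function(k1 = 0.005, k2 = 0.135, k3 = 0.001,
                           t7 = 2, temp = 5, rnaseh = 0.19,
                           ntp0 = 100, rna0 = 0) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, t7 = t7, temp = temp,
            rnaseh = rnaseh, ntp0 = ntp0, rna0 = rna0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number")
    if (v < 0) stop("'", nm, "' must be >= 0")
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  lr <- lumped_rates(x)
  cat("Kinetic parameters (production/degradation/fuel consumption)\n")
  cat(sprintf("  k1 = %g, k2 = %g, k3 = %g\n", x$k1, x$k2, x$k3))
  cat(sprintf("  T7 = %g U/ul, template = %g nM, RNaseH = %g U/ul\n",
              x$t7, x$temp, x$rnaseh))
  cat(sprintf("  NTP0 = %g uM, RNA0 = %g nM\n", x$ntp0, x$rna0))
  cat(sprintf("  lumped: A = %g nM/min, lambda = %g /min, mu = %g /min\n",
              lr[["A"]], lr[["lambda"]], lr[["mu"]]))
  invisible(x)
}

#' Lumped rates of the linear pulse model
#'
#' @param p A [kinetic_params()] object.
#' @return Named numeric vector with `A` (initial production rate, nM/min),
#'   `lambda` (fuel consumption rate, 1/min) and `mu` (degradation rate,
#'   1/min).
#' @export
lumped_rates <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  c(A = p$k1 * p$t7 * p$temp * p$ntp0,
    lambda = p$k3 * p$t7 * p$temp,
    mu = p$k2 * p$rnaseh)
}

#' Instantaneous concentration state
#'
#' @param t Time (min).
#' @param rna RNA linker concentration (nM).
#' @param ntp NTP fuel concentration (uM).
#' @return An object of class `conc_state`.
#' @export
conc_state <- function(t = 0, rna = 0, ntp = 0) {
  if (rna < 0 || ntp < 0) stop("concentrations must be >= 0")
  structure(list(t = t, rna = rna, ntp = ntp), class = "conc_state")
}

#' Net RNA production rate
#'
#' Evaluates the right-hand side of the RNA balance,
#' `k1*t7*temp*ntp - k2*rnaseh*rna`, in nM/min.
#'
#' @param state A [conc_state()].
#' @param p A [kinetic_params()].
#' @return Net rate of RNA change (nM/min).
#' @export
rna_rate <- function(state, p) {
  stopifnot(inherits(state, "conc_state"), inherits(p, "kinetic_params"))
  p$k1 * p$t7 * p$temp * state$ntp - p$k2 * p$rnaseh * state$rna
}

#' NTP fuel consumption rate
#'
#' Evaluates `-k3*ntp*t7*temp` (uM/min); always non-positive.
#'
#' @inheritParams rna_rate
#' @return Rate of NTP change (uM/min).
#' @export
ntp_rate <- function(state, p) {
  stopifnot(inherits(state, "conc_state"), inherits(p, "kinetic_params"))
  -p$k3 * state$ntp * p$t7 * p$temp
}

#' Construct an RNA trajectory object
#'
#' @param times Strictly increasing time grid (min).
#' @param rna RNA concentrations (nM).
#' @param ntp NTP concentrations (uM).
#' @return A data frame of class `rna_trajectory` with columns `times`,
#'   `rna` and `ntp`.
#' @export
rna_trajectory <- function(times, rna, ntp) {
  if (length(times) < 1L || length(rna) != length(times) ||
      length(ntp) != length(times))
    stop("'times', 'rna' and 'ntp' must have equal positive length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(data.frame(times = times, rna = rna, ntp = ntp),
            class = c("rna_trajectory", "data.frame"))
}

#' Simulate the RNA pulse by numerical integration
#'
#' Integrates the production/degradation system with (optionally) the fuel
#' consumption equation, using an adaptive solver (deSolve, `lsoda`) with
#' rtol 1e-8 / atol 1e-10.  With `consume_fuel = FALSE` the NTP pool is
#' frozen at `ntp0` and only the RNA equation is integrated.
#'
#' @param p A [kinetic_params()].
#' @param t_grid Strictly increasing output grid starting at 0 (min).
#' @param consume_fuel Logical; include the NTP depletion equation.
#' @return An [rna_trajectory()].
#' @examples
#' traj <- simulate_pulse(kinetic_params(), seq(0, 180, by = 1))
#' pulse_metrics(traj, threshold = 50)
#' @export
simulate_pulse <- function(p, t_grid = seq(0, 180, by = 0.5),
                           consume_fuel = TRUE) {
  stopifnot(inherits(p, "kinetic_params"))
  if (length(t_grid) < 2L || any(!is.finite(t_grid)))
    stop("'t_grid' must be a finite grid with >= 2 points")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  if (t_grid[1] != 0) stop("'t_grid' must start at 0")

  kprod <- p$k1 * p$t7 * p$temp
  mu <- p$k2 * p$rnaseh
  lam <- if (consume_fuel) p$k3 * p$t7 * p$temp else 0

  rhs <- function(t, y, parms) {
    list(c(kprod * y[2] - mu * y[1], -lam * y[2]))
  }
  out <- deSolve::ode(y = c(rna = p$rna0, ntp = p$ntp0), times = t_grid,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  rna <- pmax(out[, "rna"], 0)   # guard against solver round-off at ~0
  rna_trajectory(out[, "time"], as.numeric(rna), as.numeric(out[, "ntp"]))
}

# switch tolerance between the generic double exponential and its
# confluent (mu == lambda) limit; avoids catastrophic cancellation
.mu_lambda_tol <- function(mu, lam) 1e-10 * max(mu, lam, 1)

#' Closed-form RNA concentration of the pulse model
#'
#' Analytic solution of the linear system:
#' `rna0*exp(-mu t) + A*(exp(-lambda t) - exp(-mu t))/(mu - lambda)` for
#' `mu != lambda`, with the confluent limit
#' `rna0*exp(-lambda t) + A*t*exp(-lambda t)` when `|mu - lambda|` falls
#' below `1e-10 * max(mu, lambda, 1)`, and the exact linear ramp
#' `rna0 + A*t` when both rates vanish.
#'
#' @param p A [kinetic_params()].
#' @param t Time or vector of times (min), all `>= 0`.
#' @param consume_fuel Logical; if `FALSE`, `lambda` is treated as 0
#'   (unlimited fuel).
#' @return RNA concentration(s) in nM.
#' @export
closed_form_rna <- function(p, t, consume_fuel = TRUE) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  lr <- lumped_rates(p)
  A <- lr[["A"]]; mu <- lr[["mu"]]
  lam <- if (consume_fuel) lr[["lambda"]] else 0
  if (mu == 0 && lam == 0) {
    p$rna0 + A * t
  } else if (abs(mu - lam) < .mu_lambda_tol(mu, lam)) {
    p$rna0 * exp(-lam * t) + A * t * exp(-lam * t)
  } else {
    p$rna0 * exp(-mu * t) + A * (exp(-lam * t) - exp(-mu * t)) / (mu - lam)
  }
}

#' Steady-state RNA level without fuel limitation
#'
#' With unlimited fuel the system relaxes to the balance point `A/mu`
#' (production equals degradation).  Without degradation the RNA grows
#' without bound and no steady state exists.
#'
#' @param p A [kinetic_params()].
#' @return `A/mu` (nM) when `mu > 0`; `NA_real_` when `mu = 0` and `A > 0`
#'   (unbounded growth); `0` when `A = 0` and `mu = 0`.
#' @export
steady_state <- function(p) {
  lr <- lumped_rates(p)
  if (lr[["mu"]] > 0) return(lr[["A"]] / lr[["mu"]])
  if (lr[["A"]] == 0) 0 else NA_real_
}

#' Time of the pulse maximum
#'
#' For `rna0 = 0` the closed form peaks at `log(mu/lambda)/(mu - lambda)`
#' (confluent limit `1/lambda` when `mu == lambda`).  When either rate is
#' zero the trajectory is monotone and no interior peak exists.
#'
#' @param p A [kinetic_params()].
#' @return Peak time in min, or `NA_real_` when there is no interior
#'   maximum.
#' @export
peak_time <- function(p) {
  lr <- lumped_rates(p)
  mu <- lr[["mu"]]; lam <- lr[["lambda"]]
  if (mu == 0 || lam == 0) return(NA_real_)
  if (abs(mu - lam) < .mu_lambda_tol(mu, lam)) 1 / lam
  else log(mu / lam) / (mu - lam)
}

# linear-interpolation crossing times of `values` through `threshold`
# on grid `times`; returns list(up = first up-crossing, down = last
# down-crossing).  Values exactly at threshold count as above.
.crossing_times <- function(times, values, threshold) {
  above <- values >= threshold
  if (!any(above)) return(list(up = NA_real_, down = NA_real_))
  interp <- function(i) {
    # crossing between grid points i and i+1
    times[i] + (threshold - values[i]) / (values[i + 1] - values[i]) *
      (times[i + 1] - times[i])
  }
  first_up <- if (above[1]) {
    times[1]
  } else {
    i <- which(!above[-length(above)] & above[-1])[1]
    interp(i)
  }
  n <- length(values)
  last_down <- if (above[n]) {
    times[n]
  } else {
    i <- which(above[-n] & !above[-1])
    interp(i[length(i)])
  }
  list(up = first_up, down = last_down)
}

#' Pulse descriptors of a trajectory
#'
#' Locates the first up-crossing and last down-crossing of a threshold
#' (linear interpolation between grid points; values exactly at the
#' threshold count as crossed) and the grid maximum.  The lifetime is the
#' offset-minus-onset interval during which the signal exceeds the
#' threshold.
#'
#' @param traj An [rna_trajectory()] or any data frame with `times` and a
#'   value column named `rna`.
#' @param threshold Positive threshold in the units of the value column.
#' @return An object of class `pulse_metrics`: list with `crossed`,
#'   `onset_time`, `peak_time`, `offset_time`, `peak_value`, `lifetime`.
#' @export
pulse_metrics <- function(traj, threshold) {
  if (NROW(traj) == 0L) stop("empty trajectory")
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  times <- traj$times
  vals <- traj$rna
  ipk <- which.max(vals)
  if (max(vals) < threshold) {
    return(structure(list(crossed = FALSE, onset_time = NA_real_,
                          peak_time = NA_real_, offset_time = NA_real_,
                          peak_value = vals[ipk], lifetime = 0),
                     class = "pulse_metrics"))
  }
  cr <- .crossing_times(times, vals, threshold)
  structure(list(crossed = TRUE, onset_time = cr$up, peak_time = times[ipk],
                 offset_time = cr$down, peak_value = vals[ipk],
                 lifetime = cr$down - cr$up),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  if (!x$crossed) {
    cat(sprintf("Pulse never crossed threshold (peak %.3g nM)\n", x$peak_value))
  } else {
    cat(sprintf(paste0("Pulse: onset %.2f min, peak %.3g nM at %.2f min, ",
                       "offset %.2f min, lifetime %.2f min\n"),
                x$onset_time, x$peak_value, x$peak_time, x$offset_time,
                x$lifetime))
  }
  invisible(x)
}

#' Fuel bookkeeping residual of a simulated trajectory
#'
#' Checks that the NTP consumed along the trajectory equals `k3/k1` times
#' the cumulative RNA production (piecewise-quadratic quadrature of the
#' production term `k1*t7*temp*ntp(t)`); the two ODEs share the factor
#' `t7*temp*ntp(t)`, so the identity holds exactly for the continuous
#' system and the residual measures integrator consistency.
#'
#' @param traj An [rna_trajectory()] produced with fuel consumption on.
#' @param p The [kinetic_params()] used to produce it.
#' @return Maximum over the grid of the relative mass-balance residual
#'   (dimensionless, relative to `ntp0`).
#' @export
ntp_mass_balance <- function(traj, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$k1 == 0) stop("mass balance undefined for k1 = 0")
  if (p$ntp0 == 0) return(0)
  prod_rate <- p$k1 * p$t7 * p$temp * traj$ntp          # nM/min
  cum_prod <- .cum_quad(traj$times, prod_rate)          # nM produced
  consumed <- p$ntp0 - traj$ntp                         # uM consumed
  max(abs(consumed - (p$k3 / p$k1) * cum_prod)) / p$ntp0
}

# cumulative integral by piecewise-quadratic (three-point) quadrature;
# one order better than the trapezoid, which matters when the residual
# being measured is itself O(1e-6)
.cum_quad <- function(x, y) {
  n <- length(x)
  if (n < 3) {
    dt <- diff(x)
    return(c(0, cumsum(dt * (y[-n] + y[-1]) / 2)))
  }
  seg <- numeric(n - 1)
  quad_seg <- function(i0, i1, i2, a, b) {
    # integral over [a, b] of the parabola through the three points
    xi <- x[c(i0, i1, i2)]; yi <- y[c(i0, i1, i2)]
    cf <- solve(cbind(1, xi, xi^2), yi)
    (cf[1] * b + cf[2] * b^2 / 2 + cf[3] * b^3 / 3) -
      (cf[1] * a + cf[2] * a^2 / 2 + cf[3] * a^3 / 3)
  }
  seg[1] <- quad_seg(1, 2, 3, x[1], x[2])
  for (i in 2:(n - 1)) seg[i] <- quad_seg(i - 1, i, i + 1, x[i], x[i + 1])
  c(0, cumsum(seg))
}
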