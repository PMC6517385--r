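# Lattice reaction-diffusion simulation of the diffusion chamber.
#
# RNA linker is produced locally in a reservoir region (immobilised
# templates), diffuses into the channel (gaussian-kernel convolution with
# reflecting walls), and is degraded globally.  Colloids random-walk on
# the lattice, bind where the local linker concentration exceeds a
# threshold and a neighbouring colloid is available, and unbind when it
# falls below a lower threshold.  Each bound colloid accumulates an
# exposure variable h proportional to the local degradation flux; with
# history gain beta > 0 the effective thresholds grow as (1 + beta*h),
# so colloids near the source -- which saw the most degradation traffic --
# lose affinity first.  This history rule flips the disintegration front
# from backward (towards the source) to forward (into the channel), the
# behaviour observed experimentally.

#' Configuration of the chamber simulation
#'
#' @param nx,ny Lattice size; `nx` is the long (channel) axis.
#' @param dx Lattice spacing (um).
#' @param dt Time step (min).
#' @param D RNA diffusivity (um^2/min).
#' @param reservoir_cols Integer columns (x indices) where production
#'   occurs; templates are immobilised there.
#' @param prod_rate Local production rate on reservoir cells (nM/min).
#' @param mu Global degradation rate (1/min).
#' @param lambda Fuel consumption rate (1/min); production decays as
#'   `exp(-lambda*t)` when `lambda > 0` (fuel-limited pulse), and is
#'   constant when 0.
#' @param theta_on,theta_off Binding and unbinding thresholds (nM),
#'   `theta_off <= theta_on` (hysteresis).
#' @param beta History gain (dimensionless) multiplying the accumulated
#'   exposure; `beta = 0` disables the reduced-affinity rule.
#' @param n_colloids Number of colloids.
#' @param move_prob Probability that an unbound colloid attempts a
#'   lattice step per iteration.
#' @param t_end Simulated time (min).
#' @param record_every Record the aggregation state every this many
#'   steps (the cadence of the space-time record).
#' @param agg_window Half-width (columns) of the window over which the
#'   per-column bound fraction is computed.
#' @param seed RNG seed; the whole run is deterministic given the seed.
#' @return An object of class `spatial_config`.
#' @details Stability guards: the per-step diffusion kernel width
#'   `sigma = sqrt(2*D*dt)/dx` must be at least 0.3 cells (otherwise the
#'   sampled gaussian is too narrow to represent) and `mu*dt < 0.2`.
#' @export
spatial_config <- function(nx = 200, ny = 20, dx = 10, dt = 0.5, D = 6000,
                           reservoir_cols = 1:10, prod_rate = 100,
                           mu = 0.0256, lambda = 0.01,
                           theta_on = 50, theta_off = 25, beta = 0.05,
                           n_colloids = 2000, move_prob = 1,
                           t_end = 360, record_every = 4L,
                           agg_window = 2L, seed = 1L) {
  sigma <- sqrt(2 * D * dt) / dx
  if (sigma < 0.3)
    stop("sigma = sqrt(2*D*dt)/dx = ", round(sigma, 3),
         " cells is below the 0.3 stability guard")
  if (mu * dt >= 0.2)
    stop("mu*dt must be < 0.2 for the splitting scheme")
  if (theta_off > theta_on) stop("theta_off must be <= theta_on")
  if (length(reservoir_cols) &&
      (min(reservoir_cols) < 1 || max(reservoir_cols) > nx))
    stop("reservoir_cols out of range")
  structure(list(nx = nx, ny = ny, dx = dx, dt = dt, D = D, sigma = sigma,
                 reservoir_cols = as.integer(reservoir_cols),
                 prod_rate = prod_rate, mu = mu, lambda = lambda,
                 theta_on = theta_on, theta_off = theta_off, beta = beta,
                 n_colloids = n_colloids, move_prob = move_prob,
                 t_end = t_end, record_every = as.integer(record_every),
                 agg_window = as.integer(agg_window), seed = seed),
            class = "spatial_config")
}

# 1D convolution matrix for a sampled gaussian kernel with reflecting
# (no-flux) walls: every kernel tap falling outside the domain is folded
# back in, so each column sums to exactly 1 and mass is conserved to
# machine precision.
.conv_matrix <- function(n, sigma) {
  R <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-R:R, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    p <- j + (-R:R)
    while (any(p < 1 | p > n)) {
      p[p < 1] <- 1 - p[p < 1]          # reflect about the lower wall
      p[p > n] <- 2 * n + 1 - p[p > n]  # reflect about the upper wall
    }
    # p collides after reflection near walls; accumulate
    for (i in seq_along(p)) K[p[i], j] <- K[p[i], j] + w[i]
  }
  K
}

#' Diffuse an RNA field by one step
#'
#' Convolves the field with a gaussian kernel of standard deviation
#' `sigma = sqrt(2*D*dt)/dx` cells, separably in x and y, with
#' reflecting boundary treatment.  Total mass is conserved exactly.
#'
#' @param field Numeric `nx` by `ny` matrix (nM).
#' @param config A [spatial_config()] (only `sigma` is used), or a
#'   number interpreted as sigma directly.
#' @return The diffused field.
#' @export
diffuse_field <- function(field, config) {
  sigma <- if (inherits(config, "spatial_config")) config$sigma else config
  if (sigma == 0) return(field)
  Kx <- .conv_matrix(nrow(field), sigma)
  Ky <- .conv_matrix(ncol(field), sigma)
  Kx %*% field %*% t(Ky)
}

#' Apply production and degradation to an RNA field
#'
#' Adds `prod_rate * dt * exp(-lambda*t)` on the reservoir columns
#' (fuel-limited local production) and multiplies the whole field by
#' `exp(-mu*dt)` (global degradation).
#'
#' @param field Numeric `nx` by `ny` matrix (nM).
#' @param config A [spatial_config()].
#' @param t Current time (min), used for the fuel factor.
#' @return The updated field.
#' @export
react_field <- function(field, config, t = 0) {
  if (length(config$reservoir_cols))
    field[config$reservoir_cols, ] <- field[config$reservoir_cols, ] +
      config$prod_rate * config$dt * exp(-config$lambda * t)
  field * exp(-config$mu * config$dt)
}

# neighbour occupancy count: for each cell, number of colloids in the
# 8-neighbourhood (x wraps, y walls) plus co-occupants of the same cell
.neighbour_counts <- function(occ, nx, ny) {
  shift_x <- function(m, d) {
    if (d == 0) return(m)
    idx <- ((seq_len(nx) - 1 - d) %% nx) + 1
    m[idx, , drop = FALSE]
  }
  shift_y <- function(m, d) {
    if (d == 0) return(m)
    out <- matrix(0, nx, ny)
    if (d == 1) out[, 2:ny] <- m[, 1:(ny - 1)]
    else out[, 1:(ny - 1)] <- m[, 2:ny]
    out
  }
  nb <- matrix(0, nx, ny)
  for (dxs in -1:1) for (dys in -1:1) {
    if (dxs == 0 && dys == 0) next
    nb <- nb + shift_y(shift_x(occ, dxs), dys)
  }
  nb
}

#' Advance the colloid ensemble by one step
#'
#' Unbound colloids take one lattice random-walk step with probability
#' `move_prob` (periodic wrap along the channel axis, reflecting on the
#' short axis); bound colloids are frozen.  A colloid binds when the
#' local RNA is at least `theta_on * (1 + beta*h)` and another colloid
#' occupies its 8-neighbourhood (or the same cell); it unbinds when the
#' local RNA falls below `theta_off * (1 + beta*h)`.  While bound, the
#' exposure grows by `mu * rna_local * dt` -- the local degradation flux
#' of colloid-bound linkers, whose fragments block the docking strands.
#' All colloids update simultaneously from the post-move occupancy, so
#' the update is order-independent.
#'
#' @param state List with `x`, `y` (integer positions), `bound`
#'   (logical), `h` (exposure).
#' @param field RNA field (`nx` by `ny`).
#' @param config A [spatial_config()].
#' @return The updated state list.
#' @export
update_colloids <- function(state, field, config) {
  nx <- config$nx; ny <- config$ny
  n <- length(state$x)
  if (n == 0L) return(state)
  free <- !state$bound
  nfree <- sum(free)
  if (nfree > 0L && config$move_prob > 0) {
    moving <- free & (stats::runif(n) < config$move_prob)
    nm <- sum(moving)
    if (nm > 0L) {
      dir <- sample.int(4L, nm, replace = TRUE)
      dxs <- c(1L, -1L, 0L, 0L)[dir]
      dys <- c(0L, 0L, 1L, -1L)[dir]
      newx <- ((state$x[moving] - 1L + dxs) %% nx) + 1L
      newy <- state$y[moving] + dys
      blocked <- newy < 1L | newy > ny   # reflecting wall: stay put
      newy[blocked] <- state$y[moving][blocked]
      state$x[moving] <- newx
      state$y[moving] <- newy
    }
  }
  cell <- cbind(state$x, state$y)
  occ <- matrix(0, nx, ny)
  occ[] <- tabulate(state$x + nx * (state$y - 1L), nbins = nx * ny)
  nbm <- .neighbour_counts(occ, nx, ny)
  contact <- nbm[cell] + occ[cell] - 1 > 0
  rna_local <- field[cell]
  eff <- 1 + config$beta * state$h
  bind <- !state$bound & rna_local >= config$theta_on * eff & contact
  unbind <- state$bound & rna_local < config$theta_off * eff
  state$bound <- (state$bound | bind) & !unbind
  state$h <- state$h + ifelse(state$bound,
                              config$mu * rna_local * config$dt, 0)
  state
}

#' Run the chamber simulation
#'
#' Iterates diffusion, reaction and colloid updates from a zero RNA
#' field and uniformly scattered unbound colloids.  Deterministic given
#' `config$seed`.
#'
#' @param config A [spatial_config()].
#' @param snapshots Logical; keep RNA field snapshots at the record
#'   cadence.
#' @return An object of class `spacetime_record`: list with `times`
#'   (recorded times, min), `agg` (matrix, time by column: bound
#'   fraction in a `2*agg_window+1`-column window), `rna_mean` (matrix,
#'   time by column: column-averaged RNA, nM), optional `fields`, and
#'   the `config`.
#' @export
run_chamber <- function(config, snapshots = FALSE) {
  stopifnot(inherits(config, "spatial_config"))
  set.seed(config$seed)
  nx <- config$nx; ny <- config$ny
  field <- matrix(0, nx, ny)
  n <- config$n_colloids
  state <- list(x = sample.int(nx, n, replace = TRUE),
                y = sample.int(ny, n, replace = TRUE),
                bound = rep(FALSE, n), h = rep(0, n))
  Kx <- .conv_matrix(nx, config$sigma)
  Ky <- .conv_matrix(ny, config$sigma)
  n_steps <- ceiling(config$t_end / config$dt)
  rec_t <- c(); rec_agg <- list(); rec_rna <- list(); rec_field <- list()
  w <- config$agg_window
  for (step in seq_len(n_steps)) {
    t_now <- (step - 1) * config$dt
    field <- Kx %*% field %*% t(Ky)
    field <- react_field(field, config, t_now)
    state <- update_colloids(state, field, config)
    if (step %% config$record_every == 0L) {
      bound_per_col <- tabulate(state$x[state$bound], nbins = nx)
      all_per_col <- tabulate(state$x, nbins = nx)
      win_sum <- function(v) {
        cs <- cumsum(c(0, v))
        lo <- pmax(seq_len(nx) - w, 1); hi <- pmin(seq_len(nx) + w, nx)
        cs[hi + 1] - cs[lo]
      }
      bs <- win_sum(bound_per_col); as_ <- win_sum(all_per_col)
      frac <- ifelse(as_ > 0, bs / as_, 0)
      rec_t <- c(rec_t, step * config$dt)
      rec_agg[[length(rec_agg) + 1L]] <- frac
      rec_rna[[length(rec_rna) + 1L]] <- rowMeans(field)
      if (snapshots) rec_field[[length(rec_field) + 1L]] <- field
    }
  }
  structure(list(times = rec_t,
                 agg = do.call(rbind, rec_agg),
                 rna_mean = do.call(rbind, rec_rna),
                 fields = if (snapshots) rec_field else NULL,
                 config = config),
            class = "spacetime_record")
}

#' Direction of the disintegration front
#'
#' Extracts the aggregated-fraction time series at the probe columns,
#' finds the first and last times the fraction meets `frac_threshold`,
#' and classifies the disintegration front: `"forward"` if offset times
#' increase with distance from the source (disintegration starts near
#' the reservoir and travels into the channel), `"backward"` if they
#' decrease, `"simultaneous"` if all offsets agree within one record
#' cadence.
#'
#' @param record A `spacetime_record` from [run_chamber()].
#' @param probe_columns Two or more column indices at increasing
#'   distance from the reservoir.
#' @param frac_threshold Bound fraction counting as aggregated.
#' @return An object of class `front_report`: list with `probes` (data
#'   frame: column, onset, offset) and `direction`.
#' @export
front_direction <- function(record, probe_columns, frac_threshold = 0.3) {
  stopifnot(inherits(record, "spacetime_record"), length(probe_columns) >= 2)
  probe_columns <- sort(probe_columns)
  times <- record$times
  cadence <- if (length(times) > 1) times[2] - times[1] else 0
  probes <- lapply(probe_columns, function(col) {
    s <- record$agg[, col]
    above <- which(s >= frac_threshold)
    if (!length(above)) return(c(NA_real_, NA_real_))
    c(times[above[1]], times[above[length(above)]])
  })
  probes <- do.call(rbind, probes)
  if (all(is.na(probes[, 1]))) stop("no probe column ever aggregates")
  rep_df <- data.frame(column = probe_columns,
                       onset = probes[, 1], offset = probes[, 2])
  offs <- rep_df$offset[!is.na(rep_df$offset)]
  d <- diff(offs)
  direction <- if (all(abs(d) <= cadence)) "simultaneous"
               else if (all(d >= -cadence) && any(d > cadence)) "forward"
               else if (all(d <= cadence) && any(d < -cadence)) "backward"
               else "mixed"
  structure(list(probes = rep_df, direction = direction,
                 cadence = cadence, frac_threshold = frac_threshold),
            class = "front_report")
}

#' @export
print.front_report <- function(x, ...) {
  cat("Disintegration front:", x$direction, "\n")
  print(x$probes)
  invisible(x)
}
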