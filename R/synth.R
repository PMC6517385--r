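# Synthetic-data generators with known ground truth.
#
# Two raw-data modalities feed the analysis pipeline: intercalator-dye
# fluorescence time series (linear response plus template baseline,
# optional early heating-dip artefact, gaussian noise) and bright-field
# style grayscale micrographs (dark clusters on a light background).
# Every generator is deterministic per seed and returns the exact
# planted ground truth alongside the data, so calibration, fitting and
# image-analysis code can be validated end to end without any external
# data.

#' Generate a synthetic fluorescence trace
#'
#' The clean signal model is
#' `signal(t) = slope * (template_nM + rna(t) + phi * fragments(t)) -
#' dip(t) + noise`, where `rna(t)` is the closed-form pulse,
#' `fragments(t)` is the cumulative degraded RNA (trapezoidal integral
#' of `mu * rna`), `phi` in `[0, 1]` is the residual fluorescence of
#' degradation fragments, `dip(t) = dip_amplitude * exp(-t/dip_tau)` is
#' the early heating artefact, and the noise is gaussian with standard
#' deviation `noise_sd` times the clean signal (pointwise).
#'
#' @param params A [kinetic_params()].
#' @param t_grid Sampling grid (min).
#' @param slope Dye response (a.U. per nM).
#' @param template_nM Template concentration contributing to the
#'   baseline; defaults to `params$temp`.
#' @param noise_sd Noise level as a fraction of the clean signal.
#' @param dip_amplitude,dip_tau Heating-dip amplitude (a.U.) and decay
#'   time (min); amplitude 0 disables the artefact.
#' @param phi Fragment fluorescence factor in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `trace` (a [fluorescence_trace()] carrying the
#'   known settings in its metadata) and `truth` (list: `params`,
#'   `slope`, `rna`, `fragments`, `clean_signal`).
#' @export
synth_trace <- function(params = kinetic_params(),
                        t_grid = seq(0, 180, by = 1),
                        slope = 10, template_nM = NULL, noise_sd = 0.05,
                        dip_amplitude = 0, dip_tau = 8, phi = 0.3,
                        seed = 1L) {
  stopifnot(noise_sd >= 0, phi >= 0, phi <= 1)
  if (is.null(template_nM)) template_nM <- params$temp
  rna <- closed_form_rna(params, t_grid)
  mu <- lumped_rates(params)[["mu"]]
  dt <- diff(t_grid)
  frag <- c(0, cumsum(dt * mu * (rna[-length(rna)] + rna[-1]) / 2))
  clean <- slope * (template_nM + rna + phi * frag)
  dip <- if (dip_amplitude > 0) dip_amplitude * exp(-t_grid / dip_tau) else 0
  set.seed(seed)
  signal <- clean - dip + stats::rnorm(length(clean), sd = noise_sd * clean)
  trace <- fluorescence_trace(t_grid, signal, template_nM,
                              settings = list(t7 = params$t7,
                                              temp = params$temp,
                                              rnaseh = params$rnaseh,
                                              ntp0 = params$ntp0))
  list(trace = trace,
       truth = list(params = params, slope = slope, rna = rna,
                    fragments = frag, clean_signal = clean))
}

# grow a cluster shape as pixel offsets around (0, 0): a filled
# quasi-disc (pixels sorted by radius) or an Eden-like aggregate grown
# by attaching pixels to a random occupied-site neighbour
.cluster_offsets <- function(area, morphology) {
  if (morphology == "disc") {
    r <- ceiling(sqrt(area / pi)) + 2L
    g <- expand.grid(dx = -r:r, dy = -r:r)
    d2 <- g$dx^2 + g$dy^2
    ord <- order(d2, atan2(g$dy, g$dx))   # deterministic tie-break
    g[ord[seq_len(area)], , drop = FALSE]
  } else {
    taken <- matrix(FALSE, 2 * area + 1, 2 * area + 1)
    ctr <- area + 1L
    taken[ctr, ctr] <- TRUE
    px <- matrix(c(0L, 0L), ncol = 2)
    frontier <- matrix(c(ctr + 1L, ctr, ctr - 1L, ctr, ctr, ctr + 1L,
                         ctr, ctr - 1L), ncol = 2, byrow = TRUE)
    while (nrow(px) < area) {
      i <- sample.int(nrow(frontier), 1L)
      p <- frontier[i, ]
      frontier <- frontier[-i, , drop = FALSE]
      if (taken[p[1], p[2]]) next
      taken[p[1], p[2]] <- TRUE
      px <- rbind(px, p - ctr)
      for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        q <- p + s
        if (!taken[q[1], q[2]]) frontier <- rbind(frontier, q)
      }
    }
    data.frame(dx = px[, 1], dy = px[, 2])
  }
}

#' Generate a synthetic cluster micrograph
#'
#' Plants `n_clusters` non-overlapping clusters of the requested pixel
#' areas (quasi-disc or Eden-aggregate morphology) plus sub-resolution
#' background singlets on a light background, adds gaussian intensity
#' noise, and returns the image together with the exact planted
#' statistics.  Clusters are separated by at least `min_separation`
#' pixels so that connected-component labelling cannot merge them.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size um per pixel.
#' @param areas Integer vector of planted cluster areas (px); its length
#'   sets the number of clusters.
#' @param morphology `"disc"` or `"aggregate"`.
#' @param n_singlets Number of 1-2 px background specks (kept below any
#'   sensible `min_size` filter).
#' @param bg_level,fg_level Background and cluster intensities (bright
#'   field: clusters darker).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param min_separation Minimum empty margin between clusters (px).
#' @param max_retries Placement attempts per cluster before erroring.
#' @param seed RNG seed.
#' @return List with `image` (a [gray_image()]), `mask` (planted logical
#'   mask), and `truth` (list: `n_clusters`, `sizes`, `mean_size_au`,
#'   `mean_diameter_um`).
#' @export
synth_cluster_image <- function(width = 256, height = 256, pixel_size = 0.5,
                                areas = c(80, 120, 160, 200, 240),
                                morphology = c("disc", "aggregate"),
                                n_singlets = 20,
                                bg_level = 0.8, fg_level = 0.2,
                                noise_sd = 0.05, min_separation = 3,
                                max_retries = 1000, seed = 1L) {
  morphology <- match.arg(morphology)
  set.seed(seed)
  mask <- matrix(FALSE, height, width)
  blocked <- matrix(FALSE, height, width)   # mask dilated by the margin
  place <- function(offs) {
    for (try in seq_len(max_retries)) {
      cy <- sample.int(height, 1L); cx <- sample.int(width, 1L)
      ys <- cy + offs$dy; xs <- cx + offs$dx
      if (min(ys) < 2 || max(ys) > height - 1 ||
          min(xs) < 2 || max(xs) > width - 1) next
      if (any(blocked[cbind(ys, xs)])) next
      mask[cbind(ys, xs)] <<- TRUE
      m <- min_separation
      for (ddy in -m:m) for (ddx in -m:m) {
        yy <- pmin(pmax(ys + ddy, 1L), height)
        xx <- pmin(pmax(xs + ddx, 1L), width)
        blocked[cbind(yy, xx)] <<- TRUE
      }
      return(TRUE)
    }
    FALSE
  }
  sizes <- integer(0)
  for (a in areas) {
    offs <- .cluster_offsets(as.integer(a), morphology)
    if (!place(offs))
      stop("could not place cluster of ", a, " px after ", max_retries,
           " retries")
    sizes <- c(sizes, as.integer(a))
  }
  for (k in seq_len(n_singlets)) {
    offs <- data.frame(dx = 0L, dy = 0L)
    if (stats::runif(1) < 0.5) offs <- rbind(offs, c(1L, 0L))
    place(offs)   # silently skipped if the frame is too crowded
  }
  img <- matrix(bg_level, height, width)
  img[mask] <- fg_level
  img <- img + stats::rnorm(length(img), sd = noise_sd)
  truth <- list(n_clusters = length(sizes), sizes = sizes,
                mean_size_au = mean(sizes),
                mean_diameter_um = mean(2 * sqrt(sizes / pi)) * pixel_size)
  list(image = gray_image(img, pixel_size, polarity = "dark"),
       mask = mask, truth = truth)
}

#' Generate an image series following an RNA pulse
#'
#' Produces one synthetic micrograph per trajectory point, planting
#' clusters whose pixel area follows `mapping(rna(t))` (a monotone map
#' with `mapping(0)` equal to the singlet area), so the image-analysis
#' pipeline can be tested against a known aggregate-size pulse.
#'
#' @param traj An [rna_trajectory()] (typically subsampled to tens of
#'   frames).
#' @param mapping Monotone function from RNA (nM) to mean cluster area
#'   (px); default `2 + rna` px.
#' @param n_clusters Clusters planted per frame.
#' @param width,height,pixel_size,noise_sd,seed Passed to
#'   [synth_cluster_image()].
#' @return List with `frames` (list of [gray_image()]), and `truth`
#'   (data frame: `frame`, `time`, `rna`, `planted_area`).
#' @export
synth_pulse_frames <- function(traj, mapping = function(rna) 2 + rna,
                               n_clusters = 5, width = 192, height = 192,
                               pixel_size = 0.5, noise_sd = 0.05,
                               seed = 1L) {
  areas <- pmax(1L, as.integer(round(mapping(traj$rna))))
  frames <- vector("list", length(areas))
  for (i in seq_along(areas)) {
    sc <- synth_cluster_image(width = width, height = height,
                              pixel_size = pixel_size,
                              areas = rep(areas[i], n_clusters),
                              n_singlets = 0, noise_sd = noise_sd,
                              seed = seed + i)
    frames[[i]] <- sc$image
  }
  list(frames = frames,
       truth = data.frame(frame = seq_along(areas), time = traj$times,
                          rna = traj$rna, planted_area = areas))
}
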