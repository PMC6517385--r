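# Cluster-size statistics from bright-field micrographs.
#
# The aggregate-size statistic is deliberately simple: threshold the
# grayscale image to a binary mask, label connected components, and
# report the count and mean component area ("a.U." = pixels) together
# with the mean equivalent-disc diameter in micrometres.  Absolute a.U.
# values depend on magnification and threshold settings and are only
# comparable within a series; orderings and trends are the meaningful
# output.

#' Construct a grayscale image object
#'
#' @param mat Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size Physical pixel size (um per pixel).
#' @param polarity `"dark"` if clusters are darker than the background
#'   (bright field, the default) or `"light"` if brighter.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(mat, pixel_size = 1, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(mat) || !is.numeric(mat) || any(!is.finite(mat)))
    stop("'mat' must be a finite numeric matrix")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  structure(list(mat = mat, pixel_size = pixel_size, polarity = polarity),
            class = "gray_image")
}

#' Read a grayscale image from TIFF/PNG
#'
#' Thin wrapper over `EBImage::readImage`; multi-channel images are
#' averaged to one grayscale channel.
#'
#' @param path File path (TIFF or PNG).
#' @inheritParams gray_image
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size = 1,
                            polarity = c("dark", "light")) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1, 2), mean)
  gray_image(as.matrix(dat), pixel_size, match.arg(polarity))
}

#' Threshold an image to a binary cluster mask
#'
#' Pixels beyond the threshold in the polarity's direction (below for
#' dark-on-light bright field, above for light-on-dark) become
#' foreground.  `threshold = "otsu"` picks the threshold by Otsu's
#' method on the intensity histogram.  Applying [binarize()] to a mask
#' it produced returns the mask unchanged (idempotence).
#'
#' @param img A [gray_image()] (or a `binary_mask`, returned as is).
#' @param threshold Numeric intensity cutoff, or `"otsu"`.
#' @return A logical matrix of class `binary_mask` (TRUE = cluster).
#' @export
binarize <- function(img, threshold = "otsu") {
  if (inherits(img, "binary_mask")) return(img)
  stopifnot(inherits(img, "gray_image"))
  mat <- img$mat
  if (identical(threshold, "otsu")) {
    rng <- range(mat)
    if (diff(rng) == 0)
      stop("constant image: Otsu thresholding is undefined")
    norm <- (mat - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    thr <- threshold
  } else stop("'threshold' must be a number or \"otsu\"")
  mask <- if (img$polarity == "dark") mat < thr else mat > thr
  structure(mask, class = c("binary_mask", class(mask)),
            pixel_size = img$pixel_size)
}

# label connected foreground components by iterative minimum-label
# propagation (converges in O(component diameter) vectorised sweeps)
.label_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new_lab <- lab
    for (s in shifts) {
      nb <- shift_mat(lab, s[1], s[2])
      take <- mask & nb > 0L & nb < new_lab
      new_lab[take] <- nb[take]
    }
    # pointer-jumping through the provisional label ids speeds up long
    # thin components
    idx <- new_lab > 0L
    new_lab[idx] <- .compress_labels(new_lab[idx], lab[mask])
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# follow label -> label-at-that-pixel chains to their roots
.compress_labels <- function(cur, by_initial_id) {
  repeat {
    nxt <- by_initial_id[cur]
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}

#' Label connected cluster components
#'
#' Connected-component labelling of a binary mask under 4- or
#' 8-connectivity; components smaller than `min_size` pixels are
#' discarded (sub-resolution specks and single beads).
#'
#' @param mask A `binary_mask` from [binarize()] (or a logical matrix).
#' @param connectivity 4 or 8 (default 8: diagonal contact joins).
#' @param min_size Minimum component area in pixels (default 5).
#' @return An object of class `cluster_labels`: list with `labels`
#'   (integer matrix, 0 = background, components numbered 1..n), `sizes`
#'   (pixel areas) and the settings used.
#' @export
label_clusters <- function(mask, connectivity = 8, min_size = 5) {
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  m <- mask
  if (!is.logical(m)) m <- m != 0
  m <- matrix(as.logical(m), nrow(mask), ncol(mask))
  lab <- if (any(m)) .label_components(m, connectivity)
         else matrix(0L, nrow(m), ncol(m))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0L] <- relab[lab[lab > 0L]]
  structure(list(labels = out, sizes = sizes[keep],
                 connectivity = connectivity, min_size = min_size,
                 pixel_size = attr(mask, "pixel_size")),
            class = "cluster_labels")
}

#' Cluster-size statistics
#'
#' @param labels A `cluster_labels` object from [label_clusters()].
#' @param pixel_size um per pixel; defaults to the value carried through
#'   from the image, else 1.
#' @return An object of class `cluster_stats`: list with `n_clusters`,
#'   `sizes` (px), `mean_size_au` (mean pixel area), `mean_diameter_um`
#'   (mean of `2*sqrt(area/pi)*pixel_size`) and `total_mask_fraction`.
#'   With zero clusters the means are `NA`.
#' @export
cluster_stats <- function(labels, pixel_size = NULL) {
  stopifnot(inherits(labels, "cluster_labels"))
  if (is.null(pixel_size)) pixel_size <- labels$pixel_size
  if (is.null(pixel_size)) pixel_size <- 1
  sizes <- labels$sizes
  n <- length(sizes)
  structure(list(
    n_clusters = n,
    sizes = sizes,
    mean_size_au = if (n) mean(sizes) else NA_real_,
    mean_diameter_um = if (n) mean(2 * sqrt(sizes / pi)) * pixel_size
                       else NA_real_,
    total_mask_fraction = sum(sizes) / length(labels$labels)
  ), class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("%d clusters, mean size %.1f px, mean diameter %.2f um, mask fraction %.3f\n",
              x$n_clusters, x$mean_size_au, x$mean_diameter_um,
              x$total_mask_fraction))
  invisible(x)
}

#' Per-frame cluster statistics of an image series
#'
#' Runs the binarize/label/measure pipeline on every frame with one set
#' of settings and returns a tidy table; the `mean_size_au` column is
#' the aggregate-size pulse that [pulse_metrics()] measures lifetimes
#' on.
#'
#' With `threshold = "otsu"` a single threshold is computed from the
#' pooled intensity histogram of all frames and applied throughout.
#' Per-frame Otsu would fail on frames with little or no structure
#' (near-unimodal histograms at the tails of an aggregation pulse,
#' where the method would split the background noise); a shared
#' threshold is also how a time-lapse series is analysed in practice.
#'
#' @param images List of [gray_image()] objects with identical
#'   dimensions.
#' @param threshold,connectivity,min_size Settings passed to
#'   [binarize()] and [label_clusters()].
#' @return Data frame with one row per frame: `frame`, `n_clusters`,
#'   `mean_size_au`, `mean_diameter_um`, `total_mask_fraction`.
#' @export
timeseries_stats <- function(images, threshold = "otsu",
                             connectivity = 8, min_size = 5) {
  dims <- lapply(images, function(im) dim(im$mat))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    stop("frames have heterogeneous shapes")
  if (identical(threshold, "otsu")) {
    pooled <- unlist(lapply(images, function(im) as.numeric(im$mat)))
    rng <- range(pooled)
    if (diff(rng) == 0) stop("constant image stack: Otsu is undefined")
    norm <- (pooled - rng[1]) / diff(rng)
    threshold <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)),
                               range = c(0, 1)) * diff(rng) + rng[1]
  }
  rows <- lapply(seq_along(images), function(i) {
    st <- cluster_stats(label_clusters(binarize(images[[i]], threshold),
                                       connectivity, min_size))
    data.frame(frame = i, n_clusters = st$n_clusters,
               mean_size_au = st$mean_size_au,
               mean_diameter_um = st$mean_diameter_um,
               total_mask_fraction = st$total_mask_fraction)
  })
  do.call(rbind, rows)
}
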