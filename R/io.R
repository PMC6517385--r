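# Plain-text serialisation of trajectories, traces and parameters.

#' Write / read an RNA trajectory as CSV
#'
#' Column layout: `t_min,rna_nM,ntp_uM`.
#'
#' @param traj An [rna_trajectory()].
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns an [rna_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t_min = traj$times, rna_nM = traj$rna, ntp_uM = traj$ntp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  rna_trajectory(df$t_min, df$rna_nM, df$ntp_uM)
}

#' Write / read a fluorescence trace as CSV
#'
#' Column layout: `t_min,signal_au`; the template concentration and
#' known settings travel in a JSON side-car (`<path>.json`).
#'
#' @param trace A [fluorescence_trace()].
#' @param path File path for the CSV.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [fluorescence_trace()].
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(t_min = trace$times, signal_au = trace$signal),
                   path, row.names = FALSE)
  meta <- list(template_nM = attr(trace, "template_nM"),
               settings = attr(trace, "settings"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(template_nM = NA_real_, settings = list())
  fluorescence_trace(df$t_min, df$signal_au,
                     template_nM = as.numeric(meta$template_nM),
                     settings = meta$settings)
}

#' Write / read kinetic parameters as JSON
#'
#' @param p A [kinetic_params()].
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` a
#'   [kinetic_params()].
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(kinetic_params, jsonlite::read_json(path, simplifyVector = TRUE))
}
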