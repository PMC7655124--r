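#' Pipeline configuration
#'
#' Collects every tunable constant of the feature pipeline in one nested list.
#' Values the source method fixes (300 log-spaced bands between 60 and 800 Hz,
#' z threshold of 3 SD, 10-s statistical window, >4-cycle rule, ripple band
#' 80-250 Hz, fast-ripple band 250-600 Hz, 1-s connectivity windows,
#' alpha = 0.05) are defaults here, never hard-coded elsewhere.
#'
#' @param hfo,ied,connectivity,stats,svm Named lists overriding individual
#'   entries of the corresponding section; unknown names are an error.
#' @param seed Default random seed carried in the config (integer or `NULL`).
#'
#' @return An object of class `pipeline_config`: a named nested list with
#'   sections `hfo`, `ied`, `connectivity`, `stats`, `svm` and element `seed`.
#'
#' @details Sections and defaults:
#' \describe{
#'   \item{hfo}{`n_bands` (300), `fmin`/`fmax` (60/800 Hz), `band_q` (4.5;
#'     Gaussian band sigma = center / band_q, so bandwidth grows with
#'     frequency), `stat_window_s` (10), `z_threshold` (3), `min_cycles` (4,
#'     strict), `r_band` (80-250 Hz), `fr_band` (250-600 Hz).}
#'   \item{ied}{`spike_band` (20-50 Hz), `background_band` (1-35 Hz),
#'     `reference_background_uv` (30), `amp_threshold_uv` (60, scaled units),
#'     `slope_threshold_uv_ms` (3), `refractory_s` (0.2).}
#'   \item{connectivity}{`window_s` (1), `n_bins` (10), `log_base`
#'     ("natural" or "log2").}
#'   \item{stats}{`alpha` (0.05), `p_adjust` ("none"; "BH" optional).}
#'   \item{svm}{`kernels`, `c_grid`, `gamma_grid`, `refine` (TRUE: one zoom
#'     level around the best cell).}
#' }
#' @examples
#' cfg <- pipeline_config(hfo = list(z_threshold = 3.5))
#' cfg$hfo$z_threshold
#' @export
pipeline_config <- function(hfo = list(), ied = list(), connectivity = list(),
                            stats = list(), svm = list(), seed = NULL) {
  defaults <- list(
    hfo = list(
      n_bands = 300L, fmin = 60, fmax = 800, band_q = 4.5,
      stat_window_s = 10, z_threshold = 3, min_cycles = 4,
      r_band = c(80, 250), fr_band = c(250, 600)
    ),
    ied = list(
      spike_band = c(20, 50), background_band = c(1, 35),
      reference_background_uv = 30, amp_threshold_uv = 60,
      slope_threshold_uv_ms = 3, refractory_s = 0.2
    ),
    connectivity = list(window_s = 1, n_bins = 10L, log_base = "natural"),
    stats = list(alpha = 0.05, p_adjust = "none"),
    svm = list(
      kernels = c("linear", "radial"),
      c_grid = 10^(-3:2), gamma_grid = 10^(-3:2), refine = TRUE
    ),
    seed = seed
  )
  user <- list(hfo = hfo, ied = ied, connectivity = connectivity,
               stats = stats, svm = svm)
  for (sec in names(user)) {
    extra <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(extra) > 0) {
      abort(sprintf("Unknown %s config entries: %s", sec,
                    paste(extra, collapse = ", ")))
    }
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  validate_pipeline_config(structure(defaults, class = "pipeline_config"))
}

validate_pipeline_config <- function(cfg) {
  h <- cfg$hfo
  if (!(h$fmin < h$fmax)) abort("hfo: fmin must be < fmax")
  if (h$r_band[2] != h$fr_band[1]) {
    abort("hfo: ripple and fast-ripple bands must be contiguous at the boundary")
  }
  if (h$r_band[1] >= h$r_band[2] || h$fr_band[1] >= h$fr_band[2]) {
    abort("hfo: band edges must increase")
  }
  a <- cfg$stats$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) abort("stats: alpha must be in (0,1)")
  if (cfg$connectivity$n_bins < 2) abort("connectivity: n_bins must be >= 2")
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (sec in setdiff(names(x), "seed")) {
    cat(" ", sec, ": ",
        paste(names(x[[sec]]), vapply(x[[sec]], function(v)
          paste(format(v, digits = 4), collapse = "-"), ""),
          sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat("  seed:", if (is.null(x$seed)) "NULL" else x$seed, "\n")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The file mirrors [pipeline_config()] field-for-field; missing entries fall
#' back to defaults.
#'
#' @param path File path.
#' @param cfg A `pipeline_config` object.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    hfo = raw$hfo %||% list(), ied = raw$ied %||% list(),
    connectivity = raw$connectivity %||% list(),
    stats = raw$stats %||% list(), svm = raw$svm %||% list(),
    seed = raw$seed
  )
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
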