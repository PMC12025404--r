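#' Pipeline configuration
#'
#' Bundles every tunable of the detection workflow with its validated
#' default: the 15-30 Hz fourth-order call-band filter, 26-s windows,
#' entropy parameters `m = 2`, `r = 0.2 sd`, scales to `tau_max = 12`,
#' two mixture components, `zeta = 4` retained features and a 70/30
#' split. Serializes losslessly to JSON via [write_config()].
#'
#' @param f_low,f_high,filter_order band-pass settings (Hz / order).
#' @param window_s segmentation window (seconds).
#' @param m,r_coef,tau_max,norm_mode entropy settings, see [mse_matrix()].
#' @param method feature extractor: `"mse"`, `"pca"`, `"dmd"` or `"wf"`.
#' @param K mixture components; set to `NA` to select by BIC over
#'   `k_range`.
#' @param k_range BIC candidate range used when `K` is `NA`.
#' @param zeta retained feature count; the per-method defaults are
#'   mse 4, dmd 5, wf 3, pca 7.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(f_low = 15, f_high = 30, filter_order = 4,
                            window_s = 26, m = 2, r_coef = 0.2,
                            tau_max = 12, norm_mode = "paper",
                            method = "mse", K = 2, k_range = 1:8,
                            zeta = NULL, train_frac = 0.7, seed = 1) {
  method <- match.arg(method, c("mse", "pca", "dmd", "wf"))
  norm_mode <- match.arg(norm_mode, c("paper", "standard"))
  if (is.null(zeta))
    zeta <- c(mse = 4, dmd = 5, wf = 3, pca = 7)[[method]]
  stopifnot(f_low > 0, f_low < f_high, filter_order >= 1, window_s > 0,
            m >= 1, r_coef > 0, tau_max >= 1, zeta >= 1,
            train_frac > 0, train_frac < 1)
  structure(list(f_low = f_low, f_high = f_high,
                 filter_order = filter_order, window_s = window_s,
                 m = m, r_coef = r_coef, tau_max = tau_max,
                 norm_mode = norm_mode, method = method, K = K,
                 k_range = k_range, zeta = zeta, train_frac = train_frac,
                 seed = seed),
            class = "pipeline_config")
}

#' Write a pipeline configuration as JSON
#'
#' @param config a [pipeline_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#'
#' @param path JSON path.
#' @return a validated [pipeline_config].
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}
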