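#' Analysis configuration
#'
#' Collects every threshold the pipeline uses, so that no stage buries a
#' numeric literal: the classification bias threshold (0.55), the high-bias
#' volumetry threshold (0.95), the indeterminate band (0.45-0.55), the
#' equal-volume mask target (83 diffusion voxels), the histogram bin width
#' (0.01 over the biased range, i.e. 45 bins on [0.55, 1.00]), the
#' somatotopic-zone percentile (5), the per-family false-discovery level
#' (q = 0.05) and the run seed.
#'
#' @param bias_threshold minimum connection probability defining a
#'   compartment-biased (matrix-like or striosome-like) voxel.
#' @param high_threshold probability threshold for "highly biased" volumetry.
#' @param indeterminate_band closed outer bounds of the unclassified band;
#'   must be symmetric about 0.5. Voxels strictly inside the open interval
#'   are indeterminate; the endpoints themselves are biased (so the >= 0.55
#'   rule holds verbatim and the three classes are disjoint).
#' @param equal_volume_target preset equal-volume mask size, native voxels.
#' @param histogram_bin_width probability bin width; must divide the biased
#'   range `[bias_threshold, 1]` evenly.
#' @param zone_percentile percentile of positive contributions retained when
#'   thresholding somatotopic contribution maps.
#' @param fdr_q per-family Benjamini-Hochberg false-discovery level.
#' @param rng_seed integer run seed fanned out to all random stages.
#' @return An object of class `striocomp_config` (a validated list).
#' @export
striocomp_config <- function(bias_threshold = 0.55,
                             high_threshold = 0.95,
                             indeterminate_band = c(0.45, 0.55),
                             equal_volume_target = 83,
                             histogram_bin_width = 0.01,
                             zone_percentile = 5,
                             fdr_q = 0.05,
                             rng_seed = 1L) {
  cfg <- list(bias_threshold = as.numeric(bias_threshold),
              high_threshold = as.numeric(high_threshold),
              indeterminate_band = as.numeric(indeterminate_band),
              equal_volume_target = as.numeric(equal_volume_target),
              histogram_bin_width = as.numeric(histogram_bin_width),
              zone_percentile = as.numeric(zone_percentile),
              fdr_q = as.numeric(fdr_q),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "striocomp_config")
}

validate_config <- function(cfg) {
  fail <- function(key, why) stop("config invariant violated [", key, "]: ",
                                  why, call. = FALSE)
  if (!(cfg$bias_threshold > 0.5)) fail("bias_threshold", "must exceed 0.5")
  if (!(cfg$bias_threshold <= cfg$high_threshold))
    fail("high_threshold", "must be >= bias_threshold")
  if (!(cfg$high_threshold <= 1)) fail("high_threshold", "must be <= 1.0")
  b <- cfg$indeterminate_band
  if (length(b) != 2L || b[1] >= b[2])
    fail("indeterminate_band", "must be an increasing pair")
  if (abs((b[1] + b[2]) / 2 - 0.5) > 1e-9)
    fail("indeterminate_band", "must be symmetric about 0.5")
  if (cfg$equal_volume_target < 1)
    fail("equal_volume_target", "must be a positive voxel count")
  span <- 1 - cfg$bias_threshold
  nb <- span / cfg$histogram_bin_width
  if (abs(nb - round(nb)) > 1e-9)
    fail("histogram_bin_width", "must divide the biased range evenly")
  if (cfg$zone_percentile < 0 || cfg$zone_percentile > 100)
    fail("zone_percentile", "must lie in [0, 100]")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) fail("fdr_q", "must lie in (0, 1)")
  invisible(cfg)
}

#' Load a configuration from file and/or overrides
#'
#' Reads a YAML or JSON config file (recognised by extension), applies
#' `key = value` overrides on top, fills the remaining keys with the package
#' defaults, and validates the result. Unknown keys are an error so typos
#' cannot silently revert a threshold to its default.
#'
#' @param path optional path to a `.yaml`/`.yml` or `.json` config file.
#' @param overrides named list of keys overriding both file and defaults.
#' @return An [striocomp_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing config file: ", path)
    ext <- tolower(tools::file_ext(path))
    vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
            else if (ext == "json") jsonlite::fromJSON(path)
            else stop("unrecognised config format: .", ext)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(striocomp_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(striocomp_config, vals)
}

#' @export
print.striocomp_config <- function(x, ...) {
  cat("<striocomp_config>\n")
  for (k in names(x)) cat("  ", k, ": ", paste(format(x[[k]]), collapse = " "),
                          "\n", sep = "")
  invisible(x)
}
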