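#' Convert competing streamline counts to a connection-probability map
#'
#' Given path-length-corrected streamline counts from each striatal voxel
#' toward the matrix-favoring and striosome-favoring composite targets, each
#' striatal voxel is assigned the probability of matrix-favoring connectivity
#'
#'   p_matrix = counts_matrix / (counts_matrix + counts_striosome)
#'
#' (p_striosome is its complement). Voxels whose total count is zero carry no
#' connectivity evidence: they are flagged undefined (NA), never imputed, and
#' are excluded from all downstream volumetry denominators.
#'
#' @param counts_matrix,counts_striosome [volume_grid()]s of nonnegative
#'   streamline counts on a shared grid.
#' @param striatum striatal [region_mask()] on the same grid.
#' @param caudate,putamen optional nucleus [region_mask()]s; if both given
#'   they must partition the striatum.
#' @param subject_id,hemisphere optional labels carried through reports.
#' @return An object of class `probability_map`: the striatal mask plus
#'   `p_matrix` (a `volume_grid`, NA outside the striatum and at undefined
#'   voxels), an `undefined` logical array flagging zero-evidence voxels,
#'   and the nucleus masks when supplied.
#' @export
compute_probability <- function(counts_matrix, counts_striosome, striatum,
                                caudate = NULL, putamen = NULL,
                                subject_id = NA_character_,
                                hemisphere = NA_character_) {
  stop_if_grid_mismatch(counts_matrix, counts_striosome, "count volumes")
  stop_if_grid_mismatch(counts_matrix, striatum, "counts and striatal mask")
  cm <- counts_matrix$data; cs <- counts_striosome$data
  if (any(cm < 0, na.rm = TRUE) || any(cs < 0, na.rm = TRUE))
    stop("negative counts are not valid streamline evidence")
  s <- striatum$data
  if (!any(s)) stop("striatal mask is empty")
  if (!is.null(caudate) && !is.null(putamen))
    check_nucleus_partition(striatum, caudate, putamen)
  tot <- cm + cs
  p <- array(NA_real_, dim(cm))
  undef <- array(FALSE, dim(cm))
  inside <- which(s)
  zero <- inside[tot[inside] == 0]
  ok <- inside[tot[inside] > 0]
  p[ok] <- cm[ok] / tot[ok]
  undef[zero] <- TRUE
  structure(
    list(p_matrix = volume_grid(p, counts_matrix$voxel_size_mm,
                                counts_matrix$origin, counts_matrix$axes),
         undefined = undef, striatum = striatum,
         caudate = caudate, putamen = putamen,
         subject_id = subject_id, hemisphere = hemisphere),
    class = "probability_map")
}

#' Build a probability map directly from a probability array
#'
#' Convenience constructor used by the simulator and by tests that start
#' from probabilities rather than raw counts.
#'
#' @param p 3D array of matrix-favoring probabilities (NA outside striatum).
#' @param striatum striatal [region_mask()]; defaults to `!is.na(p)`.
#' @inheritParams compute_probability
#' @param voxel_size_mm,origin grid geometry for `p`.
#' @return A `probability_map`.
#' @export
probability_map <- function(p, striatum = NULL, caudate = NULL,
                            putamen = NULL, voxel_size_mm = c(2, 2, 2),
                            origin = c(0, 0, 0),
                            subject_id = NA_character_,
                            hemisphere = NA_character_) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  pg <- volume_grid(p, voxel_size_mm, origin)
  if (is.null(striatum))
    striatum <- region_mask(volume_grid(array(!is.na(p), dim(p)),
                                        voxel_size_mm, origin), "striatum")
  stop_if_grid_mismatch(pg, striatum, "probabilities and striatal mask")
  structure(
    list(p_matrix = pg, undefined = array(FALSE, dim(p)),
         striatum = striatum, caudate = caudate, putamen = putamen,
         subject_id = subject_id, hemisphere = hemisphere),
    class = "probability_map")
}

PARCEL_LEVELS <- c("matrix-like", "striosome-like", "indeterminate",
                   "undefined")

#' Classify striatal voxels into compartment-like labels
#'
#' A voxel is matrix-like iff `p_matrix >= bias_threshold` (0.55), or
#' striosome-like iff `p_matrix <= 1 - bias_threshold` (0.45). Voxels on
#' the open interval between are indeterminate (unclassified); voxels with
#' no connectivity evidence stay undefined. The band endpoints are biased,
#' keeping the >= 0.55 rule verbatim and the classes disjoint.
#'
#' @param pmap a `probability_map`.
#' @param config an [striocomp_config()].
#' @return An object of class `parcellation`: `labels` (a `volume_grid` of
#'   integers indexing `levels`), `levels`, the thresholds used and the
#'   originating masks.
#' @export
classify <- function(pmap, config = striocomp_config()) {
  stopifnot(inherits(pmap, "probability_map"))
  p <- pmap$p_matrix$data
  lab <- array(NA_integer_, dim(p))
  lab[pmap$undefined] <- 4L
  def <- !is.na(p)
  bt <- config$bias_threshold
  eps <- 1e-9   # guards the band endpoints against FP (1 - 0.55 != 0.45)
  lab[def & p >= bt - eps] <- 1L
  lab[def & p <= 1 - bt + eps] <- 2L
  lab[def & p > 1 - bt + eps & p < bt - eps] <- 3L
  structure(
    list(labels = volume_grid(lab, pmap$p_matrix$voxel_size_mm,
                              pmap$p_matrix$origin, pmap$p_matrix$axes),
         levels = PARCEL_LEVELS, bias_threshold = bt,
         striatum = pmap$striatum, caudate = pmap$caudate,
         putamen = pmap$putamen, subject_id = pmap$subject_id),
    class = "parcellation")
}

vols_at <- function(p, thr, eps = 1e-9) {
  c(matrix_vol = sum(p >= thr - eps, na.rm = TRUE),
    striosome_vol = sum(p <= 1 - thr + eps, na.rm = TRUE))
}

#' Compartment volumetry at multiple probability thresholds
#'
#' Voxel counts per compartment at each threshold (default 0.95 and 0.55),
#' for the whole striatum and separately for caudate and putamen when
#' nucleus masks are present, together with the within-subject difference
#' M-S (matrix-like minus striosome-like voxels) at each threshold and the
#' indeterminate count. Undefined voxels are excluded from every count.
#'
#' @param pmap a `probability_map`.
#' @param thresholds probability thresholds, each in (0.5, 1].
#' @param config an [striocomp_config()] supplying the indeterminate band.
#' @return A `data.frame` with columns `nucleus`, `threshold`,
#'   `matrix_vol`, `striosome_vol`, `m_minus_s`, `indeterminate`.
#' @export
compartment_volumes <- function(pmap, thresholds = NULL,
                                config = striocomp_config()) {
  stopifnot(inherits(pmap, "probability_map"))
  if (is.null(thresholds))
    thresholds <- c(config$high_threshold, config$bias_threshold)
  if (any(thresholds <= 0.5 | thresholds > 1))
    stop("thresholds must lie in (0.5, 1]")
  p <- pmap$p_matrix$data
  bt <- config$bias_threshold
  nuclei <- list(striatum = pmap$striatum$data)
  if (!is.null(pmap$caudate) && !is.null(pmap$putamen)) {
    check_nucleus_partition(pmap$striatum, pmap$caudate, pmap$putamen)
    nuclei$caudate <- pmap$caudate$data
    nuclei$putamen <- pmap$putamen$data
  }
  rows <- list()
  for (nm in names(nuclei)) {
    pv <- p[nuclei[[nm]]]
    eps <- 1e-9
    ind <- sum(pv > 1 - bt + eps & pv < bt - eps, na.rm = TRUE)
    for (thr in thresholds) {
      v <- vols_at(pv, thr)
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus = nm, threshold = thr,
        matrix_vol = unname(v["matrix_vol"]),
        striosome_vol = unname(v["striosome_vol"]),
        m_minus_s = unname(v["matrix_vol"] - v["striosome_vol"]),
        indeterminate = ind)
    }
  }
  do.call(rbind, rows)
}

#' Probability histogram over the biased range
#'
#' Bins the chosen compartment's connection probabilities in
#' `histogram_bin_width`-wide bins over the biased range
#' `[bias_threshold, 1.00]` — 45 bins of width 0.01 at the defaults. Bins
#' are left-closed/right-open except the final bin, which is closed so a
#' probability of exactly 1.0 is counted. Bin counts conserve the
#' compartment's biased-voxel volume at the bias threshold. A full-range
#' variant (`full_range = TRUE`) bins p_matrix over [0, 1] in 100 bins for
#' parity with whole-distribution histogram tools.
#'
#' @param pmap a `probability_map`.
#' @param compartment `"matrix"` or `"striosome"`; the striosome histogram
#'   bins `1 - p_matrix`.
#' @param config an [striocomp_config()].
#' @param full_range bin the full [0, 1] range instead of the biased range.
#' @return A `data.frame` with columns `compartment`, `bin_lo`, `bin_hi`,
#'   `count`, plus attribute `subject_id`.
#' @export
probability_histogram <- function(pmap,
                                  compartment = c("matrix", "striosome"),
                                  config = striocomp_config(),
                                  full_range = FALSE) {
  stopifnot(inherits(pmap, "probability_map"))
  compartment <- match.arg(compartment)
  p <- pmap$p_matrix$data[pmap$striatum$data]
  p <- p[!is.na(p)]
  if (compartment == "striosome") p <- 1 - p
  lo <- if (full_range) 0 else config$bias_threshold
  w <- histogram_width_check(lo, config$histogram_bin_width)
  edges <- seq(lo, 1, by = w)
  nb <- length(edges) - 1L
  x <- p[p >= lo - 1e-9 & p <= 1]
  # the 1e-9 guard keeps edge values (e.g. 0.56) in their own bin despite
  # floating-point division; pmin closes the final bin at 1.0
  bin <- pmin(floor((x - lo) / w + 1e-9) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  out <- data.frame(compartment = compartment,
                    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = counts)
  attr(out, "subject_id") <- pmap$subject_id
  out
}

histogram_width_check <- function(lo, w) {
  nb <- (1 - lo) / w
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin width ", w, " does not divide the range [", lo, ", 1] evenly")
  w
}
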