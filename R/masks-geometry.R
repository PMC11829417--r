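#' Equal-volume most-discriminating compartment masks
#'
#' For one subject-hemisphere, selects for each compartment the qualifying
#' voxels (own-compartment connection probability >= `bias_threshold`),
#' sorts them by that probability in descending order (starting at the
#' uppermost biased probability, 1.0) and accepts voxels until a preset
#' volume target (83 native voxels by default) is reached. If either
#' compartment has fewer qualifying voxels than the target, both masks are
#' truncated to N = min(available matrix, available striosome), preserving
#' the core fairness contract that the two masks have exactly equal volume
#' within every subject-hemisphere. Ties at equal probability are broken
#' deterministically by ascending linear voxel index.
#'
#' @param pmap a `probability_map`.
#' @param config an [striocomp_config()]; `equal_volume_target` sets the
#'   preset volume.
#' @return An object of class `equal_volume_masks`: `matrix_mask` and
#'   `striosome_mask` ([region_mask()]s), `achieved_volume`,
#'   `target_volume`, and a `selection_trace` with the own-compartment
#'   probability of the last-accepted voxel per compartment.
#' @export
build_equal_volume_masks <- function(pmap, config = striocomp_config()) {
  stopifnot(inherits(pmap, "probability_map"))
  p <- pmap$p_matrix$data
  inside <- which(pmap$striatum$data & !is.na(p))
  bt <- config$bias_threshold
  qual_m <- inside[p[inside] >= bt - 1e-9]
  qual_s <- inside[(1 - p[inside]) >= bt - 1e-9]
  n <- min(length(qual_m), length(qual_s), config$equal_volume_target)
  if (n == 0)
    warning("a compartment has zero qualifying voxels; ",
            "both equal-volume masks are empty")
  top_n <- function(idx, prob) {
    o <- order(-prob, idx)          # descending probability, index tie-break
    idx[o][seq_len(n)]
  }
  sel_m <- top_n(qual_m, p[qual_m])
  sel_s <- top_n(qual_s, 1 - p[qual_s])
  as_mask <- function(sel, name) {
    m <- array(FALSE, dim(p)); m[sel] <- TRUE
    region_mask(volume_grid(m, pmap$p_matrix$voxel_size_mm,
                            pmap$p_matrix$origin, pmap$p_matrix$axes), name)
  }
  structure(
    list(matrix_mask = as_mask(sel_m, "matrix-like"),
         striosome_mask = as_mask(sel_s, "striosome-like"),
         achieved_volume = n,
         target_volume = config$equal_volume_target,
         selection_trace = data.frame(
           compartment = c("matrix", "striosome"),
           last_accepted_p = c(if (n) min(p[sel_m]) else NA_real_,
                               if (n) min(1 - p[sel_s]) else NA_real_))),
    class = "equal_volume_masks")
}

#' Fraction of a normal distribution beyond +/- 1.5 SD, per tail
#'
#' Documented helper re-deriving the reasoning behind the 83-voxel
#' equal-volume target: drop the median +/- 1.5 SD mass of a normal volume
#' distribution and split the remainder across the two tails. The default
#' target itself stays a config constant because it additionally depends on
#' a template hemistriatum segmentation.
#'
#' @param sd_band half-width of the retained central band in SD units.
#' @return Fraction of total volume in one tail.
#' @export
normal_tail_fraction <- function(sd_band = 1.5) {
  (1 - (stats::pnorm(sd_band) - stats::pnorm(-sd_band))) / 2
}

#' Centroid-relative voxel offsets
#'
#' For every voxel of a compartment mask, the offset (dx, dy, dz) in
#' physical mm from the centroid of the nucleus that voxel occupies
#' (caudate or putamen), where the centroid is the mean physical centre of
#' all member voxels of that whole nucleus. Computing offsets per nucleus
#' means the relative placement of the nuclei within the hemisphere cannot
#' leak into compartment position statistics.
#'
#' @param mask a [region_mask()] of compartment voxels.
#' @param nuclei named list of nucleus [region_mask()]s (e.g. caudate,
#'   putamen); every mask voxel must belong to exactly one nucleus.
#' @param compartment label copied into the output.
#' @return A `data.frame` with columns `voxel`, `nucleus`, `dx`, `dy`, `dz`,
#'   `compartment`; attribute `axis_means` holds the per-axis mean offsets.
#' @export
centroid_offsets <- function(mask, nuclei, compartment = mask$region_name) {
  stopifnot(inherits(mask, "region_mask"), length(nuclei) >= 1)
  for (nuc in nuclei) stop_if_grid_mismatch(mask, nuc, "mask and nuclei")
  sel <- which(mask$data)
  member <- matrix(FALSE, length(sel), length(nuclei))
  for (j in seq_along(nuclei)) member[, j] <- nuclei[[j]]$data[sel]
  nmem <- rowSums(member)
  if (any(nmem == 0)) stop("mask voxel outside all nuclei")
  if (any(nmem > 1)) stop("mask voxel inside more than one nucleus")
  cent <- lapply(nuclei, function(nuc)
    colMeans(voxel_centers(nuc, which(nuc$data))))
  xyz <- voxel_centers(mask, sel)
  nuc_of <- names(nuclei)[max.col(member)]
  off <- xyz - do.call(rbind, cent[nuc_of])
  out <- data.frame(voxel = sel, nucleus = nuc_of,
                    dx = off[, 1], dy = off[, 2], dz = off[, 3],
                    compartment = compartment)
  attr(out, "axis_means") <- colMeans(off)
  out
}

#' Distance between two mean voxel locations
#'
#' Euclidean norm of the difference between two 3-vector mean offsets (the
#' reading adopted for a "root-mean-square distance" between two mean
#' locations; the divide-by-sqrt(3) per-axis RMS variant is available via
#' `per_axis_rms = TRUE`).
#'
#' @param mean_a,mean_b numeric length-3 mean offsets in mm, on the same
#'   axis convention.
#' @param per_axis_rms divide the norm by sqrt(3).
#' @return Distance in mm.
#' @export
group_offset_distance <- function(mean_a, mean_b, per_axis_rms = FALSE) {
  if (length(mean_a) != 3L || length(mean_b) != 3L)
    stop("mean offsets must be 3-vectors")
  if (!is.null(names(mean_a)) && !is.null(names(mean_b)) &&
      !identical(names(mean_a), names(mean_b)))
    stop("axis mismatch between mean offsets")
  d <- sqrt(sum((as.numeric(mean_a) - as.numeric(mean_b))^2))
  if (per_axis_rms) d / sqrt(3) else d
}
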