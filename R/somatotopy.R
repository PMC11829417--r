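#' Default bait-region roster
#'
#' The ten extra-striatal regions with known compartment-biased striatal
#' projections used as tractography target classes: five matrix-favoring
#' and five striosome-favoring.
#'
#' @return A `data.frame` with columns `region` and `class`.
#' @export
bait_roster <- function() {
  data.frame(
    region = c("primary_sensory", "vlc_vplo_thalamus", "supplementary_motor",
               "primary_motor", "globus_pallidus_interna",
               "mediodorsal_thalamus", "posterior_orbitofrontal",
               "anterior_insula", "basolateral_amygdala", "basal_operculum"),
    class = rep(c("matrix-favoring", "striosome-favoring"), each = 5L))
}

#' Leave-one-out somatotopic contribution of one bait region
#'
#' The contribution of bait region A is the voxelwise difference between
#' the probability map segmented with the full bait roster and the map
#' segmented with A left out: for a matrix-favoring region,
#' dP = p_full - p_reduced; for a striosome-favoring region the inverse,
#' dP = p_reduced - p_full (the sites where that region most influences
#' matrix-like connection probability). Negative values are retained —
#' thresholding happens later in [threshold_zones()].
#'
#' @param p_full [volume_grid()] of the full-roster (usually group-average)
#'   probability map; NA outside the striatal mask.
#' @param p_reduced [volume_grid()] computed with `region_name` left out.
#' @param region_name bait region; must appear in `roster`.
#' @param roster bait roster `data.frame` (default [bait_roster()]).
#' @return An object of class `contribution_map` with fields `region`,
#'   `class`, and `delta` (a `volume_grid`).
#' @export
region_contribution <- function(p_full, p_reduced, region_name,
                                roster = bait_roster()) {
  stop_if_grid_mismatch(p_full, p_reduced, "full and reduced maps")
  i <- match(region_name, roster$region)
  if (is.na(i)) stop("region not in the bait roster: ", region_name)
  cls <- roster$class[i]
  delta <- if (cls == "matrix-favoring") p_full$data - p_reduced$data
           else p_reduced$data - p_full$data
  structure(
    list(region = region_name, class = cls,
         delta = volume_grid(delta, p_full$voxel_size_mm, p_full$origin,
                             p_full$axes)),
    class = "contribution_map")
}

#' Somatotopic zones from thresholded contribution maps
#'
#' Per bait region, retains voxels whose positive contribution is at or
#' above the configured percentile of that region's positive contributions
#' (default: the 5th percentile, read literally from the thresholding
#' convention; set `zone_percentile = 95` to keep only the top 5 percent).
#' Survivors are then made pairwise disjoint by assigning each voxel to the
#' region of its maximum contribution, with ties broken deterministically
#' by roster order.
#'
#' @param contribution_maps list of `contribution_map`s, one per bait
#'   region.
#' @param config an [striocomp_config()]; `zone_percentile` sets the cut.
#' @return An object of class `somatotopic_zones`: a named list `zones` of
#'   logical arrays (pairwise disjoint), the `assignment` integer array
#'   (0 = unassigned), and rule metadata.
#' @export
threshold_zones <- function(contribution_maps, config = striocomp_config()) {
  stopifnot(length(contribution_maps) >= 1)
  g0 <- contribution_maps[[1]]$delta
  regions <- vapply(contribution_maps, function(m) m$region, character(1))
  nvox <- prod(dim(g0$data))
  keep <- matrix(FALSE, nvox, length(regions))
  dmat <- matrix(-Inf, nvox, length(regions))
  for (j in seq_along(contribution_maps)) {
    cm <- contribution_maps[[j]]
    stop_if_grid_mismatch(g0, cm$delta, "contribution maps")
    d <- as.vector(cm$delta$data)
    pos <- which(!is.na(d) & d > 0)
    if (!length(pos)) {
      warning("all-nonpositive contribution map for region ", cm$region,
              "; its zone is empty")
      next
    }
    cut <- stats::quantile(d[pos], config$zone_percentile / 100,
                           names = FALSE)
    sel <- pos[d[pos] >= cut]
    keep[sel, j] <- TRUE
    dmat[sel, j] <- d[sel]
  }
  any_keep <- which(rowSums(keep) > 0)
  assign_vec <- integer(nvox)
  # max.col(ties.method = "first") = deterministic roster-order tie-break
  assign_vec[any_keep] <- max.col(dmat[any_keep, , drop = FALSE],
                                  ties.method = "first")
  zones <- lapply(seq_along(regions), function(j) {
    z <- array(assign_vec == j, dim(g0$data)); z
  })
  names(zones) <- regions
  structure(
    list(zones = zones,
         assignment = array(assign_vec, dim(g0$data)),
         regions = regions,
         rule = list(percentile = config$zone_percentile,
                     disjoint_by = "argmax contribution, roster-order ties"),
         grid = g0),
    class = "somatotopic_zones")
}

#' Zone-wise matrix-like volumetry, case vs control
#'
#' With zones fixed (derived from the control-group average contribution
#' maps), extracts per subject the matrix-like volume (p >= high_threshold)
#' inside each zone, averages within cohort, normalizes the case mean to
#' the control mean (control = 100 percent), and computes the paired
#' two-tailed t-test feeding the per-zone test family.
#'
#' @param zones a `somatotopic_zones` object.
#' @param pmaps_case,pmaps_control lists of `probability_map`s, paired in
#'   order (element i of each list forms matched pair i).
#' @param config an [striocomp_config()].
#' @return A `data.frame` with one row per zone: `zone`, `n_voxels`,
#'   `mean_case`, `mean_control`, `normalized_pct`, `sem_pct`, `p_value`.
#' @export
zone_volumetry <- function(zones, pmaps_case, pmaps_control,
                           config = striocomp_config()) {
  stopifnot(inherits(zones, "somatotopic_zones"))
  if (length(pmaps_case) != length(pmaps_control))
    stop("cohorts unpaired: case and control lists differ in length")
  thr <- config$high_threshold
  per_subject <- function(pm, zidx) {
    p <- pm$p_matrix$data
    sum(!is.na(p[zidx]) & p[zidx] >= thr)
  }
  rows <- lapply(zones$regions, function(rg) {
    zidx <- which(zones$zones[[rg]])
    if (!length(zidx))
      return(data.frame(zone = rg, n_voxels = 0L, mean_case = NA_real_,
                        mean_control = NA_real_, normalized_pct = NA_real_,
                        sem_pct = NA_real_, p_value = NA_real_))
    vc <- vapply(pmaps_case, per_subject, numeric(1), zidx = zidx)
    vt <- vapply(pmaps_control, per_subject, numeric(1), zidx = zidx)
    mt <- mean(vt)
    norm_pct <- if (mt > 0) 100 * mean(vc) / mt else NA_real_
    sem_pct <- if (mt > 0)
      100 * stats::sd(vc) / sqrt(length(vc)) / mt else NA_real_
    pv <- if (stats::sd(vc - vt) > 0)
      stats::t.test(vc, vt, paired = TRUE)$p.value
    else if (mean(vc - vt) == 0) 1 else NA_real_
    data.frame(zone = rg, n_voxels = length(zidx), mean_case = mean(vc),
               mean_control = mt, normalized_pct = norm_pct,
               sem_pct = sem_pct, p_value = pv)
  })
  do.call(rbind, rows)
}
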