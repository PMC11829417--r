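#' Dice similarity coefficient between two streamline volumes
#'
#' Each amplitude volume is first thresholded to retain its uppermost
#' fraction (default 75 percent) of nonzero-amplitude voxels by value, then
#' binarized; the overlap is
#'
#'   DSC = 2 |A n B| / (|A| + |B|)
#'
#' which is symmetric in the two volumes and lies in [0, 1]. If both
#' volumes are empty after thresholding the coefficient is undefined and
#' reported as NA ("no signal"), which is distinct from 0 ("no overlap").
#'
#' @param amp_a,amp_b nonnegative amplitude [volume_grid()]s on one grid,
#'   or logical/binary grids (used as-is when `retain = NULL`).
#' @param retain fraction of nonzero voxels retained per volume before
#'   binarizing; `NULL` skips thresholding.
#' @return List with `dsc`, the thresholds applied, and the binarized
#'   voxel counts.
#' @export
dice_overlap <- function(amp_a, amp_b, retain = 0.75) {
  stop_if_grid_mismatch(amp_a, amp_b, "streamline volumes")
  bin <- function(g) {
    v <- g$data
    if (any(v < 0, na.rm = TRUE)) stop("amplitudes must be nonnegative")
    if (is.null(retain)) return(list(mask = !is.na(v) & v > 0, thr = 0))
    nz <- v[!is.na(v) & v > 0]
    if (!length(nz)) return(list(mask = array(FALSE, dim(v)), thr = NA_real_))
    thr <- stats::quantile(nz, 1 - retain, names = FALSE)
    list(mask = !is.na(v) & v >= thr & v > 0, thr = thr)
  }
  a <- bin(amp_a); b <- bin(amp_b)
  na_ <- sum(a$mask); nb <- sum(b$mask)
  dsc <- if (na_ + nb == 0) NA_real_ else 2 * sum(a$mask & b$mask) / (na_ + nb)
  list(dsc = dsc, threshold_a = a$thr, threshold_b = b$thr,
       n_a = na_, n_b = nb)
}

#' Scalar summary (e.g. FA) by compartment mask
#'
#' Mean of a scalar map inside the matrix-like and striosome-like
#' equal-volume masks, with the percent difference and matrix:striosome
#' ratio. Means use only mask voxels where the scalar is defined; results
#' are invariant to voxel visitation order.
#'
#' @param scalar_map [volume_grid()] of the scalar (NA where undefined).
#' @param masks an `equal_volume_masks` object from
#'   [build_equal_volume_masks()].
#' @param subject_id label carried through reports.
#' @return A one-row `data.frame`: `subject_id`, `mean_matrix`,
#'   `mean_striosome`, `pct_diff` (100 x (M - S)/S), `ratio`.
#' @export
scalar_by_compartment <- function(scalar_map, masks,
                                  subject_id = NA_character_) {
  stopifnot(inherits(masks, "equal_volume_masks"))
  stop_if_grid_mismatch(scalar_map, masks$matrix_mask, "scalar and masks")
  mean_in <- function(mask) {
    v <- scalar_map$data[mask$data]
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty mask (or scalar undefined on all mask voxels)")
    mean(v)
  }
  m <- mean_in(masks$matrix_mask)
  s <- mean_in(masks$striosome_mask)
  data.frame(subject_id = subject_id, mean_matrix = m, mean_striosome = s,
             pct_diff = 100 * (m - s) / s, ratio = m / s)
}

#' Paired streamline-count comparison
#'
#' Compares case and control total streamline counts (waytotal-style
#' scalars) pairwise, in either tractography direction (bait-to-striatum
#' or compartment-seed-to-gray-matter). Reports the group percent
#' difference, the paired two-tailed t-test, and — when per-compartment
#' columns are supplied — the within-subject matrix:striosome count ratio
#' and its group comparison (paired t on log ratios).
#'
#' @param counts `data.frame` with columns `pair_id`, `group`
#'   (`"case"`/`"control"`) and one or more numeric count columns; every
#'   `pair_id` must appear once per group.
#' @param ratio_cols optional length-2 character vector naming the
#'   matrix-favoring and striosome-favoring count columns for the ratio
#'   comparison.
#' @return A list with `per_direction` (one row per count column:
#'   `direction`, `pct_diff`, `t`, `p_value`) and `ratio` (NULL unless
#'   `ratio_cols` given).
#' @export
paired_count_comparison <- function(counts, ratio_cols = NULL) {
  need <- c("pair_id", "group")
  if (!all(need %in% names(counts))) stop("counts must have pair_id, group")
  ca <- counts[counts$group == "case", , drop = FALSE]
  co <- counts[counts$group == "control", , drop = FALSE]
  if (!setequal(ca$pair_id, co$pair_id) ||
      anyDuplicated(ca$pair_id) || anyDuplicated(co$pair_id))
    stop("unpaired rows: every pair_id needs exactly one case and control")
  co <- co[match(ca$pair_id, co$pair_id), , drop = FALSE]
  value_cols <- setdiff(names(counts), need)
  per_dir <- do.call(rbind, lapply(value_cols, function(cl) {
    x <- ca[[cl]]; y <- co[[cl]]
    if (stats::sd(x - y) > 0) {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(direction = cl,
                 pct_diff = 100 * (mean(x) - mean(y)) / mean(y),
                 t = unname(tt$statistic), p_value = tt$p.value)
    } else {
      data.frame(direction = cl,
                 pct_diff = 100 * (mean(x) - mean(y)) / mean(y),
                 t = if (mean(x - y) == 0) 0 else NA_real_,
                 p_value = if (mean(x - y) == 0) 1 else NA_real_)
    }
  }))
  ratio <- NULL
  if (!is.null(ratio_cols)) {
    stopifnot(length(ratio_cols) == 2L, all(ratio_cols %in% value_cols))
    lr_case <- log(ca[[ratio_cols[1]]] / ca[[ratio_cols[2]]])
    lr_ctrl <- log(co[[ratio_cols[1]]] / co[[ratio_cols[2]]])
    if (stats::sd(lr_case - lr_ctrl) > 0) {
      tt <- stats::t.test(lr_case, lr_ctrl, paired = TRUE)
      ratio <- data.frame(mean_ratio_case = mean(exp(lr_case)),
                          mean_ratio_control = mean(exp(lr_ctrl)),
                          t = unname(tt$statistic), p_value = tt$p.value)
    } else {
      ratio <- data.frame(mean_ratio_case = mean(exp(lr_case)),
                          mean_ratio_control = mean(exp(lr_ctrl)),
                          t = 0, p_value = 1)
    }
  }
  list(per_direction = per_dir, ratio = ratio)
}
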