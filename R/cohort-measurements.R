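#' Assemble the four pre-registered measurement families from a cohort
#'
#' Builds aligned case/control tables for the four paired-test families:
#' \enumerate{
#'   \item compartment volumes and the within-subject M-S difference at
#'     both probability thresholds for the whole striatum (two-tailed),
#'     plus one-tailed caudate/putamen follow-ups in the direction of the
#'     whole-striatum effect;
#'   \item the top-five histogram bins of the matrix-like and
#'     striosome-like biased distributions;
#'   \item per-bait-region extra-striate bias counts;
#'   \item per-somatotopic-zone matrix-like volume (zones derived from
#'     the control-group average probability map).
#' }
#'
#' @param cohort a `striocomp_cohort` (with `keep_maps = TRUE` for
#'   family 4).
#' @param config an [striocomp_config()].
#' @return List of four elements `family1..family4`, each with `case` and
#'   `control` data.frames (rows = pairs, columns = tests); `family1`
#'   additionally carries `alternative`; plus the `zones` object used.
#' @export
cohort_measurements <- function(cohort, config = striocomp_config()) {
  stopifnot(inherits(cohort, "striocomp_cohort"))
  s <- cohort$subjects
  icase <- which(s$group == "case")[order(s$pair_id[s$group == "case"])]
  ictrl <- which(s$group == "control")[order(s$pair_id[s$group == "control"])]
  stopifnot(length(icase) == length(ictrl))

  vol_cols2 <- c("matrix_vol_95", "striosome_vol_95", "m_minus_s_95",
                 "matrix_vol_55", "striosome_vol_55", "m_minus_s_55")
  nuc_cols <- c("caud_matrix_95", "caud_striosome_95", "put_matrix_95",
                "put_striosome_95", "caud_matrix_55", "caud_striosome_55",
                "put_matrix_55", "put_striosome_55")
  f1_case <- s[icase, c(vol_cols2, nuc_cols)]
  f1_ctrl <- s[ictrl, c(vol_cols2, nuc_cols)]
  # one-tailed nucleus follow-ups use a priori directions (matrix expands,
  # striosome shrinks under the compartment-shift hypothesis). Taking the
  # direction from the observed whole-striatum sign instead would make
  # these p-values anti-conservative under the null, since nucleus and
  # whole-striatum volumes are strongly correlated.
  alt <- c(rep("two.sided", length(vol_cols2)),
           ifelse(grepl("matrix", nuc_cols), "greater", "less"))

  nb <- ncol(cohort$mat_hist)
  top <- (nb - 4):nb
  bin_lab <- function(pfx) paste0(pfx, "_bin", top)
  f2_case <- data.frame(cohort$mat_hist[icase, top, drop = FALSE],
                        cohort$strio_hist[icase, top, drop = FALSE])
  f2_ctrl <- data.frame(cohort$mat_hist[ictrl, top, drop = FALSE],
                        cohort$strio_hist[ictrl, top, drop = FALSE])
  names(f2_case) <- names(f2_ctrl) <- c(bin_lab("mat"), bin_lab("strio"))

  f3_case <- as.data.frame(cohort$bait_bias[icase, , drop = FALSE])
  f3_ctrl <- as.data.frame(cohort$bait_bias[ictrl, , drop = FALSE])

  zones <- cohort_zones(cohort, config)
  zc <- zone_counts(cohort, zones, icase, config)
  zt <- zone_counts(cohort, zones, ictrl, config)

  list(family1 = list(case = f1_case, control = f1_ctrl,
                      alternative = alt),
       family2 = list(case = f2_case, control = f2_ctrl),
       family3 = list(case = f3_case, control = f3_ctrl),
       family4 = list(case = zc, control = zt),
       zones = zones)
}

#' Somatotopic zones from a cohort's control-group average map
#'
#' Voxelwise-averages the control subjects' probability maps (the control
#' average serves as the source of the somatotopic maps), constructs the
#' ten leave-one-out contribution maps from the simulator's kernel
#' specification, and thresholds them into disjoint zones.
#'
#' @param cohort a `striocomp_cohort` with kept maps.
#' @param config an [striocomp_config()].
#' @return A `somatotopic_zones` object.
#' @export
cohort_zones <- function(cohort, config = striocomp_config()) {
  if (is.null(cohort$pmaps))
    stop("cohort was simulated with keep_maps = FALSE")
  s <- cohort$subjects
  ictrl <- which(s$group == "control")
  stack <- vapply(cohort$pmaps[ictrl],
                  function(pm) as.vector(pm$p_matrix$data),
                  numeric(prod(dim(cohort$grid$data))))
  pbar <- rowMeans(stack, na.rm = TRUE)
  ndef <- rowSums(!is.na(stack))
  pbar[ndef <= length(ictrl) / 2] <- NA_real_
  g <- cohort$grid
  p_full <- volume_grid(array(pbar, dim(g$data)), g$voxel_size_mm,
                        g$origin, g$axes)
  spec <- somatotopy_spec()
  semi <- cohort$envelope_semiaxes_mm
  maps <- lapply(seq_len(nrow(spec)), function(j) {
    k <- contribution_kernel(p_full, spec[j, ], semi)
    sgn <- if (spec$class[j] == "matrix-favoring") -1 else 1
    p_red <- pmin(pmax(p_full$data + sgn * k, 0), 1)
    region_contribution(p_full,
                        volume_grid(array(p_red, dim(k)),
                                    g$voxel_size_mm, g$origin, g$axes),
                        spec$region[j])
  })
  threshold_zones(maps, config)
}

zone_counts <- function(cohort, zones, rows, config) {
  thr <- config$high_threshold
  out <- vapply(zones$regions, function(rg) {
    zidx <- which(zones$zones[[rg]])
    vapply(cohort$pmaps[rows], function(pm) {
      p <- pm$p_matrix$data[zidx]
      sum(!is.na(p) & p >= thr)
    }, numeric(1))
  }, numeric(length(rows)))
  as.data.frame(out)
}

#' Case-control histogram signature
#'
#' Paired t-statistics summarizing how the case group's biased-probability
#' histograms differ from controls: the indeterminate pool, and each
#' compartment's top-five bins, body (all lower bins) and total. These are
#' the quantities in which the three tissue-level perturbation scenarios
#' leave distinct fingerprints.
#'
#' @param cohort a `striocomp_cohort`.
#' @return One-row `data.frame` of paired t statistics: `t_ind`,
#'   `t_mat_top5`, `t_mat_body`, `t_mat_total`, `t_strio_top5`,
#'   `t_strio_body`, `t_strio_total`, plus the mean paired deltas
#'   (`d_*`) on the voxel-count scale.
#' @export
histogram_signature <- function(cohort) {
  s <- cohort$subjects
  icase <- which(s$group == "case")[order(s$pair_id[s$group == "case"])]
  ictrl <- which(s$group == "control")[order(s$pair_id[s$group == "control"])]
  nb <- ncol(cohort$mat_hist)
  top <- (nb - 4):nb
  body <- seq_len(nb - 5)
  tstat <- function(x, y) {
    d <- x - y
    if (stats::sd(d) == 0) return(c(t = 0, d = mean(d)))
    c(t = mean(d) / (stats::sd(d) / sqrt(length(d))), d = mean(d))
  }
  pairsum <- function(h, rows, cols) rowSums(h[rows, cols, drop = FALSE])
  v <- list(
    ind = tstat(s$indeterminate[icase], s$indeterminate[ictrl]),
    mat_top5 = tstat(pairsum(cohort$mat_hist, icase, top),
                     pairsum(cohort$mat_hist, ictrl, top)),
    mat_body = tstat(pairsum(cohort$mat_hist, icase, body),
                     pairsum(cohort$mat_hist, ictrl, body)),
    mat_total = tstat(pairsum(cohort$mat_hist, icase, seq_len(nb)),
                      pairsum(cohort$mat_hist, ictrl, seq_len(nb))),
    strio_top5 = tstat(pairsum(cohort$strio_hist, icase, top),
                       pairsum(cohort$strio_hist, ictrl, top)),
    strio_body = tstat(pairsum(cohort$strio_hist, icase, body),
                       pairsum(cohort$strio_hist, ictrl, body)),
    strio_total = tstat(pairsum(cohort$strio_hist, icase, seq_len(nb)),
                        pairsum(cohort$strio_hist, ictrl, seq_len(nb))),
    # within-distribution shift: top-five bins minus body, case vs control
    mat_shift = tstat(pairsum(cohort$mat_hist, icase, top) -
                        pairsum(cohort$mat_hist, icase, body),
                      pairsum(cohort$mat_hist, ictrl, top) -
                        pairsum(cohort$mat_hist, ictrl, body)),
    strio_shift = tstat(pairsum(cohort$strio_hist, icase, top) -
                          pairsum(cohort$strio_hist, icase, body),
                        pairsum(cohort$strio_hist, ictrl, top) -
                          pairsum(cohort$strio_hist, ictrl, body)))
  out <- data.frame(t(c(
    stats::setNames(vapply(v, `[`, numeric(1), 1),
                    paste0("t_", names(v))),
    stats::setNames(vapply(v, `[`, numeric(1), 2),
                    paste0("d_", names(v))))))
  out
}

#' Rule-based tissue-scenario classifier
#'
#' Decides which tissue-level perturbation best explains a case-control
#' histogram signature, via a two-split decision tree grounded in the
#' scenarios' mechanisms:
#' \enumerate{
#'   \item A (striosome volume loss) is the only scenario that destroys
#'     striosome-like volume outright: the total striosome-like histogram
#'     collapses (`t_strio_total` strongly negative), while the other two
#'     scenarios conserve striosome tissue.
#'   \item B vs C separate on the body of the matrix-like distribution
#'     (bins below the top five). Matrix expansion (C) floods the whole
#'     upper matrix distribution with new pure-matrix voxels, so the body
#'     gains strongly; architectural simplification (B) drains
#'     mid-probability voxels (fewer oblique striosome cuts), so the body
#'     stalls or loses.
#' }
#' Secondary fingerprints (striosome top-bin gain and indeterminate loss
#' in B; flat striosome and indeterminate pools in C) corroborate the
#' splits but carry less signal per replicate; [histogram_signature()]
#' reports them all.
#'
#' @param signature a row from [histogram_signature()].
#' @param z_strio_loss t-statistic at or below which the striosome-like
#'   total is treated as collapsed (scenario A).
#' @param z_mat_body t-statistic at or below which the matrix body is
#'   treated as non-expanding (scenario B rather than C).
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_scenario <- function(signature, z_strio_loss = -5,
                              z_mat_body = 3) {
  if (signature$t_strio_total <= z_strio_loss) return("A")
  if (signature$t_mat_body <= z_mat_body) return("B")
  "C"
}
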