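#' Assemble a run report
#'
#' Collects stage outputs into deterministic tables and figures: cohort
#' volumetry, per-bin case/control mean histograms over the biased range
#' (45 bins), the four family test reports, and a zone table with
#' matrix-like volume normalized to the control cohort (control = 100
#' percent). Tables are written as CSV; figures as PNG. All numbers in
#' the report come from the stage outputs passed in — figures are
#' rendering artifacts, never a measurement surface.
#'
#' @param cohort a `striocomp_cohort`.
#' @param families list of `test_family` objects (from
#'   [run_test_families()]); optional.
#' @param zone_table `data.frame` from [zone_volumetry()]; optional.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config an [striocomp_config()].
#' @param figures also render PNG figures.
#' @return An object of class `run_report` with the tables, the resolved
#'   config and the seed; written file paths in `$files`.
#' @export
build_report <- function(cohort, families = NULL, zone_table = NULL,
                         out_dir = NULL, config = striocomp_config(),
                         figures = TRUE) {
  stopifnot(inherits(cohort, "striocomp_cohort"))
  s <- cohort$subjects
  vol_cols <- c("matrix_vol_95", "striosome_vol_95", "m_minus_s_95",
                "matrix_vol_55", "striosome_vol_55", "m_minus_s_55",
                "indeterminate")
  volumetry <- do.call(rbind, lapply(vol_cols, function(cl) {
    mc <- mean(s[[cl]][s$group == "case"])
    mt <- mean(s[[cl]][s$group == "control"])
    data.frame(measure = cl, mean_case = mc, mean_control = mt,
               normalized_pct = if (mt != 0) 100 * mc / mt else NA_real_)
  }))
  nb <- ncol(cohort$mat_hist)
  bin_lo <- config$bias_threshold +
    (seq_len(nb) - 1) * config$histogram_bin_width
  hist_tab <- data.frame(
    bin_lo = rep(bin_lo, 2),
    compartment = rep(c("matrix", "striosome"), each = nb),
    mean_case = c(colMeans(cohort$mat_hist[s$group == "case", , drop = FALSE]),
                  colMeans(cohort$strio_hist[s$group == "case", ,
                                             drop = FALSE])),
    mean_control = c(colMeans(cohort$mat_hist[s$group == "control", ,
                                              drop = FALSE]),
                     colMeans(cohort$strio_hist[s$group == "control", ,
                                                drop = FALSE])))
  family_tab <- if (!is.null(families))
    do.call(rbind, lapply(families, function(f)
      cbind(family_id = f$family_id, f$tests,
            threshold = ifelse(is.na(f$threshold), "none",
                               format(f$threshold))))) else NULL
  rep_obj <- structure(
    list(volumetry = volumetry, histograms = hist_tab,
         families = family_tab, zones = zone_table,
         config = unclass(config), seed = cohort$seed, files = character()),
    class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      p <- file.path(out_dir, name)
      write_table_csv(df, p)
      rep_obj$files <<- c(rep_obj$files, p)
    }
    wr(volumetry, "volumetry.csv")
    wr(hist_tab, "histograms.csv")
    wr(family_tab, "families.csv")
    wr(zone_table, "zones.csv")
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(c(unclass(config), list(seed = cohort$seed)),
                         cfg_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    rep_obj$files <- c(rep_obj$files, cfg_path)
    if (figures) {
      rep_obj$files <- c(rep_obj$files,
                         plot_histogram_overlay(hist_tab, out_dir),
                         plot_volumetry(volumetry, out_dir))
      if (!is.null(zone_table))
        rep_obj$files <- c(rep_obj$files,
                           plot_zone_table(zone_table, out_dir))
    }
  }
  rep_obj
}

plot_histogram_overlay <- function(hist_tab, out_dir) {
  long <- rbind(
    data.frame(bin_lo = hist_tab$bin_lo, compartment = hist_tab$compartment,
               group = "case", mean_count = hist_tab$mean_case),
    data.frame(bin_lo = hist_tab$bin_lo, compartment = hist_tab$compartment,
               group = "control", mean_count = hist_tab$mean_control))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_lo,
                                          y = .data$mean_count,
                                          colour = .data$group)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "connection probability bin (lower edge)",
                  y = "mean voxels per bin",
                  title = "Biased-probability histograms (45 bins)") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "histogram_overlay.png")
  ggplot2::ggsave(f, p, width = 8, height = 4)
  f
}

plot_volumetry <- function(volumetry, out_dir) {
  long <- rbind(
    data.frame(measure = volumetry$measure, group = "case",
               mean_vol = volumetry$mean_case),
    data.frame(measure = volumetry$measure, group = "control",
               mean_vol = volumetry$mean_control))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$measure,
                                          y = .data$mean_vol,
                                          fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean voxels",
                  title = "Compartment volumetry") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "volumetry.png")
  ggplot2::ggsave(f, p, width = 7, height = 4)
  f
}

plot_zone_table <- function(zone_table, out_dir) {
  zt <- zone_table[!is.na(zone_table$normalized_pct), , drop = FALSE]
  p <- ggplot2::ggplot(zt, ggplot2::aes(x = .data$zone,
                                        y = .data$normalized_pct)) +
    ggplot2::geom_col(fill = "#d95f02") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "matrix-like volume, % of control",
                  title = "Somatotopic zone volumetry") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "zones.png")
  ggplot2::ggsave(f, p, width = 7, height = 4)
  f
}
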