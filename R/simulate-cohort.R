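#' Simulation parameter sets
#'
#' Problem-size presets for the phantom pipeline. `"full"` is the default
#' desk-scale study condition: a 40 mm striatal envelope (semi-axes
#' 10 x 20 x 10 mm) at 0.25 mm phantom resolution, voxelized to 2 mm.
#' `"reduced"` shrinks the envelope by 0.8 and coarsens the phantom grid
#' to 0.5 mm; it is used for Monte-Carlo calibration runs where thousands
#' of replicates are needed.
#'
#' @param size `"full"` or `"reduced"`.
#' @return Named list of generator arguments.
#' @export
phantom_preset <- function(size = c("full", "reduced")) {
  size <- match.arg(size)
  if (size == "full")
    list(envelope_semiaxes_mm = c(10, 20, 10), spacing_mm = 0.25,
         margin_mm = 3)
  else
    list(envelope_semiaxes_mm = c(8, 16, 8), spacing_mm = 0.5,
         margin_mm = 3)
}

#' Simulate one subject's parcellation inputs
#'
#' Runs the forward pipeline for a single subject-hemistriatum: grow a
#' tissue phantom (optionally perturbed by a scenario), voxelize to
#' diffusion resolution, map tissue fractions through the forward model to
#' streamline counts, and assemble the probability map with a stylized
#' caudate/putamen split (caudate = dorsal-medial-rostral half of the
#' striatal mask by a fixed linear score, putamen = the rest).
#'
#' @param scenario `"none"`, `"A"`, `"B"` or `"C"`.
#' @param magnitude perturbation magnitude (ignored for `"none"`).
#' @param fm a [forward_model()].
#' @param size preset name passed to [phantom_preset()].
#' @param envelope_scale multiplier on the envelope semi-axes (anatomy
#'   size jitter).
#' @param seed RNG seed for this subject.
#' @param subject_id label.
#' @param ... further arguments to [generate_phantom()].
#' @return List: `pmap` (a `probability_map`), `fmap` (`fraction_map`),
#'   `phantom_provenance`, `striatal_volume_voxels`.
#' @export
simulate_subject <- function(scenario = "none", magnitude = 0.2,
                             fm = forward_model(), size = "full",
                             envelope_scale = 1, seed = NULL,
                             subject_id = NA_character_, ...) {
  preset <- phantom_preset(size)
  base_semi <- preset$envelope_semiaxes_mm
  preset$envelope_semiaxes_mm <- base_semi * envelope_scale
  ph <- do.call(generate_phantom,
                c(preset, list(grid_reference_mm = base_semi, seed = seed),
                  list(...)))
  if (scenario != "none")
    ph <- apply_perturbation(ph, scenario, magnitude,
                             seed = if (is.null(seed)) NULL else seed + 1L,
                             quiet = TRUE)
  fmap <- voxelize(ph)
  cp <- fractions_to_counts(fmap, fm,
                            seed = if (is.null(seed)) NULL else seed + 2L)
  nuclei <- split_nuclei(fmap$mask)
  pmap <- compute_probability(cp$counts_matrix, cp$counts_striosome,
                              fmap$mask, nuclei$caudate, nuclei$putamen,
                              subject_id = subject_id)
  list(pmap = pmap, fmap = fmap, phantom_provenance = ph$provenance,
       striatal_volume_voxels = sum(fmap$mask$data))
}

#' Stylized caudate/putamen split of a striatal mask
#'
#' Partitions the mask at the median of the rostro-caudal coordinate
#' (caudate = rostral half, putamen = caudal half), a deliberately
#' one-dimensional stylization of the real nuclei. Splitting on the
#' rostral axis alone leaves the medial and ventral position gradients
#' intact within each nucleus, so centroid-relative offset statistics
#' remain sensitive to them. The split is exact: the two nuclei are
#' disjoint and their union is the striatum.
#'
#' @param mask striatal [region_mask()].
#' @return List with `caudate` and `putamen` [region_mask()]s.
#' @export
split_nuclei <- function(mask) {
  idx <- which(mask$data)
  xyz <- voxel_centers(mask, idx)
  score <- xyz[, 2]
  cut <- stats::median(score)
  cda <- array(FALSE, dim(mask$data)); put <- array(FALSE, dim(mask$data))
  hi <- score > cut
  # resolve the median tie deterministically so the split stays exact
  tie <- which(score == cut)
  n_hi <- sum(hi)
  need <- floor(length(idx) / 2) - n_hi
  if (need > 0 && length(tie)) hi[tie[seq_len(min(need, length(tie)))]] <- TRUE
  cda[idx[hi]] <- TRUE
  put[idx[!hi]] <- TRUE
  list(caudate = region_mask(volume_grid(cda, mask$voxel_size_mm,
                                         mask$origin, mask$axes), "caudate"),
       putamen = region_mask(volume_grid(put, mask$voxel_size_mm,
                                         mask$origin, mask$axes), "putamen"))
}

#' Somatotopic kernel specification for the simulator
#'
#' Ten Gaussian influence kernels, one per bait region, with fixed centres
#' (in envelope-normalized coordinates), widths and amplitudes. They stand
#' in for the leave-one-out probability differences a real bait roster
#' would produce: matrix-favoring regions raise p_matrix locally,
#' striosome-favoring regions lower it.
#'
#' @return `data.frame`: `region`, `class`, `cx`, `cy`, `cz` (normalized
#'   centre), `sd` (normalized width), `amp` (probability amplitude).
#' @export
somatotopy_spec <- function() {
  r <- bait_roster()
  cbind(r, data.frame(
    cx = c(0.35, 0.20, 0.05, 0.40, 0.30, -0.30, -0.45, -0.20, -0.40, -0.10),
    cy = c(0.55, 0.10, -0.30, -0.55, 0.20, 0.65, 0.30, 0.40, -0.10, -0.40),
    cz = c(0.30, 0.50, 0.40, 0.10, -0.20, -0.30, -0.10, -0.40, -0.30, -0.50),
    sd = rep(0.35, 10),
    amp = seq(0.16, 0.08, length.out = 10)))
}

# Gaussian kernel of one spec row evaluated on a diffusion grid (array)
contribution_kernel <- function(grid, spec_row, semiaxes) {
  xyz <- voxel_centers(grid)
  q <- sweep(xyz, 2, semiaxes, "/")
  ctr <- c(spec_row$cx, spec_row$cy, spec_row$cz)
  d2 <- rowSums(sweep(q, 2, ctr, "-")^2)
  array(spec_row$amp * exp(-d2 / (2 * spec_row$sd^2)), dim(grid$data))
}

#' Simulate a matched case-control cohort
#'
#' The study design this analysis assumes: `n_pairs` matched pairs, each
#' with one case and one control. Every subject gets an independent tissue
#' phantom (cases perturbed by the assigned scenario), run through
#' voxelization, the forward model and parcellation. The bundle also
#' carries compartment-dependent FA maps summarized over equal-volume
#' masks (matrix-like FA higher by `fa_gap` at the tissue level),
#' waytotal-style streamline totals with a global case deficit, per-region
#' extra-striate bias counts, and demographics satisfying the matching
#' windows (ages 78-508 months, 30 percent female pairs, five originating
#' studies, ADOS-high/mid diagnosis categories and CSS scores for a
#' sub-cohort of cases).
#'
#' @param n_pairs number of matched pairs (>= 2).
#' @param scenario perturbation scenario for cases: `"none"`, `"A"`,
#'   `"B"`, `"C"`.
#' @param magnitude perturbation magnitude.
#' @param fm a [forward_model()].
#' @param config an [striocomp_config()].
#' @param size phantom preset (`"full"` or `"reduced"`).
#' @param fa_levels FA at a pure-matrix voxel and at a striosome-rich
#'   voxel (defaults 0.222 and 0.213, a 4.2 percent gap).
#' @param fa_ref_fraction striosome fraction at which FA reaches its
#'   striosome level.
#' @param fa_noise per-voxel FA noise SD.
#' @param count_deficit fractional case deficit in completed streamlines
#'   (applied to both compartments' totals; default 0.10).
#' @param size_jitter_sd SD of the log-normal per-subject envelope scale.
#' @param seed master seed; all per-subject seeds are fanned out from it.
#' @param keep_maps keep per-subject probability arrays (needed for zone
#'   volumetry and group-average maps).
#' @return An object of class `striocomp_cohort`: `subjects` data.frame,
#'   `mat_hist` / `strio_hist` (n x 45 matrices), `bait_bias` (n x 10),
#'   `pmaps` (optional list), `grid` geometry, and the generating
#'   parameters.
#' @export
simulate_cohort <- function(n_pairs, scenario = c("none", "A", "B", "C"),
                            magnitude = 0.2, fm = forward_model(),
                            config = striocomp_config(), size = "full",
                            fa_levels = c(matrix = 0.222,
                                          striosome = 0.213),
                            fa_ref_fraction = 0.5, fa_noise = 0.01,
                            count_deficit = 0.10, size_jitter_sd = 0.03,
                            seed = NULL, keep_maps = TRUE) {
  scenario <- match.arg(scenario)
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  demo <- simulate_demographics(n_pairs)
  n <- nrow(demo)
  subject_seeds <- sample.int(2^31 - 10L, n) # fan-out, kept under 2^31
  nb <- round((1 - config$bias_threshold) / config$histogram_bin_width)
  mat_hist <- matrix(0L, n, nb)
  strio_hist <- matrix(0L, n, nb)
  roster <- bait_roster()
  bait_bias <- matrix(0, n, nrow(roster),
                      dimnames = list(NULL, roster$region))
  pmaps <- if (keep_maps) vector("list", n) else NULL
  rows <- vector("list", n)
  grid <- NULL
  base_way <- c(bait_matrix = 1.0e6, bait_striosome = 0.9e6,
                seed_matrix = 7.0e5, seed_striosome = 9.1e5)
  for (i in seq_len(n)) {
    is_case <- demo$group[i] == "case"
    sc <- if (is_case) scenario else "none"
    # envelope sizes live on a discrete 3-percent grid, clamped at two
    # SDs: inter-subject anatomy varies while the geometry stays
    # cacheable and inside the fixed grid margin
    esc <- round(exp(stats::rnorm(1, 0, size_jitter_sd)) / 0.03) * 0.03
    esc <- min(max(esc, 1 - 2 * size_jitter_sd), 1 + 2 * size_jitter_sd)
    sub <- simulate_subject(scenario = sc, magnitude = magnitude, fm = fm,
                            size = size, envelope_scale = esc,
                            seed = subject_seeds[i],
                            subject_id = demo$subject_id[i])
    pm <- sub$pmap
    if (is.null(grid)) grid <- pm$p_matrix
    vol <- compartment_volumes(pm, config = config)
    mh <- probability_histogram(pm, "matrix", config)
    sh <- probability_histogram(pm, "striosome", config)
    mat_hist[i, ] <- mh$count
    strio_hist[i, ] <- sh$count
    # FA: tissue-level compartment dependence + voxel noise
    f <- sub$fmap$f$data
    fa <- fa_levels[["matrix"]] -
      (fa_levels[["matrix"]] - fa_levels[["striosome"]]) *
      pmin(ifelse(is.na(f), 0, f) / fa_ref_fraction, 1) +
      stats::rnorm(length(f), 0, fa_noise)
    fa_map <- volume_grid(array(fa, dim(f)), pm$p_matrix$voxel_size_mm,
                          pm$p_matrix$origin)
    evm <- suppressWarnings(build_equal_volume_masks(pm, config))
    fa_row <- if (evm$achieved_volume > 0)
      scalar_by_compartment(fa_map, evm, demo$subject_id[i])
    else data.frame(subject_id = demo$subject_id[i], mean_matrix = NA_real_,
                    mean_striosome = NA_real_, pct_diff = NA_real_,
                    ratio = NA_real_)
    # waytotal-style streamline totals; cases carry a global deficit
    subj_factor <- exp(stats::rnorm(1, 0, 0.10))
    dir_noise <- exp(stats::rnorm(4, 0, 0.08))
    deficit <- if (is_case) 1 - count_deficit else 1
    way <- round(base_way * subj_factor * dir_noise * deficit)
    # per-bait extra-striate bias counts (null: no group effect)
    bait_bias[i, ] <- round(1000 * subj_factor *
                              exp(stats::rnorm(nrow(roster), 0, 0.15)))
    w <- function(nuc, thr, col) vol[[col]][vol$nucleus == nuc &
                                              vol$threshold == thr]
    bt <- config$bias_threshold; ht <- config$high_threshold
    rows[[i]] <- data.frame(
      demo[i, , drop = FALSE],
      striatal_volume_voxels = sub$striatal_volume_voxels,
      strio_conservation = sub$fmap$strio_in_mask / sub$fmap$strio_total,
      matrix_vol_95 = w("striatum", ht, "matrix_vol"),
      striosome_vol_95 = w("striatum", ht, "striosome_vol"),
      m_minus_s_95 = w("striatum", ht, "m_minus_s"),
      matrix_vol_55 = w("striatum", bt, "matrix_vol"),
      striosome_vol_55 = w("striatum", bt, "striosome_vol"),
      m_minus_s_55 = w("striatum", bt, "m_minus_s"),
      indeterminate = w("striatum", ht, "indeterminate"),
      caud_matrix_95 = w("caudate", ht, "matrix_vol"),
      caud_striosome_95 = w("caudate", ht, "striosome_vol"),
      put_matrix_95 = w("putamen", ht, "matrix_vol"),
      put_striosome_95 = w("putamen", ht, "striosome_vol"),
      caud_matrix_55 = w("caudate", bt, "matrix_vol"),
      caud_striosome_55 = w("caudate", bt, "striosome_vol"),
      put_matrix_55 = w("putamen", bt, "matrix_vol"),
      put_striosome_55 = w("putamen", bt, "striosome_vol"),
      fa_matrix = fa_row$mean_matrix,
      fa_striosome = fa_row$mean_striosome,
      equal_volume_n = evm$achieved_volume,
      waytotal_bait_matrix = way[["bait_matrix"]],
      waytotal_bait_striosome = way[["bait_striosome"]],
      waytotal_seed_matrix = way[["seed_matrix"]],
      waytotal_seed_striosome = way[["seed_striosome"]])
    if (keep_maps) pmaps[[i]] <- pm
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  structure(
    list(subjects = subjects, mat_hist = mat_hist, strio_hist = strio_hist,
         bait_bias = bait_bias, pmaps = pmaps, grid = grid,
         scenario = scenario, magnitude = magnitude, n_pairs = n_pairs,
         size = size, fm = fm, config = config, seed = seed,
         envelope_semiaxes_mm = phantom_preset(size)$envelope_semiaxes_mm),
    class = "striocomp_cohort")
}

#' Simulated cohort demographics
#'
#' Matched-pair demographics mirroring the assumed study design: ages
#' 78-508 months (mean about 182), sex-matched pairs (30 percent female),
#' five originating studies with realistic weights (89 percent of pairs
#' intra-study), 79 percent race-matched pairs, ADOS-high (77.9 percent)
#' vs ADOS-mid diagnosis categories for cases, and calibrated severity
#' scores (3-10) for 72.8 percent of cases.
#'
#' @param n_pairs number of pairs.
#' @return `data.frame` with one row per subject (2 x n_pairs).
#' @export
simulate_demographics <- function(n_pairs) {
  studies <- c("study1", "study2", "study3", "study45")
  study_w <- c(0.556, 0.232, 0.150, 0.062)
  races <- c("White", "Black", "Asian", "NativeAmerican", "MoreThanOne")
  race_w <- c(0.81, 0.08, 0.06, 0.01, 0.04)
  rows <- vector("list", 2L * n_pairs)
  for (k in seq_len(n_pairs)) {
    # right-skewed age distribution, 78-508 months, mean about 182
    age <- round(stats::rlnorm(1, log(170), 0.35))
    age <- max(78, min(508, age))
    sex <- if (stats::runif(1) < 0.30) "F" else "M"
    study <- sample(studies, 1, prob = study_w)
    race <- sample(races, 1, prob = race_w)
    win <- age_match_window(age)
    age_ctrl <- age + round(stats::runif(1, -win, win))
    study_ctrl <- if (stats::runif(1) < 0.89) study
                  else sample(studies, 1, prob = study_w)
    race_ctrl <- if (stats::runif(1) < 0.79) race
                 else sample(races, 1, prob = race_w)
    diagnosis <- if (stats::runif(1) < 0.779) "ADOS-high" else "ADOS-mid"
    css <- if (stats::runif(1) < 0.728)
      max(3, min(10, round(stats::rnorm(1, 7.1, 1.6)))) else NA_real_
    rows[[2 * k - 1]] <- data.frame(
      subject_id = sprintf("case_%03d", k), pair_id = k, group = "case",
      age_months = age, sex = sex, study_id = study, race_label = race,
      diagnosis = diagnosis, css = css, hemisphere = "R")
    rows[[2 * k]] <- data.frame(
      subject_id = sprintf("ctrl_%03d", k), pair_id = k, group = "control",
      age_months = age_ctrl, sex = sex, study_id = study_ctrl,
      race_label = race_ctrl, diagnosis = "TD", css = NA_real_,
      hemisphere = "R")
  }
  do.call(rbind, rows)
}

#' @export
print.striocomp_cohort <- function(x, ...) {
  cat("<striocomp_cohort> ", x$n_pairs, " pairs, scenario ", x$scenario,
      if (x$scenario != "none") paste0(" @ ", x$magnitude), ", size ",
      x$size, "\n", sep = "")
  invisible(x)
}
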