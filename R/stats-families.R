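#' Benjamini-Hochberg step-up procedure
#'
#' Standard step-up control of the false discovery rate within one family
#' of tests: with ordered p-values p_(1) <= ... <= p_(m), find the largest
#' rank k* with p_(k*) <= q k*/m and reject the k* smallest. The reported
#' corrected significance threshold is q k*/m; when nothing is rejected no
#' threshold is reported (`NA`, printed as "none") rather than q/m.
#'
#' @param p_values numeric p-values in [0, 1] (NA allowed; NA entries are
#'   never rejected and do not count toward m).
#' @param q false discovery level.
#' @return List: `threshold` (q k*/m or NA), `reject` (logical, input
#'   order), `k` (number of rejections), `m` (family size).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value family")
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (!length(p)) stop("empty p-value family (all NA)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  passing <- which(ps <= q * seq_len(m) / m)
  k <- if (length(passing)) max(passing) else 0L
  reject_sorted <- seq_len(m) <= k
  reject <- logical(m)
  reject[o] <- reject_sorted
  out <- rep(FALSE, length(p_values))
  out[ok] <- reject
  list(threshold = if (k > 0) q * k / m else NA_real_,
       reject = out, k = k, m = m)
}

#' Paired t-tests for one pre-registered family
#'
#' Runs a paired t-test per measurement column of matched case/control
#' tables and applies [bh_fdr()] within the family. Tests with zero
#' within-pair variance are reported with p = 1 when the difference is
#' identically zero, NA otherwise (degenerate), and NA tests do not count
#' toward the family size.
#'
#' @param case_tab,control_tab numeric `data.frame`s with identical
#'   column names (one per test) and rows aligned by matched pair.
#' @param family_id identifier 1-4 (or a label).
#' @param q false discovery level.
#' @param alternative `"two.sided"` (default) or a vector per test (e.g.
#'   `"greater"`/`"less"` for one-tailed follow-ups).
#' @return An object of class `test_family`: a `data.frame` `tests`
#'   (`test_label`, `effect` = mean paired difference, `pct_diff`, `t`,
#'   `p_value`, `reject`) plus `family_id`, `q`, `threshold`, `k`, `m`.
#' @export
test_family <- function(case_tab, control_tab, family_id, q = 0.05,
                        alternative = "two.sided") {
  stopifnot(identical(names(case_tab), names(control_tab)),
            nrow(case_tab) == nrow(control_tab))
  if (nrow(case_tab) < 2) stop("family with <2 pairs")
  labs <- names(case_tab)
  alternative <- rep(alternative, length.out = length(labs))
  rows <- lapply(seq_along(labs), function(i) {
    x <- case_tab[[i]]; y <- control_tab[[i]]
    d <- x - y
    eff <- mean(d)
    pct <- if (mean(y) != 0) 100 * eff / mean(y) else NA_real_
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative[i])
      data.frame(test_label = labs[i], effect = eff, pct_diff = pct,
                 t = unname(tt$statistic), p_value = tt$p.value)
    } else {
      data.frame(test_label = labs[i], effect = eff, pct_diff = pct,
                 t = if (eff == 0) 0 else NA_real_,
                 p_value = if (eff == 0) 1 else NA_real_)
    }
  })
  tests <- do.call(rbind, rows)
  bh <- bh_fdr(tests$p_value, q)
  tests$reject <- bh$reject
  structure(list(family_id = family_id, tests = tests, q = q,
                 threshold = bh$threshold, k = bh$k, m = bh$m),
            class = "test_family")
}

#' @export
print.test_family <- function(x, ...) {
  cat("<test_family ", x$family_id, "> m = ", x$m, ", rejections = ", x$k,
      ", corrected threshold = ",
      if (is.na(x$threshold)) "none" else format(x$threshold), "\n", sep = "")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Run the four pre-registered test families
#'
#' Family 1: compartment volumes (matrix-like, striosome-like) and the
#' within-subject M-S difference at both probability thresholds for the
#' whole striatum (two-tailed), plus the caudate/putamen follow-ups at the
#' same thresholds (one-tailed, in the direction observed for the whole
#' striatum). Family 2: the top-five histogram bins of each compartment's
#' biased distribution. Family 3: per-bait-region extra-striate bias
#' counts. Family 4: per-somatotopic-zone matrix-like volume. Each family
#' is Benjamini-Hochberg corrected independently at `q`.
#'
#' @param meas a measurement bundle as returned by
#'   [cohort_measurements()]: a list of aligned case/control tables per
#'   family.
#' @param config an [striocomp_config()].
#' @return Named list of four `test_family` objects.
#' @export
run_test_families <- function(meas, config = striocomp_config()) {
  q <- config$fdr_q
  f1 <- test_family(meas$family1$case, meas$family1$control, 1L, q,
                    alternative = meas$family1$alternative)
  f2 <- test_family(meas$family2$case, meas$family2$control, 2L, q)
  f3 <- test_family(meas$family3$case, meas$family3$control, 3L, q)
  f4 <- test_family(meas$family4$case, meas$family4$control, 4L, q)
  list(family1 = f1, family2 = f2, family3 = f3, family4 = f4)
}

#' Regression harness for matrix-like volume
#'
#' Multiple linear regression of highly-biased matrix-like volume
#' (p >= 0.95) on demographic and experimental covariates: diagnosis,
#' originating study, hemisphere, total striatal volume, sex and race.
#' Age is excluded (it is collinear with striatal volume, which dominates).
#' A rank-deficient design is reported, never silently dropped. A
#' secondary model restricted to the significant covariates plus their
#' interactions, and a severity model (volume ~ CSS) for the sub-cohort
#' with calibrated severity scores, are fitted when requested.
#'
#' @param subjects `data.frame` with `matrix_vol_95` plus any of
#'   `diagnosis`, `study_id`, `hemisphere`, `striatal_volume_voxels`,
#'   `sex`, `race_label`, `css`.
#' @param covariates character vector of covariate column names to use.
#' @param secondary fit the significant-covariates + interactions model.
#' @param alpha significance level used to pick secondary covariates.
#' @return List: `model` (lm), `coefficients` (data.frame with estimates,
#'   t, p), `aliased` (names of any non-estimable coefficients),
#'   `r_squared`, and optionally `secondary` and `css_model`
#'   (with `css_ci`, the 95 percent CI on the CSS slope).
#' @export
regression_harness <- function(subjects,
                               covariates = c("diagnosis", "study_id",
                                              "hemisphere",
                                              "striatal_volume_voxels",
                                              "sex", "race_label"),
                               secondary = FALSE, alpha = 0.05) {
  stopifnot("matrix_vol_95" %in% names(subjects))
  covariates <- intersect(covariates, names(subjects))
  covariates <- covariates[vapply(covariates, function(cl)
    length(unique(subjects[[cl]])) > 1, logical(1))]
  if (!length(covariates)) {
    fml <- stats::as.formula("matrix_vol_95 ~ 1")
  } else {
    fml <- stats::as.formula(paste("matrix_vol_95 ~",
                                   paste(covariates, collapse = " + ")))
  }
  fit <- stats::lm(fml, data = subjects)
  sm <- summary(fit)
  aliased <- names(which(sm$aliased))
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p_value")
  coefs$term <- rownames(coefs); rownames(coefs) <- NULL
  # a zero-variance response explains nothing; summary.lm's 0/0 is noise
  r2 <- if (stats::var(subjects$matrix_vol_95) < 1e-12) 0 else sm$r.squared
  out <- list(model = fit, coefficients = coefs, aliased = aliased,
              r_squared = r2)
  if (length(aliased))
    out$rank_deficient <- paste("non-estimable terms:",
                                paste(aliased, collapse = ", "))
  if (secondary && length(covariates)) {
    sig_terms <- unique(unlist(lapply(covariates, function(cl) {
      hit <- grepl(paste0("^", cl), coefs$term) & coefs$p_value < alpha
      if (any(hit, na.rm = TRUE)) cl else NULL
    })))
    if (length(sig_terms) >= 1) {
      f2 <- stats::as.formula(paste("matrix_vol_95 ~ (",
                                    paste(sig_terms, collapse = " + "),
                                    ")^2"))
      out$secondary <- stats::lm(f2, data = subjects)
    }
  }
  if ("css" %in% names(subjects) && any(!is.na(subjects$css))) {
    sub <- subjects[!is.na(subjects$css), , drop = FALSE]
    cfit <- stats::lm(matrix_vol_95 ~ css, data = sub)
    out$css_model <- cfit
    out$css_ci <- stats::confint(cfit)["css", ]
  }
  out
}
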