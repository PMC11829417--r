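test_that("sex is an obligatory match and age windows bind by band", {
  subjects <- data.frame(
    subject_id = c("c1", "t1", "t2"),
    group = c("case", "control", "control"),
    age_months = c(100, 111, 100),
    sex = c("M", "M", "F"),
    study_id = "s1", race_label = "White")
  res <- match_pairs(subjects)
  expect_equal(res$pairs$control_id, "t1")      # same-sex despite larger gap
  # 250-month case: 24-month window; sole same-sex control 30 months away
  s2 <- data.frame(subject_id = c("c1", "t1"),
                   group = c("case", "control"),
                   age_months = c(250, 280), sex = "M",
                   study_id = "s1", race_label = "White")
  expect_equal(nrow(match_pairs(s2)$pairs), 0)
  # 400-month case: 48-month window admits a 40-month gap
  s3 <- s2; s3$age_months <- c(400, 440)
  expect_equal(nrow(match_pairs(s3)$pairs), 1)
  # boundary 240 months takes the younger band's 12-month window
  s4 <- s2; s4$age_months <- c(240, 255)
  expect_equal(nrow(match_pairs(s4)$pairs), 0)
  expect_error(match_pairs(subjects[subjects$group == "case", ]),
               "empty cohorts")
})

test_that("matching prefers intra-study, then age, then race, deterministically", {
  subjects <- data.frame(
    subject_id = c("c1", "tA", "tB", "tC"),
    group = c("case", rep("control", 3)),
    age_months = c(120, 121, 124, 125),
    sex = "F",
    study_id = c("s1", "s2", "s1", "s1"),
    race_label = c("White", "White", "Black", "White"))
  res <- match_pairs(subjects)
  # tA has the smallest gap but is cross-study; tB beats tC on age
  expect_equal(res$pairs$control_id, "tB")
  # race breaks an age tie
  s2 <- subjects; s2$age_months <- c(120, 121, 124, 124)
  expect_equal(match_pairs(s2)$pairs$control_id, "tC")
  expect_identical(match_pairs(subjects)$pairs,
                   match_pairs(subjects)$pairs)   # deterministic
})

test_that("emitted pairs always satisfy the constraints, nobody used twice", {
  set.seed(81)
  for (rep in 1:5) {
    n <- 40
    subjects <- data.frame(
      subject_id = sprintf("s%02d_%d", 1:(2 * n), rep),
      group = rep(c("case", "control"), each = n),
      age_months = round(runif(2 * n, 78, 508)),
      sex = sample(c("M", "F"), 2 * n, replace = TRUE),
      study_id = sample(c("s1", "s2", "s3"), 2 * n, replace = TRUE),
      race_label = sample(c("White", "Black"), 2 * n, replace = TRUE))
    res <- match_pairs(subjects)
    p <- res$pairs
    ids <- c(p$case_id, p$control_id)
    expect_equal(anyDuplicated(ids), 0)
    if (nrow(p)) {
      cs <- subjects[match(p$case_id, subjects$subject_id), ]
      ct <- subjects[match(p$control_id, subjects$subject_id), ]
      expect_true(all(cs$sex == ct$sex))
      expect_true(all(abs(cs$age_months - ct$age_months) <=
                        age_match_window(cs$age_months)))
    }
    expect_setequal(c(ids, res$unmatched), subjects$subject_id)
  }
})

test_that("BH step-up reproduces the conventional family thresholds", {
  # rank-1-only families: critical value q * 1 / m
  p7 <- c(0.001, rep(0.9, 6))
  r7 <- bh_fdr(p7, 0.05)
  expect_equal(r7$threshold, 0.05 / 7)
  expect_equal(round(r7$threshold, 4), 0.0071)
  expect_equal(r7$k, 1)
  p10 <- c(0.004, rep(0.9, 9))
  r10 <- bh_fdr(p10, 0.05)
  expect_equal(r10$threshold, 5.0e-3)
  r <- bh_fdr(c(0.001, 0.02, 0.03, 0.04, 0.06), 0.05)
  expect_equal(r$k, 4)
  expect_equal(r$threshold, 0.04)
  expect_true(all(r$reject[1:4]) && !r$reject[5])
  none <- bh_fdr(rep(0.9, 5), 0.05)
  expect_true(is.na(none$threshold))
  expect_equal(none$k, 0)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH matches the exhaustive oracle and p.adjust on 0.01-grid families", {
  set.seed(82)
  for (rep in 1:200) {
    m <- sample(1:10, 1)
    p <- sample(seq(0, 1, by = 0.01), m, replace = TRUE)
    got <- bh_fdr(p, 0.05)
    orc <- bh_oracle(p, 0.05)
    expect_equal(got$k, orc$k)
    expect_equal(got$threshold, orc$threshold)
    expect_equal(got$reject, orc$reject)
    # independent library cross-check
    expect_equal(got$reject, p.adjust(p, "BH") <= 0.05 + 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("identical case/control tables reject nothing in any family", {
  set.seed(83)
  tab <- as.data.frame(matrix(rnorm(80), 10, 8))
  fam <- test_family(tab, tab, 1L)
  expect_true(all(fam$tests$p_value == 1))
  expect_equal(fam$k, 0)
  expect_output(print(fam), "none")
  expect_error(test_family(tab[1, , drop = FALSE], tab[1, , drop = FALSE], 1L),
               "<2 pairs")
})

test_that("family 2 holds five top-bin tests per compartment", {
  co <- simulate_cohort(3, "none", size = "reduced", seed = 84)
  meas <- cohort_measurements(co)
  labs <- names(meas$family2$case)
  expect_equal(sum(grepl("^mat_", labs)), 5)
  expect_equal(sum(grepl("^strio_", labs)), 5)
  fams <- run_test_families(meas)
  expect_equal(fams$family2$m, 10)
  expect_equal(fams$family3$m, 10)
  expect_equal(fams$family4$m, 10)
  expect_equal(fams$family1$m, 14)
})

test_that("regression harness recovers injected structure", {
  set.seed(85)
  n <- 400
  sv <- runif(n, 700, 1200)
  subj <- data.frame(
    matrix_vol_95 = 0.373 * sv + rnorm(n, 0, 1e-6),
    striatal_volume_voxels = sv,
    diagnosis = sample(c("TD", "ADOS-mid", "ADOS-high"), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE))
  fit <- regression_harness(subj)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "striatal_volume_voxels"], 0.373,
               tolerance = 1e-4)
  # constant response: slopes vanish, R^2 = 0
  flat <- subj; flat$matrix_vol_95 <- 100
  ffit <- regression_harness(flat)
  slopes <- ffit$coefficients
  expect_true(all(abs(slopes$estimate[slopes$term != "(Intercept)"]) < 1e-9))
  expect_equal(ffit$r_squared, 0)
})

test_that("a null CSS effect yields a CI covering zero", {
  set.seed(86)
  n <- 160
  subj <- data.frame(
    matrix_vol_95 = rnorm(n, 248, 40),
    striatal_volume_voxels = runif(n, 700, 1200),
    css = sample(3:10, n, replace = TRUE))
  fit <- regression_harness(subj)
  expect_true(fit$css_ci[1] < 0 && fit$css_ci[2] > 0)
  expect_lt(summary(fit$css_model)$r.squared, 0.05)
})

test_that("rank deficiency is reported, not silently dropped", {
  set.seed(87)
  subj <- data.frame(
    matrix_vol_95 = rnorm(40),
    striatal_volume_voxels = rep(c(800, 900), 20),
    hemisphere = rep(c("L", "R"), 20))   # perfectly collinear with volume
  subj$diagnosis <- ifelse(subj$hemisphere == "L", "TD", "ADOS-high")
  fit <- regression_harness(subj)
  expect_true(length(fit$aliased) > 0)
  expect_match(fit$rank_deficient, "non-estimable")
})
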