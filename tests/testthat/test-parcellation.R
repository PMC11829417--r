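cfg <- striocomp_config()

test_that("probability is the count ratio, with zero-evidence flagged", {
  cm <- toy_grid(c(9, 5, 0, 7, rep(0, 60)))
  cs <- toy_grid(c(1, 5, 0, 3, rep(0, 60)))
  s <- region_mask(toy_grid(c(1, 1, 1, 1, rep(0, 60))), "striatum")
  pm <- compute_probability(cm, cs, s)
  expect_equal(pm$p_matrix$data[1], 0.9)
  expect_equal(pm$p_matrix$data[2], 0.5)
  expect_true(is.na(pm$p_matrix$data[3]))
  expect_true(pm$undefined[3])
  expect_false(any(pm$undefined[c(1, 2, 4)]))
  # undefined voxels enter no volumetry denominator
  vols <- compartment_volumes(pm, config = cfg)
  st <- vols[vols$nucleus == "striatum" & vols$threshold == 0.55, ]
  expect_equal(st$matrix_vol + st$striosome_vol + st$indeterminate, 3)
})

test_that("probability computation validates grids and counts", {
  cm <- toy_grid(rep(1, 64)); cs <- toy_grid(rep(1, 64))
  s <- region_mask(toy_grid(rep(1, 64)), "striatum")
  bad <- volume_grid(array(1, c(2, 2, 2)))
  expect_error(compute_probability(cm, bad, s), "grid mismatch")
  neg <- toy_grid(c(-1, rep(1, 63)))
  expect_error(compute_probability(neg, cs, s), "negative counts")
  empty <- region_mask(toy_grid(rep(0, 64)), "striatum")
  expect_error(compute_probability(cm, cs, empty), "empty")
})

test_that("classification honours the bias rule and the open band", {
  pm <- toy_pmap(c(0.55, 0.50, 0.40, 0.45, 0.5499999, 1.0, 0.0))
  par <- classify(pm, cfg)
  lab <- par$labels$data
  expect_equal(lab[1], 1L)   # p = 0.55 -> matrix-like (>= rule verbatim)
  expect_equal(lab[2], 3L)   # p = 0.50 -> indeterminate
  expect_equal(lab[3], 2L)   # p = 0.40 -> striosome-like
  expect_equal(lab[4], 2L)   # band endpoint 0.45 is biased
  expect_equal(lab[5], 3L)   # just inside the open interval
  expect_equal(lab[6], 1L); expect_equal(lab[7], 2L)
})

test_that("compartment volumes match a hand-enumerated toy map", {
  pm <- toy_pmap(c(0.96, 0.80, 0.50, 0.10))
  vols <- compartment_volumes(pm, thresholds = c(0.95, 0.55), config = cfg)
  st <- vols[vols$nucleus == "striatum", ]
  expect_equal(st$matrix_vol[st$threshold == 0.95], 1)
  expect_equal(st$matrix_vol[st$threshold == 0.55], 2)
  expect_equal(st$striosome_vol[st$threshold == 0.55], 1)
  expect_equal(st$striosome_vol[st$threshold == 0.95], 0)
  expect_equal(unique(st$indeterminate), 1)
  expect_equal(st$m_minus_s[st$threshold == 0.55], 1)
})

test_that("uniform high-probability map puts all volume in matrix", {
  pm <- toy_pmap(rep(0.97, 100), d = c(100, 1, 1))
  vols <- compartment_volumes(pm, config = cfg)
  st <- vols[vols$nucleus == "striatum", ]
  expect_equal(st$matrix_vol, c(100, 100))
  expect_equal(st$striosome_vol, c(0, 0))
  expect_equal(st$m_minus_s, c(100, 100))
})

test_that("caudate and putamen volumes sum to the striatal volume", {
  set.seed(21)
  pm <- toy_pmap(runif(40), d = c(40, 1, 1))
  vols <- compartment_volumes(pm, config = cfg)
  for (thr in unique(vols$threshold)) {
    v <- vols[vols$threshold == thr, ]
    for (col in c("matrix_vol", "striosome_vol", "indeterminate"))
      expect_equal(v[[col]][v$nucleus == "caudate"] +
                     v[[col]][v$nucleus == "putamen"],
                   v[[col]][v$nucleus == "striatum"])
  }
})

test_that("partition conservation, threshold monotonicity and swap symmetry", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    cm <- toy_grid(c(rpois(n, 40), rep(0, 4)))
    cs <- toy_grid(c(rpois(n, 40), rep(0, 4)))
    s <- region_mask(toy_grid(rep(1, 64)), "striatum")
    pm <- compute_probability(cm, cs, s)
    par <- classify(pm, cfg)
    counts <- tabulate(par$labels$data[s$data], 4)
    expect_equal(sum(counts), 64)                      # conservation
    # monotonicity: raising the threshold never grows a biased class
    for (bt in c(0.6, 0.7, 0.9)) {
      cfg2 <- striocomp_config(bias_threshold = bt,
                               indeterminate_band = c(1 - bt, bt),
                               histogram_bin_width = 0.01)
      if (abs(((1 - bt) / 0.01) %% 1) > 1e-9) next
      par2 <- classify(pm, cfg2)
      c2 <- tabulate(par2$labels$data[s$data], 4)
      expect_lte(c2[1], counts[1])
      expect_lte(c2[2], counts[2])
    }
    # swapping count volumes swaps the label sets exactly
    pm_sw <- compute_probability(cs, cm, s)
    par_sw <- classify(pm_sw, cfg)
    expect_equal(which(par_sw$labels$data == 1L),
                 which(par$labels$data == 2L))
    expect_equal(which(par_sw$labels$data == 2L),
                 which(par$labels$data == 1L))
  }
})

test_that("the biased histogram has 45 closed-final bins conserving volume", {
  h <- probability_histogram(toy_pmap(c(0.55, 0.99, 1.0, 0.7)), "matrix",
                             cfg)
  expect_equal(nrow(h), 45)
  expect_equal(h$bin_lo[1], 0.55)
  expect_equal(h$bin_hi[45], 1.00)
  expect_equal(sum(h$count), 4)           # p = 1.0 lands in the final bin
  expect_equal(h$count[45], 2)            # 0.99 and 1.0 share [0.99, 1.00]
  # one voxel per bin when probabilities sit at bin midpoints
  mids <- seq(0.555, 0.995, by = 0.01)
  h2 <- probability_histogram(toy_pmap(mids, d = c(45, 1, 1)), "matrix",
                              cfg)
  expect_true(all(h2$count == 1))
})

test_that("histogram totals equal the bias-threshold volumes per compartment", {
  set.seed(41)
  pm <- toy_pmap(runif(200), d = c(200, 1, 1))
  vols <- compartment_volumes(pm, config = cfg)
  st <- vols[vols$nucleus == "striatum" & vols$threshold == 0.55, ]
  expect_equal(sum(probability_histogram(pm, "matrix", cfg)$count),
               st$matrix_vol)
  expect_equal(sum(probability_histogram(pm, "striosome", cfg)$count),
               st$striosome_vol)
})

test_that("the full-range variant bins the whole distribution in 100 bins", {
  pm <- toy_pmap(c(0, 0.004, 0.5, 1))
  h <- probability_histogram(pm, "matrix", cfg, full_range = TRUE)
  expect_equal(nrow(h), 100)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[1], 2)
  expect_equal(h$count[100], 1)
})
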