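# phantom tests run at the reduced preset where full fidelity is not the
# point; geometry-sensitive checks use the full preset
red <- phantom_preset("reduced")

test_that("the generator hits its volume-fraction target inside the envelope", {
  ph <- do.call(generate_phantom, c(red, list(seed = 91)))
  expect_gte(ph$achieved_fraction, 0.9 * ph$target_fraction)
  expect_lte(ph$achieved_fraction, 1.1 * ph$target_fraction)
  expect_gte(length(ph$branches), 20)
  # striosome fully interior to the envelope
  expect_true(all(ph$envelope[ph$strio]))
  expect_equal(sum(ph$strio), ph$strio_count)
})

test_that("an isotropic phantom is centred; gradients displace the striosome", {
  ph0 <- do.call(generate_phantom,
                 c(red, list(gradient = c(0, 0, 0), seed = 92)))
  ctr <- colMeans(arrayInd(which(ph0$strio), ph0$dims))
  mid <- (ph0$dims + 1) / 2
  # isotropy: striosome centroid near the envelope centroid (in voxels)
  expect_true(all(abs(ctr - mid) * ph0$spacing_mm < 2.5))
  phg <- do.call(generate_phantom,
                 c(red, list(gradient = c(1.5, 1.5, 1.5), seed = 92)))
  sxyz <- voxel_centers(volume_grid(phg$strio, rep(phg$spacing_mm, 3),
                                    phg$origin), which(phg$strio))
  mxyz <- voxel_centers(volume_grid(phg$strio, rep(phg$spacing_mm, 3),
                                    phg$origin),
                        which(phg$envelope & !phg$strio))
  expect_lt(mean(sxyz[, 1]), mean(mxyz[, 1]))   # more medial
  expect_gt(mean(sxyz[, 2]), mean(mxyz[, 2]))   # more rostral
  expect_lt(mean(sxyz[, 3]), mean(mxyz[, 3]))   # more ventral
})

test_that("branch diameters respect the configured range on the grid", {
  ph <- do.call(generate_phantom, c(red, list(seed = 93)))
  d <- branch_diameters(ph)
  expect_true(all(d >= ph$diameter_range_mm[1] - 1e-9))
  expect_true(all(d <= ph$diameter_range_mm[2] + 1e-9))
  # grid-measured diameter of an isolated branch within a voxel of
  # nominal: a tiny volume target stops growth after the first branch
  iso <- generate_phantom(envelope_semiaxes_mm = c(8, 16, 8),
                          spacing_mm = 0.5, margin_mm = 3,
                          target_fraction = 0.001, gradient = c(0, 0, 0),
                          seed = 94)
  # restamp only the longest branch so the measurement is truly isolated
  lead <- which.max(vapply(iso$branches, function(b) nrow(b$points),
                           numeric(1)))
  iso$branches <- iso$branches[lead]
  iso$strio <- striocomp:::restamp(iso, iso$branches)$strio
  meas <- measure_branch_diameter(iso, 1)
  nominal <- 2 * iso$branches[[1]]$radius
  interior <- meas[2:(length(meas) - 1)]        # ends taper by construction
  expect_lte(abs(median(interior) - nominal), iso$spacing_mm + 1e-9)
})

test_that("infeasible configurations fail loudly", {
  expect_error(generate_phantom(target_fraction = 0.6), "infeasible")
  expect_error(generate_phantom(envelope_semiaxes_mm = c(1.5, 2, 1.5),
                                spacing_mm = 0.5, margin_mm = 2),
               "infeasible|20 branches")
  expect_error(generate_phantom(margin_mm = 0.2), "margin_mm")
})

test_that("scenario A deletes volume but not architecture", {
  ph <- do.call(generate_phantom, c(red, list(seed = 95)))
  pa <- apply_perturbation(ph, "A", 0.5, seed = 1)
  expect_equal(pa$strio_count / ph$strio_count, 0.5, tolerance = 0.16)
  # surviving branch thickness distribution is the original one (KS)
  ks <- suppressWarnings(
    ks.test(vapply(pa$branches, `[[`, numeric(1), "radius"),
            vapply(ph$branches, `[[`, numeric(1), "radius")))
  expect_gt(ks$p.value, 0.05)
  expect_equal(pa$provenance$scenario, "A")
  expect_error(apply_perturbation(ph, "A", 0.6), "magnitude")
})

test_that("scenario B trades branch count for thickness, conserving volume", {
  ph <- do.call(generate_phantom, c(red, list(seed = 96)))
  pb <- apply_perturbation(ph, "B", 0.3, seed = 1, quiet = TRUE)
  expect_equal(length(pb$branches), round(0.7 * length(ph$branches)))
  expect_equal(pb$strio_count / ph$strio_count, 1, tolerance = 0.02)
  expect_gt(pb$provenance$diameter_inflation, 1)
  # inflation past the configured maximum is reported, never clamped
  expect_equal(pb$provenance$max_diameter_mm, max(branch_diameters(pb)))
  if (pb$provenance$max_diameter_exceeded)
    expect_gt(pb$provenance$max_diameter_mm, ph$diameter_range_mm[2])
  expect_message(apply_perturbation(ph, "B", 0.3, seed = 1),
                 "exceeds the configured maximum")
})

test_that("scenario C leaves the striosome bit-identical and grows matrix", {
  ph <- do.call(generate_phantom, c(red, list(seed = 97)))
  pc <- apply_perturbation(ph, "C", 0.1)
  expect_identical(pc$strio, ph$strio)
  vm0 <- ph$envelope_count - ph$strio_count
  vm1 <- pc$envelope_count - pc$strio_count
  expect_equal(vm1 / vm0, 1.1, tolerance = 0.01)
})

test_that("voxelization computes exact block fractions and conserves volume", {
  ph <- do.call(generate_phantom, c(red, list(seed = 98)))
  fmap <- voxelize(ph)
  # conservation: striosome volume inside the mask within 1 percent
  expect_gte(fmap$strio_in_mask / fmap$strio_total, 0.99)
  # a fully-matrix diffusion voxel has f = 0
  f <- fmap$f$data
  expect_true(any(f[!is.na(f)] == 0))
  expect_true(all(f[!is.na(f)] >= 0 & f[!is.na(f)] <= 1))
  expect_error(voxelize(ph, voxel_size_mm = 0.75), "non-integer")
  # hand-checked 8x8x8 block ratio: 64 striosome of 512 tissue -> 0.125
  strio <- array(FALSE, c(16, 8, 8))
  strio[1:8, 1:8, 1] <- TRUE
  tissue <- array(TRUE, c(16, 8, 8))
  sb <- striocomp:::block_sum(strio, 8)
  tb <- striocomp:::block_sum(tissue, 8)
  expect_equal(sb[1, 1, 1] / tb[1, 1, 1], 64 / 512)
  expect_equal(sb[2, 1, 1], 0)
  expect_equal(tb[2, 1, 1], 512)
})

test_that("the forward model is monotone with the stated ceiling and midpoint", {
  fm <- forward_model()
  fs <- seq(0, 1, by = 0.01)
  p <- forward_probability(fm, fs)
  expect_true(all(diff(p) < 0))                    # strictly decreasing
  expect_gte(forward_probability(fm, 0), 0.95)     # ceiling
  expect_equal(forward_probability(fm, fm$midpoint), 0.5)
  expect_error(forward_model(steepness = -1), "strictly decreasing")
  expect_warning(forward_model(midpoint = 0.1, steepness = 10), "ceiling")
})

test_that("noise-free counts recover the model curve; midpoint voxels are
           indeterminate", {
  ph <- do.call(generate_phantom, c(red, list(seed = 99)))
  fmap <- voxelize(ph)
  fm0 <- forward_model(noise_sd = 0)
  cp <- fractions_to_counts(fmap, fm0)
  pm <- compute_probability(cp$counts_matrix, cp$counts_striosome,
                            fmap$mask)
  f <- fmap$f$data; p <- pm$p_matrix$data
  idx <- which(!is.na(f))
  expect_equal(p[idx], forward_probability(fm0, f[idx]), tolerance = 2e-4)
  # pure-matrix voxels classify matrix-like at the high threshold
  pure <- idx[f[idx] == 0]
  expect_true(all(p[pure] >= 0.95))
  expect_error(fractions_to_counts(fmap, forward_model(budget = 0)),
               "zero streamline budget")
})

test_that("noisy counts are unbiased for the forward probability", {
  set.seed(101)
  d <- c(1, 1, 1)
  fm <- forward_model(noise_sd = 0.15, budget = 5000)
  f0 <- 0.18
  p_true <- forward_probability(fm, f0)
  draws <- replicate(1e4, {
    cmm <- round(fm$budget * p_true * exp(rnorm(1, 0, fm$noise_sd)))
    css <- round(fm$budget * (1 - p_true) * exp(rnorm(1, 0, fm$noise_sd)))
    cmm / (cmm + css)
  })
  expect_equal(mean(draws), p_true, tolerance = 0.01)
})

test_that("cohort bundles satisfy partition conservation on every subject", {
  co <- simulate_cohort(3, "B", 0.2, size = "reduced", seed = 102)
  s <- co$subjects
  # all defined voxels are matrix-like, striosome-like or indeterminate
  expect_equal(s$matrix_vol_55 + s$striosome_vol_55 + s$indeterminate,
               s$striatal_volume_voxels)
  expect_true(all(s$strio_conservation >= 0.99))
  expect_true(all(rowSums(co$mat_hist) == s$matrix_vol_55))
  expect_true(all(rowSums(co$strio_hist) == s$striosome_vol_55))
  expect_error(simulate_cohort(1, "none"), "n_pairs")
})
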