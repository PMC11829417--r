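cfg <- striocomp_config()

test_that("equal-volume masks reach the target when both compartments can", {
  set.seed(51)
  p <- c(runif(200, 0.56, 1.0), runif(90, 0.0, 0.44),
         runif(20, 0.46, 0.54))
  pm <- toy_pmap(sample(p), d = c(310, 1, 1))
  evm <- build_equal_volume_masks(pm, cfg)
  expect_equal(evm$achieved_volume, 83)
  expect_equal(sum(evm$matrix_mask$data), 83)
  expect_equal(sum(evm$striosome_mask$data), 83)
})

test_that("fallback rule truncates both masks to the scarcer compartment", {
  set.seed(52)
  p <- c(runif(200, 0.56, 1.0), runif(60, 0.0, 0.44))
  pm <- toy_pmap(sample(p), d = c(260, 1, 1))
  evm <- build_equal_volume_masks(pm, cfg)
  expect_equal(evm$achieved_volume, 60)
  expect_equal(sum(evm$matrix_mask$data), sum(evm$striosome_mask$data))
  pm0 <- toy_pmap(runif(50, 0.56, 1.0), d = c(50, 1, 1))
  expect_warning(evm0 <- build_equal_volume_masks(pm0, cfg),
                 "zero qualifying")
  expect_equal(evm0$achieved_volume, 0)
})

test_that("selection matches the loop-based oracle, ties and all", {
  set.seed(53)
  for (rep in 1:5) {
    # coarse probabilities force ties; the oracle breaks them by index
    p <- round(runif(120), 2)
    pm <- toy_pmap(p, d = c(120, 1, 1))
    cfg_small <- striocomp_config(equal_volume_target = 15)
    evm <- build_equal_volume_masks(pm, cfg_small)
    orc <- equal_volume_oracle(pm$p_matrix$data, 15)
    expect_equal(evm$achieved_volume, orc$n)
    expect_equal(which(evm$matrix_mask$data), orc$matrix)
    expect_equal(which(evm$striosome_mask$data), orc$striosome)
  }
})

test_that("masks are top-N optimal", {
  set.seed(54)
  p <- runif(300)
  pm <- toy_pmap(p, d = c(300, 1, 1))
  evm <- build_equal_volume_masks(pm, cfg)
  inside <- p[which(evm$matrix_mask$data)]
  rejected <- p[setdiff(which(!is.na(p) & p >= 0.55),
                        which(evm$matrix_mask$data))]
  if (length(rejected)) expect_gte(min(inside), max(rejected))
  expect_equal(evm$selection_trace$last_accepted_p[1], min(inside))
})

test_that("centroid offsets are physical-mm and nucleus-relative", {
  # 3-voxel nucleus at x = 0, 2, 4 mm; centroid at x = 2
  d <- c(3, 1, 1)
  nucleus <- region_mask(volume_grid(array(TRUE, d), c(2, 2, 2)), "caudate")
  m <- array(FALSE, d); m[1] <- TRUE
  mask <- region_mask(volume_grid(m, c(2, 2, 2)), "matrix-like")
  off <- centroid_offsets(mask, list(caudate = nucleus))
  expect_equal(unname(unlist(off[1, c("dx", "dy", "dz")])), c(-2, 0, 0))
  # a voxel at the centroid has zero offset; a symmetric pair means zero
  m2 <- array(FALSE, d); m2[2] <- TRUE
  off2 <- centroid_offsets(region_mask(volume_grid(m2, c(2, 2, 2)), "x"),
                           list(caudate = nucleus))
  expect_equal(unname(unlist(off2[1, c("dx", "dy", "dz")])), c(0, 0, 0))
  m3 <- array(FALSE, d); m3[c(1, 3)] <- TRUE
  off3 <- centroid_offsets(region_mask(volume_grid(m3, c(2, 2, 2)), "x"),
                           list(caudate = nucleus))
  expect_equal(unname(attr(off3, "axis_means")), c(0, 0, 0))
})

test_that("offsets over a whole nucleus sum to zero and strays error", {
  set.seed(55)
  d <- c(5, 4, 3)
  nuc_arr <- array(runif(prod(d)) > 0.4, d)
  nuc <- region_mask(volume_grid(nuc_arr, c(2, 2, 2)), "putamen")
  off <- centroid_offsets(nuc, list(putamen = nuc))
  expect_equal(unname(attr(off, "axis_means")), c(0, 0, 0), tolerance = 1e-12)
  stray <- array(FALSE, d); stray[which(!nuc_arr)[1]] <- TRUE
  expect_error(
    centroid_offsets(region_mask(volume_grid(stray, c(2, 2, 2)), "x"),
                     list(putamen = nuc)),
    "outside all nuclei")
})

test_that("group offset distance is the Euclidean norm of the difference", {
  expect_equal(group_offset_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(group_offset_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(group_offset_distance(c(0.1, 0.1, 0.05), c(0, 0, 0)),
               sqrt(0.0225))
  expect_equal(round(group_offset_distance(c(0.1, 0.1, 0.05), c(0, 0, 0)), 2),
               0.15)
  expect_error(group_offset_distance(c(1, 2), c(1, 2, 3)), "3-vector")
  expect_error(group_offset_distance(c(x = 1, y = 2, z = 3),
                                     c(y = 1, x = 2, z = 3)),
               "axis mismatch")
})

test_that("the 1.5 SD normal-tail helper reproduces the target-volume reasoning", {
  # drop the central +/- 1.5 SD mass, split the rest over two tails
  expect_equal(normal_tail_fraction(1.5),
               (1 - (pnorm(1.5) - pnorm(-1.5))) / 2)
  expect_equal(round(normal_tail_fraction(1.5), 4), 0.0668)
})
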