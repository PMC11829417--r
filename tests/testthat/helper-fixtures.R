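# Small in-code fixtures shared across test files.

# a volume_grid from a vector of values laid out on a d-dim grid
toy_grid <- function(values, d = c(4, 4, 4), voxel = 2, origin = c(0, 0, 0)) {
  volume_grid(array(values, d), rep(voxel, 3), origin)
}

# probability map over an n-voxel striatal strip with given p values
toy_pmap <- function(p_values, d = NULL, split = TRUE) {
  n <- length(p_values)
  if (is.null(d)) d <- c(n, 1, 1)
  p <- array(NA_real_, d)
  p[seq_len(n)] <- p_values
  mask <- array(FALSE, d); mask[seq_len(n)] <- TRUE
  striatum <- region_mask(volume_grid(array(mask, d), c(2, 2, 2)),
                          "striatum")
  cda <- put <- NULL
  if (split && n >= 2) {
    half <- ceiling(n / 2)
    cm <- array(FALSE, d); cm[seq_len(half)] <- TRUE
    pm <- array(FALSE, d); pm[setdiff(seq_len(n), seq_len(half))] <- TRUE
    cda <- region_mask(volume_grid(cm, c(2, 2, 2)), "caudate")
    put <- region_mask(volume_grid(pm, c(2, 2, 2)), "putamen")
  }
  probability_map(p, striatum, cda, put)
}

# independent brute-force step-up oracle: largest k with p_(k) <= qk/m,
# checked by explicit enumeration over every rank
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k_best <- 0L
  for (k in seq_len(m)) if (ps[k] <= q * k / m) k_best <- k
  list(k = k_best,
       threshold = if (k_best > 0) q * k_best / m else NA_real_,
       reject = if (k_best > 0) p <= ps[k_best] else rep(FALSE, m))
}

# set-arithmetic Dice oracle on two logical arrays
dice_oracle <- function(a, b) {
  A <- which(a); B <- which(b)
  if (length(A) + length(B) == 0) return(NA_real_)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# loop-based equal-volume mask selection oracle (independent of the
# package's vectorized implementation), including the fallback-N rule
equal_volume_oracle <- function(p, target, bias = 0.55) {
  idx <- which(!is.na(p))
  qm <- idx[p[idx] >= bias]
  qs <- idx[(1 - p[idx]) >= bias]
  n <- min(length(qm), length(qs), target)
  pick <- function(cand, prob) {
    chosen <- integer(0)
    prob_left <- prob; cand_left <- cand
    while (length(chosen) < n) {
      best <- max(prob_left)
      at <- cand_left[prob_left == best]
      take <- min(at)                      # lexicographic tie-break
      chosen <- c(chosen, take)
      drop <- match(take, cand_left)
      cand_left <- cand_left[-drop]; prob_left <- prob_left[-drop]
    }
    sort(chosen)
  }
  list(n = n,
       matrix = if (n) pick(qm, p[qm]) else integer(0),
       striosome = if (n) pick(qs, 1 - p[qs]) else integer(0))
}
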