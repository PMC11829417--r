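#' Voxelize a phantom to diffusion resolution
#'
#' Downsamples the high-resolution label grid to diffusion voxels (default
#' 2 mm isotropic) by exact block counting: for each diffusion voxel the
#' intra-voxel striosome tissue fraction is
#'
#'   f = (striosome high-res voxels) / (tissue high-res voxels)
#'
#' so every diffusion voxel can mix striosome and matrix (partial-volume
#' averaging). Diffusion voxels dominated by exterior (tissue fraction
#' below `tissue_min`, default 0.5) are masked out of the striatal mask.
#' Striosome volume is conserved through voxelization: the sum of f times
#' in-voxel tissue equals the high-res striosome count exactly; masking
#' removes only exterior-dominated rim voxels (< 1 percent of striosome).
#'
#' @param phantom a `tissue_phantom`.
#' @param voxel_size_mm diffusion voxel size; must be an integer multiple
#'   of the phantom spacing.
#' @param tissue_min minimum in-voxel tissue fraction to enter the
#'   striatal mask.
#' @return An object of class `fraction_map`: `f` (a [volume_grid()], NA
#'   outside the mask), `mask` (striatal [region_mask()]), `tissue`
#'   (tissue-fraction `volume_grid`), counts used, and provenance linking
#'   back to the phantom.
#' @export
voxelize <- function(phantom, voxel_size_mm = 2, tissue_min = 0.5) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  ratio <- voxel_size_mm / phantom$spacing_mm
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("non-integer downsampling ratio: voxel size ", voxel_size_mm,
         " mm is not a multiple of the phantom spacing ",
         phantom$spacing_mm, " mm")
  r <- as.integer(round(ratio))
  if (any(phantom$dims %% r != 0))
    stop("phantom grid dimensions are not divisible by the downsampling ",
         "ratio ", r)
  sblk <- block_sum(phantom$strio, r)
  tblk <- tissue_blocks(phantom, r)
  f <- ifelse(tblk > 0, sblk / pmax(tblk, 1), 0)
  mask <- tblk >= tissue_min * r^3
  f[!mask] <- NA_real_
  vx <- rep(voxel_size_mm, 3)
  org <- phantom$origin + (r - 1) / 2 * phantom$spacing_mm
  fg <- volume_grid(array(f, dim(sblk)), vx, org)
  mk <- region_mask(volume_grid(array(mask, dim(sblk)), vx, org), "striatum")
  structure(
    list(f = fg, mask = mk,
         tissue = volume_grid(array(tblk / r^3, dim(sblk)), vx, org),
         strio_in_mask = sum(sblk[mask]), strio_total = phantom$strio_count,
         provenance = phantom$provenance),
    class = "fraction_map")
}

# per-block tissue counts of a phantom's envelope; cached per envelope
# geometry since subjects share a small set of envelope sizes
.tissue_cache <- new.env(parent = emptyenv())
tissue_blocks <- function(phantom, r) {
  semi <- phantom$envelope_semiaxes_mm * phantom$envelope_scale
  key <- paste(c(phantom$dims, round(phantom$origin, 6),
                 phantom$spacing_mm, round(semi, 6), r), collapse = "_")
  hit <- .tissue_cache[[key]]
  if (!is.null(hit)) return(hit)
  tblk <- block_sum(phantom$envelope, r)
  if (length(ls(.tissue_cache)) > 48)
    rm(list = ls(.tissue_cache)[1], envir = .tissue_cache)
  .tissue_cache[[key]] <- tblk
  tblk
}

# exact block sums of an (r*nx, r*ny, r*nz) array over r^3 blocks
block_sum <- function(x, r) {
  d <- dim(x)
  a <- colSums(array(x, c(r, d[1] / r, d[2], d[3])))
  a <- aperm(a, c(2, 1, 3))
  a <- colSums(array(a, c(r, d[2] / r, d[1] / r, d[3])))
  a <- aperm(a, c(3, 2, 1))
  a <- colSums(array(a, c(r, d[3] / r, d[1] / r, d[2] / r)))
  aperm(a, c(2, 3, 1))
}

#' Forward model from tissue fraction to connection probability
#'
#' A strictly decreasing logistic mapping from intra-voxel striosome
#' fraction f to the probability of matrix-favoring connectivity:
#'
#'   p_matrix(f) = 1 / (1 + exp(steepness * (f - midpoint)))
#'
#' At the midpoint f0 the voxel's connectivity is indeterminate
#' (p = 0.5); a pure-matrix voxel (f = 0) maps to the model ceiling,
#' which must reach the highly-biased range (>= 0.95) for the default
#' calibration. Streamline counts are generated from the probability with
#' multiplicative log-normal noise against a per-voxel streamline budget.
#'
#' @param midpoint striosome fraction at which connectivity is
#'   indeterminate (default 0.25 — see the methods vignette for why the
#'   midpoint sits well below an equal tissue split).
#' @param steepness logistic slope; must be positive (strict monotonicity).
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   count noise.
#' @param budget streamline budget per voxel (samples per seed voxel).
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(midpoint = 0.25, steepness = 12,
                          noise_sd = 0.15, budget = 5000) {
  if (steepness <= 0) stop("steepness must be positive (mapping must be ",
                           "strictly decreasing in f)")
  if (midpoint <= 0 || midpoint >= 1) stop("midpoint must lie in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  ceiling_p <- 1 / (1 + exp(-steepness * midpoint))
  if (ceiling_p < 0.95)
    warning("model ceiling p_matrix(0) = ", round(ceiling_p, 4),
            " is below the highly-biased threshold 0.95")
  structure(list(midpoint = midpoint, steepness = steepness,
                 noise_sd = noise_sd, budget = budget,
                 ceiling = ceiling_p),
            class = "forward_model")
}

#' Evaluate the forward model's probability curve
#'
#' @param fm a [forward_model()].
#' @param f striosome fraction(s) in [0, 1].
#' @return p_matrix value(s).
#' @export
forward_probability <- function(fm, f) {
  1 / (1 + exp(fm$steepness * (f - fm$midpoint)))
}

#' Simulate streamline counts from a fraction map
#'
#' Maps each in-mask diffusion voxel's striosome fraction through the
#' forward model and draws the competing streamline counts:
#' counts toward the matrix-favoring composite are budget x p with
#' multiplicative log-normal noise, and counts toward the
#' striosome-favoring composite are budget x (1 - p) with independent
#' noise. As the budget grows the recovered ratio converges to p.
#'
#' @param fmap a `fraction_map` from [voxelize()].
#' @param fm a [forward_model()].
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return A list (`count_pair`): `counts_matrix`, `counts_striosome`
#'   ([volume_grid()]s, zero outside the mask) and `striatum`.
#' @export
fractions_to_counts <- function(fmap, fm, seed = NULL) {
  stopifnot(inherits(fmap, "fraction_map"), inherits(fm, "forward_model"))
  if (fm$budget <= 0) stop("zero streamline budget")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  f <- fmap$f$data
  idx <- which(!is.na(f))
  p <- forward_probability(fm, f[idx])
  n <- length(idx)
  noise <- function() if (fm$noise_sd > 0)
    exp(stats::rnorm(n, 0, fm$noise_sd)) else rep(1, n)
  cm <- array(0, dim(f)); cs <- array(0, dim(f))
  cm[idx] <- round(fm$budget * p * noise())
  cs[idx] <- round(fm$budget * (1 - p) * noise())
  g <- fmap$f
  list(counts_matrix = volume_grid(cm, g$voxel_size_mm, g$origin, g$axes),
       counts_striosome = volume_grid(cs, g$voxel_size_mm, g$origin,
                                      g$axes),
       striatum = fmap$mask)
}
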