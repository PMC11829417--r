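#' Generate a branched striosome/matrix tissue phantom
#'
#' Builds a high-resolution (default 0.25 mm isotropic) label grid of an
#' ellipsoidal striatal envelope containing a randomly grown, branched,
#' labyrinthine striosome embedded in matrix. Branches are tortuous tubules
#' whose diameters are sampled per branch from the configured range
#' (default 0.5-1.25 mm, the coronal-plane diameter range of the human
#' striosome); new branches sprout either from gradient-weighted random
#' seeds or from points on existing branches, so the skeleton forms a
#' connected-ish branch graph. Striosome density is modulated by a
#' rostral/medial/ventral enrichment gradient. Growth stops when the
#' striosome occupies the target fraction of the envelope (default 0.15).
#'
#' Axes follow the canonical frame: +x medial-to-lateral, +y
#' caudal-to-rostral, +z ventral-to-dorsal; positive gradient weights
#' enrich the medial, rostral and ventral ends respectively.
#'
#' @param envelope_semiaxes_mm ellipsoid semi-axes (x, y, z) in mm.
#' @param spacing_mm isotropic high-resolution voxel size.
#' @param target_fraction striosome volume fraction of the envelope.
#' @param diameter_range_mm tubule diameter range, mm.
#' @param gradient length-3 nonnegative weights (medial, rostral, ventral)
#'   of the log-linear enrichment gradient; `c(0,0,0)` is isotropic.
#' @param branch_length_mm range of branch lengths, mm.
#' @param tortuosity per-step direction noise of the branch random walk.
#' @param root_prob probability a new branch starts from a fresh seed
#'   rather than sprouting from the existing skeleton.
#' @param margin_mm grid margin outside the envelope (reserves room for
#'   matrix-expansion perturbations).
#' @param max_branches growth cap before the configuration is declared
#'   infeasible.
#' @param grid_reference_mm semi-axes used to size the voxel grid
#'   (default: the envelope itself). Passing a fixed reference keeps the
#'   grid identical across subjects whose envelopes differ in size, so
#'   their diffusion-space maps are voxelwise comparable.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return An object of class `tissue_phantom`: the striosome logical
#'   array `strio`, the envelope logical array, grid geometry, the branch
#'   list (skeleton points in mm + radius + parent), achieved counts and
#'   provenance.
#' @export
generate_phantom <- function(envelope_semiaxes_mm = c(10, 20, 10),
                             spacing_mm = 0.25,
                             target_fraction = 0.15,
                             diameter_range_mm = c(0.5, 1.25),
                             gradient = c(medial = 1.5, rostral = 1.5,
                                          ventral = 1.5),
                             branch_length_mm = c(6, 14),
                             tortuosity = 0.25,
                             root_prob = 0.3,
                             margin_mm = 3,
                             max_branches = 4000,
                             grid_reference_mm = NULL,
                             seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  semi <- as.numeric(envelope_semiaxes_mm)
  stopifnot(length(semi) == 3L, all(semi > 0), spacing_mm > 0)
  if (target_fraction <= 0 || target_fraction > 0.45)
    stop("infeasible volume-fraction/diameter combination: ",
         "target_fraction must lie in (0, 0.45]")
  rmax <- diameter_range_mm[2] / 2
  rmin <- diameter_range_mm[1] / 2
  if (rmin <= 0 || rmax < rmin) stop("invalid diameter range")
  if (margin_mm < rmax + spacing_mm)
    stop("margin_mm must exceed the maximum tubule radius")
  # grid: dims rounded up so a 2 mm diffusion grid divides it evenly
  gref <- if (is.null(grid_reference_mm)) semi
          else as.numeric(grid_reference_mm)
  if (any(semi > gref + margin_mm - 2 * spacing_mm))
    stop("envelope exceeds the grid reference plus margin")
  blk <- max(1L, round(2 / spacing_mm))
  dims <- vapply(gref, function(s)
    as.integer(blk * ceiling(2 * (s + margin_mm) / spacing_mm / blk)),
    integer(1))
  origin <- -(dims - 1) / 2 * spacing_mm
  # feasibility: the inner envelope must hold >= 20 minimum-size branches
  # (shrink by the radius plus two voxels so stamped tubules stay interior)
  inner <- semi - rmax - 2 * spacing_mm
  if (any(inner <= 0) ||
      (4 / 3 * pi * prod(inner)) <
        20 * pi * rmin^2 * branch_length_mm[1])
    stop("infeasible volume-fraction/diameter combination: ",
         "envelope too small for >= 20 branches at this diameter")
  env_arr <- ellipsoid_array(dims, origin, spacing_mm, semi)
  env_n <- sum(env_arr)
  target_n <- round(target_fraction * env_n)

  strio <- array(FALSE, dims)
  branches <- list()
  g <- as.numeric(gradient)
  step <- spacing_mm
  count <- 0L
  while (count < target_n) {
    if (length(branches) >= max_branches)
      stop("infeasible volume-fraction/diameter combination: ",
           "growth cap reached at fraction ", round(count / env_n, 3))
    from_root <- (length(branches) == 0L) || (stats::runif(1) < root_prob)
    p0 <- if (from_root) sample_gradient_point(inner, g)
          else {
            pb <- branches[[sample.int(length(branches), 1L)]]$points
            pb[sample.int(nrow(pb), 1L), ]
          }
    r <- stats::runif(1, rmin, rmax)
    len <- stats::runif(1, branch_length_mm[1], branch_length_mm[2])
    pts <- grow_branch(p0, len, step, tortuosity, semi - r - 2 * spacing_mm)
    if (nrow(pts) < 4L) next
    parent <- if (from_root) NA_integer_ else length(branches)
    branches[[length(branches) + 1L]] <-
      list(points = pts, radius = r, parent = parent)
    count <- count + stamp_branch_inplace(strio, pts, r, dims, origin,
                                          spacing_mm)
  }
  frac <- count / env_n
  structure(
    list(strio = strio, envelope = env_arr, dims = dims,
         spacing_mm = spacing_mm, origin = origin,
         envelope_semiaxes_mm = semi, envelope_scale = 1,
         margin_mm = margin_mm, gradient = g,
         branches = branches,
         strio_count = count, envelope_count = env_n,
         achieved_fraction = frac, target_fraction = target_fraction,
         diameter_range_mm = diameter_range_mm,
         provenance = list(scenario = "none", magnitude = 0, seed = seed)),
    class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", paste(x$dims, collapse = "x"), " @ ",
      x$spacing_mm, " mm; ", length(x$branches), " branches; ",
      "striosome fraction ", round(x$achieved_fraction, 3),
      " (target ", x$target_fraction, "); scenario ",
      x$provenance$scenario, "\n", sep = "")
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# logical array of the ellipsoid (x/a)^2+(y/b)^2+(z/c)^2 <= 1; built one
# z-slice at a time against the shared xy-plane sum to avoid a full-size
# double intermediate. Cached per geometry (phantom envelopes recur across
# simulated subjects), with a small LRU-ish cap.
.envelope_cache <- new.env(parent = emptyenv())
ellipsoid_array <- function(dims, origin, spacing, semi) {
  key <- paste(c(dims, round(origin, 6), spacing, round(semi, 6)),
               collapse = "_")
  hit <- .envelope_cache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- ((origin[1] + (seq_len(dims[1]) - 1) * spacing) / semi[1])^2
  ay <- ((origin[2] + (seq_len(dims[2]) - 1) * spacing) / semi[2])^2
  az <- ((origin[3] + (seq_len(dims[3]) - 1) * spacing) / semi[3])^2
  xy <- as.vector(outer(ax, ay, "+"))
  m <- vapply(az, function(z) xy <= 1 - z, logical(length(xy)))
  dim(m) <- dims
  if (length(ls(.envelope_cache)) > 24)
    rm(list = ls(.envelope_cache)[1], envir = .envelope_cache)
  .envelope_cache[[key]] <- m
  m
}

# rejection-sample one point inside the ellipsoid with semiaxes `inner`,
# density proportional to exp(g1*(-x/a) + g2*(y/b) + g3*(-z/c));
# candidates are drawn in batches to keep the rejection loop vectorized
sample_gradient_point <- function(inner, g) {
  u <- c(-g[1], g[2], -g[3])
  wmax <- sqrt(sum(u^2))
  repeat {
    q <- matrix(stats::runif(96, -1, 1), 32, 3)
    ok <- rowSums(q * q) <= 1
    if (wmax > 0)
      ok <- ok & (stats::runif(32) < exp(drop(q %*% u) - wmax))
    i <- which(ok)
    if (length(i)) return(q[i[1], ] * inner)
  }
}

# tortuous random-walk branch from p0, truncated at the inner envelope
grow_branch <- function(p0, length_mm, step, tortuosity, inner) {
  n <- max(2L, round(length_mm / step))
  d0 <- stats::rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
  vx <- d0[1] + cumsum(stats::rnorm(n, sd = tortuosity))
  vy <- d0[2] + cumsum(stats::rnorm(n, sd = tortuosity))
  vz <- d0[3] + cumsum(stats::rnorm(n, sd = tortuosity))
  nrm <- sqrt(vx * vx + vy * vy + vz * vz) / step
  px <- p0[1] + cumsum(vx / nrm)
  py <- p0[2] + cumsum(vy / nrm)
  pz <- p0[3] + cumsum(vz / nrm)
  q <- (px / inner[1])^2 + (py / inner[2])^2 + (pz / inner[3])^2
  out <- which(q > 1)
  keep <- if (length(out)) seq_len(out[1] - 1L) else seq_len(n)
  cbind(c(p0[1], px[keep]), c(p0[2], py[keep]), c(p0[3], pz[keep]))
}

# ball of integer voxel offsets within radius rv (in voxels), as linear
# index offsets for a grid of the given dims; cached per (rv, dims)
.offset_cache <- new.env(parent = emptyenv())
ball_offsets <- function(rv, dims) {
  key <- paste0(round(rv, 3), "_", paste(dims, collapse = "x"))
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- floor(rv)
  rng <- -k:k
  off <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  off <- off[rowSums(off^2) <= rv^2, , drop = FALSE]
  lin <- off[, 1] + dims[1] * off[, 2] + dims[1] * dims[2] * off[, 3]
  .offset_cache[[key]] <- lin
  lin
}

# 1-based linear indices of a branch's skeleton points on the grid
skeleton_indices <- function(pts, dims, origin, spacing) {
  i <- round((pts[, 1] - origin[1]) / spacing)
  j <- round((pts[, 2] - origin[2]) / spacing)
  k <- round((pts[, 3] - origin[3]) / spacing)
  as.integer(i + dims[1] * j + dims[1] * dims[2] * k + 1)
}

# stamp one tubule into the (exclusively owned) label array via the
# compiled kernel; returns the count of newly marked voxels
stamp_branch_inplace <- function(label, pts, radius, dims, origin,
                                 spacing) {
  lin <- skeleton_indices(pts, dims, origin, spacing)
  off <- as.integer(ball_offsets(radius / spacing, dims))
  stamp_mark(label, lin, off)
}

# rebuild the striosome array from a branch list (used by perturbations)
restamp <- function(phantom, branches, radius_scale = 1) {
  strio <- array(FALSE, phantom$dims)
  count <- 0L
  for (b in branches)
    count <- count + stamp_branch_inplace(strio, b$points,
                                          b$radius * radius_scale,
                                          phantom$dims, phantom$origin,
                                          phantom$spacing_mm)
  list(strio = strio, count = count)
}

nominal_branch_volumes <- function(branches, step) {
  vapply(branches, function(b)
    pi * b$radius^2 * (nrow(b$points) * step), numeric(1))
}

#' Nominal tubule diameters of a phantom's branches
#'
#' @param phantom a `tissue_phantom`.
#' @return Numeric vector of stamped branch diameters in mm.
#' @export
branch_diameters <- function(phantom) {
  vapply(phantom$branches, function(b) 2 * b$radius, numeric(1))
}

#' Grid-measured tubule diameter along one branch
#'
#' For each skeleton point of the branch, finds the largest voxel ball
#' fully inside the striosome label and converts it to a diameter. On an
#' isolated branch this recovers the stamped diameter to within one
#' high-resolution voxel; where branches overlap it measures the local
#' (merged) thickness.
#'
#' @param phantom a `tissue_phantom`.
#' @param branch_id index into `phantom$branches`.
#' @return Numeric vector of measured diameters (mm) along the branch.
#' @export
measure_branch_diameter <- function(phantom, branch_id) {
  b <- phantom$branches[[branch_id]]
  dims <- phantom$dims; sp <- phantom$spacing_mm
  ijk <- round(sweep(b$points, 2, phantom$origin, "-") / sp) + 1
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  kmax <- ceiling(phantom$diameter_range_mm[2] / sp)
  vapply(lin, function(l) {
    k_in <- 0
    for (k in seq_len(kmax + 1L)) {
      off <- ball_offsets(k, dims)
      if (all(phantom$strio[l + off])) k_in <- k else break
    }
    (2 * k_in + 1) * sp
  }, numeric(1))
}

#' Apply a tissue-level perturbation scenario
#'
#' The three hypothesized tissue changes behind an expanded matrix-like
#' compartment:
#' \describe{
#'   \item{A (striosome volume loss)}{branches are deleted in random order
#'     until the deleted nominal volume reaches `magnitude` of the total;
#'     surviving branches keep their diameters, so the architecture of the
#'     remainder is intact.}
#'   \item{B (architectural simplification)}{the striosome is rebuilt from
#'     `(1 - magnitude)` of the branch count with diameters inflated to
#'     conserve striosome volume within 2 percent — fewer, thicker
#'     tubules. If inflation pushes diameters past the configured maximum
#'     this is recorded in the provenance (and messaged), never clamped
#'     silently.}
#'   \item{C (matrix expansion)}{the matrix envelope is dilated so matrix
#'     volume grows by `magnitude`; the striosome label array is
#'     bit-identical to the input.}
#' }
#'
#' @param phantom a `tissue_phantom`.
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param magnitude fractional change, in (0, 0.5].
#' @param seed optional RNG seed for the random branch selections.
#' @param quiet suppress the scenario-B diameter message.
#' @return A perturbed `tissue_phantom` with provenance recording the
#'   scenario, magnitude and any diameter overflow.
#' @export
apply_perturbation <- function(phantom, scenario = c("A", "B", "C"),
                               magnitude = 0.2, seed = NULL, quiet = FALSE) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  scenario <- match.arg(scenario)
  if (magnitude <= 0 || magnitude > 0.5)
    stop("magnitude must lie in (0, 0.5]")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  out <- phantom
  step <- phantom$spacing_mm
  if (scenario == "A") {
    vols <- nominal_branch_volumes(phantom$branches, step)
    ord <- sample.int(length(vols))
    ndel <- which(cumsum(vols[ord]) >= magnitude * sum(vols))[1]
    if (is.na(ndel)) ndel <- length(vols)
    keep <- phantom$branches[-ord[seq_len(ndel)]]
    rs <- restamp(phantom, keep)
    out$branches <- keep
    out$strio <- rs$strio
    out$strio_count <- rs$count
    out$provenance <- list(scenario = "A", magnitude = magnitude,
                           seed = seed, branches_deleted = ndel)
  } else if (scenario == "B") {
    nb <- length(phantom$branches)
    nkeep <- max(1L, round((1 - magnitude) * nb))
    keep <- phantom$branches[sort(sample.int(nb, nkeep))]
    v_all <- sum(nominal_branch_volumes(phantom$branches, step))
    v_keep <- sum(nominal_branch_volumes(keep, step))
    lambda <- sqrt(v_all / v_keep)
    target <- phantom$strio_count
    rs <- restamp(phantom, keep, lambda)
    for (it in 1:3) {             # volume conservation within 2 percent
      if (abs(rs$count - target) / target <= 0.02) break
      lambda <- lambda * sqrt(target / rs$count)
      rs <- restamp(phantom, keep, lambda)
    }
    max_d <- 2 * lambda * max(vapply(keep, `[[`, numeric(1), "radius"))
    overflow <- max_d > phantom$diameter_range_mm[2]
    if (overflow && !quiet)
      message("scenario B inflation: max tubule diameter ",
              round(max_d, 3), " mm exceeds the configured maximum ",
              phantom$diameter_range_mm[2], " mm (recorded, not clamped)")
    out$branches <- lapply(keep, function(b) {
      b$radius <- b$radius * lambda; b
    })
    out$strio <- rs$strio
    out$strio_count <- rs$count
    out$provenance <- list(scenario = "B", magnitude = magnitude,
                           seed = seed, branch_count = nkeep,
                           diameter_inflation = lambda,
                           max_diameter_mm = max_d,
                           max_diameter_exceeded = overflow)
  } else {                         # C: dilate matrix, striosome untouched
    vs <- phantom$strio_count
    vm <- phantom$envelope_count - vs
    scale <- ((vs + (1 + magnitude) * vm) / (vs + vm))^(1 / 3)
    semi_new <- phantom$envelope_semiaxes_mm * scale
    if (any(semi_new > -phantom$origin - phantom$spacing_mm))
      stop("matrix dilation exceeds the grid extent; regenerate the ",
           "phantom with a larger margin_mm")
    env_new <- ellipsoid_array(phantom$dims, phantom$origin,
                               phantom$spacing_mm, semi_new)
    out$envelope <- env_new
    out$envelope_count <- sum(env_new)
    out$envelope_scale <- phantom$envelope_scale * scale
    out$provenance <- list(scenario = "C", magnitude = magnitude,
                           seed = seed, envelope_scale = scale)
  }
  out$achieved_fraction <- out$strio_count / out$envelope_count
  out
}
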