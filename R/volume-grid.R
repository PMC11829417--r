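#' Volume grid container
#'
#' A `volume_grid` is the package's in-memory representation of a 3D scalar
#' lattice: a numeric/integer/logical array plus the physical geometry needed
#' for millimetre-space computations (per-axis voxel size and the physical
#' coordinate of the centre of voxel `[1,1,1]`) and anatomical axis tags.
#'
#' The canonical anatomical frame is RAS-like for a right hemistriatum:
#' +x = medial-to-lateral, +y = caudal-to-rostral, +z = ventral-to-dorsal.
#' All geometry (centroids, offsets) is computed in physical mm at voxel
#' centres, never in index units.
#'
#' @param data 3D array.
#' @param voxel_size_mm numeric length-3, strictly positive per-axis sizes.
#' @param origin physical coordinate (mm) of the centre of voxel `[1,1,1]`.
#' @param axes character length-3 anatomical orientation tags.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data,
                        voxel_size_mm = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        axes = c("medial-lateral", "caudal-rostral",
                                 "ventral-dorsal")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 coordinate")
  if (length(axes) != 3L || any(!nzchar(axes)))
    stop("orientation tags must be present before any geometry operation")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         origin = as.numeric(origin), axes = as.character(axes)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size_mm), collapse = " x "),
      " mm\n  axes: ", paste(x$axes, collapse = ", "),
      "\n  origin (mm): ", paste(format(x$origin), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Check two grids share geometry
#'
#' @param a,b `volume_grid` objects.
#' @param tol geometric tolerance in mm.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what,
         " must share dimensions, voxel size and origin")
  invisible(TRUE)
}

#' Physical voxel-centre coordinates
#'
#' @param grid a `volume_grid`.
#' @param idx optional integer vector of linear voxel indices; default all.
#' @return n x 3 matrix of mm coordinates (columns x, y, z).
#' @export
voxel_centers <- function(grid, idx = NULL) {
  d <- dim(grid$data)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ijk <- arrayInd(idx, d)
  sweep(sweep(ijk - 1, 2, grid$voxel_size_mm, "*"), 2, grid$origin, "+")
}

#' Region mask
#'
#' A binary `volume_grid` tagged with an anatomical region name. Values must
#' be 0/1 (or logical). Caudate and putamen masks must partition the striatum
#' for any subject; [check_nucleus_partition()] asserts this.
#'
#' @param grid a `volume_grid` with values in \{0, 1\} (or logical).
#' @param region_name label such as "striatum", "caudate", "putamen".
#' @return An object of class `region_mask` (inherits `volume_grid`).
#' @export
region_mask <- function(grid, region_name) {
  if (!inherits(grid, "volume_grid")) stop("grid must be a volume_grid")
  v <- grid$data
  if (!is.logical(v)) {
    u <- unique(as.vector(v[!is.na(v)]))
    if (!all(u %in% c(0, 1)))
      stop("region mask values must be in {0, 1}")
    grid$data <- array(v != 0, dim(v))
  }
  grid$region_name <- as.character(region_name)[1]
  class(grid) <- c("region_mask", "volume_grid")
  grid
}

#' Assert caudate and putamen partition the striatum
#'
#' @param striatum,caudate,putamen `region_mask` objects on one grid.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_nucleus_partition <- function(striatum, caudate, putamen) {
  stop_if_grid_mismatch(striatum, caudate, "nucleus masks")
  stop_if_grid_mismatch(striatum, putamen, "nucleus masks")
  s <- striatum$data; cda <- caudate$data; p <- putamen$data
  if (any(cda & p))
    stop("nucleus masks not partitioning striatum: caudate and putamen overlap")
  if (!identical(as.vector(cda | p), as.vector(s)))
    stop("nucleus masks not partitioning striatum: union differs from striatum")
  invisible(TRUE)
}
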