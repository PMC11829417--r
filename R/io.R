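#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into a [volume_grid()].
#' Real-world input is reoriented to the canonical RAS-like frame
#' (+x medial-to-lateral for a right hemistriatum, +y caudal-to-rostral,
#' +z ventral-to-dorsal) so that anatomical direction statements are
#' assertable by coordinate sign. A missing or ambiguous orientation in the
#' header is an explicit failure, never a silent default.
#'
#' @param path file path to a `.nii` or `.nii.gz` image.
#' @param reorient reorient to the canonical "RAS" frame (default `TRUE`).
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, reorient = TRUE) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), " dimensions in ", path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(orient) || !nzchar(orient))
    stop("missing/ambiguous orientation in NIfTI header of ", path)
  if (reorient && orient != "RAS") RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  volume_grid(array(as.vector(img), dim(img)),
              voxel_size_mm = RNifti::pixdim(img)[1:3],
              origin = xf[1:3, 4])
}

#' Write a volume grid as NIfTI
#'
#' The header encodes voxel size and origin (qform, code 2) so that a
#' write-then-read round trip reproduces data, voxel size and origin exactly.
#' Floating-point data are stored as doubles (probability maps are not
#' quantized); integer-valued data (e.g. label or mask volumes) are stored
#' with an integer datatype.
#'
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (!inherits(grid, "volume_grid")) stop("grid must be a volume_grid")
  v <- grid$data
  storage <- if (is.logical(v) ||
                 (is.numeric(v) && !anyNA(v) &&
                  all(v == round(v)) && max(abs(v)) <= .Machine$integer.max))
    "int32" else "double"
  if (is.logical(v)) v <- array(as.integer(v), dim(v))
  img <- RNifti::asNifti(v)
  attr(img, "pixdim") <- grid$voxel_size_mm
  m <- diag(4)
  m[1, 1] <- grid$voxel_size_mm[1]
  m[2, 2] <- grid$voxel_size_mm[2]
  m[3, 3] <- grid$voxel_size_mm[3]
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = storage); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("unwritable path: ", path)
  invisible(path)
}

#' Read / write delimited tables
#'
#' Thin wrappers fixing the conventions used throughout the pipeline
#' (comma-separated, header row, no factor coercion, no row names).
#'
#' @param path file path.
#' @return `read_table_csv` returns a `data.frame`.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_table_csv
#' @param df a `data.frame` to write.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Log a pipeline stage
#'
#' Appends a timestamp-free, reproducible record of a stage run (resolved
#' config, input checksums, output summary) to a run log file. Content-based
#' checksums keep the log deterministic across machines.
#'
#' @param log_path path of the run log (created if absent); `NULL` to skip.
#' @param stage stage name.
#' @param config an [striocomp_config()] (or any list) resolved for the run.
#' @param inputs named character vector of input file paths to checksum.
#' @param summary named list of scalar output summaries.
#' @return `log_path` invisibly.
#' @export
log_stage <- function(log_path, stage, config = NULL, inputs = character(),
                      summary = list()) {
  if (is.null(log_path)) return(invisible(NULL))
  sums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else "missing",
    character(1))
  rec <- list(stage = stage, config = config,
              input_md5 = as.list(sums), summary = summary)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
      "\n", file = log_path, append = TRUE)
  invisible(log_path)
}
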