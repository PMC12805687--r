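# Volume and table I/O. Conventions used throughout the package:
#   * grids are 3D arrays indexed [x, y, z]; the third dimension is the
#     sectioning axis (one TIFF page per z slice)
#   * voxels are isotropic; the center of voxel [i, j, k] sits at physical
#     coordinate ((i, j, k) - 1) * voxel_size, in micrometres
#   * label 0 is background

#' Labeled 3D volume
#'
#' Container for an integer instance-label grid with physical voxel size.
#' Label 0 is background; label n marks the voxels of instance n. The third
#' array dimension is the sectioning (z) axis.
#'
#' @param grid 3D array of non-negative integers.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @return An object of class `labeled_volume`: a list with elements `grid`
#'   (integer array) and `voxel_size`.
#' @export
labeled_volume <- function(grid, voxel_size) {
  check_dim3(grid, "grid")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stopf("'voxel_size' must be a single positive number (micrometres)")
  if (is.double(grid)) {
    if (any(grid != round(grid)))
      stopf("label grid contains non-integer values (dtype double)")
    storage.mode(grid) <- "integer"
  }
  if (min(grid) < 0L) stopf("labels must be non-negative")
  structure(list(grid = grid, voxel_size = voxel_size),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$grid)
  labs <- unique(x$grid[x$grid > 0L])
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %g um, %d labels\n",
              d[1], d[2], d[3], x$voxel_size, length(labs)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else stopf("cannot guess volume format from '%s'; pass 'format'", path)
}

#' Read a labeled volume from a TIFF stack or NIfTI file
#'
#' TIFF stacks carry no unit metadata, so the voxel size is taken from a
#' sidecar JSON file (`<path>.json` with field `voxel_size_um`) written by
#' [write_volume()], or from the `voxel_size` argument; if neither is
#' available the read fails. Float-typed label data is rejected.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"tiff"` or `"nifti"`.
#' @param voxel_size explicit voxel size in micrometres; overrides metadata.
#' @return A [labeled_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nifti"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    grid <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
    if (is.double(grid) && any(grid != round(grid)))
      stopf("'%s' holds float-typed pixels (dtype double); label volumes must be integer-typed", path)
    if (is.null(voxel_size)) {
      sc <- sidecar_path(path)
      if (file.exists(sc)) {
        meta <- jsonlite::read_json(sc)
        voxel_size <- meta$voxel_size_um
      }
    }
    if (is.null(voxel_size))
      stopf("no voxel size for '%s': provide a sidecar %s or the voxel_size argument", path, sidecar_path(path))
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    grid <- array(as.vector(img), dim = dim(img))
    if (is.double(grid) && any(grid != round(grid)))
      stopf("'%s' holds float-typed voxels (dtype double); label volumes must be integer-typed", path)
    if (is.null(voxel_size)) {
      if (length(pd) >= 3 && all(pd[1:3] > 0)) {
        if (max(pd[1:3]) - min(pd[1:3]) > 1e-6)
          stopf("anisotropic voxels in '%s' (pixdim %s); only isotropic volumes are supported", path, paste(signif(pd[1:3], 4), collapse = " x "))
        voxel_size <- pd[1]
      }
    }
    if (is.null(voxel_size))
      stopf("no voxel size for '%s': pixdim missing, provide the voxel_size argument", path)
  }
  labeled_volume(grid, voxel_size)
}

#' Write a labeled volume
#'
#' TIFF output is a 16-bit multi-page stack (one page per z slice) plus a
#' `<path>.json` sidecar recording the voxel size; labels above 65535 are
#' rejected. NIfTI output stores the voxel size in the header `pixdim`, in
#' micrometres.
#'
#' @param vol a [labeled_volume()].
#' @param path output path.
#' @param format `"auto"`, `"tiff"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nifti")) {
  stopifnot(inherits(vol, "labeled_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "tiff") {
    if (max(vol$grid) > 65535L)
      stopf("labels exceed 65535; 16-bit TIFF cannot represent them")
    nz <- dim(vol$grid)[3]
    pages <- lapply(seq_len(nz), function(k) vol$grid[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
    jsonlite::write_json(list(voxel_size_um = vol$voxel_size),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    a <- vol$grid
    attr(a, "pixdim") <- rep(vol$voxel_size, 3)
    RNifti::writeNifti(a, path, datatype = "int32")
  }
  invisible(path)
}

oocyte_required_cols <- c("id", "x_um", "y_um", "z_um", "diameter_um")

#' Validate a per-oocyte table
#'
#' Checks the schema used throughout the pipeline: mandatory columns `id`,
#' `x_um`, `y_um`, `z_um`, `diameter_um`; optional `volume_um3`, `depth_um`,
#' `neighbor_count`, `parent_id`. Unknown columns are preserved untouched.
#'
#' @param tab a data.frame.
#' @return `tab`, validated.
#' @export
as_oocyte_table <- function(tab) {
  if (!is.data.frame(tab)) stopf("oocyte table must be a data.frame")
  missing_cols <- setdiff(oocyte_required_cols, names(tab))
  if (length(missing_cols))
    stopf("oocyte table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$id)) stopf("oocyte ids must be unique")
  if (nrow(tab) > 0) {
    if (any(!is.finite(tab$diameter_um)) || any(tab$diameter_um <= 0))
      stopf("diameters must be positive and finite")
    if ("depth_um" %in% names(tab) &&
        any(tab$depth_um < 0, na.rm = TRUE))
      stopf("depths must be non-negative")
  }
  tab
}

#' Read / write per-oocyte tables (CSV with mandatory header)
#'
#' @param path CSV file path.
#' @return `read_oocyte_table()` returns a validated data.frame;
#'   `write_oocyte_table()` returns `path` invisibly.
#' @export
read_oocyte_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as_oocyte_table(read.csv(path, check.names = FALSE))
}

#' @param tab a data.frame passing [as_oocyte_table()].
#' @rdname read_oocyte_table
#' @export
write_oocyte_table <- function(tab, path) {
  tab <- as_oocyte_table(tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
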