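#' Image volume container
#'
#' A `qvol` is a minimal 3-D image container: a numeric array plus voxel
#' dimensions (mm) and a 4x4 voxel-to-world affine. All map computation in
#' this package is voxelwise; the container only carries the geometry needed
#' to read, write and grid-check NIfTI volumes.
#'
#' @param data numeric 3-D array.
#' @param voxdim length-3 numeric, voxel size in mm (strictly positive).
#' @param affine 4x4 voxel-to-world transform; defaults to a scaling by
#'   `voxdim` with the origin at the first voxel.
#' @return An object of class `qvol` with elements `data`, `voxdim`,
#'   `affine` and `n_nonfinite` (count of non-finite voxels zeroed on
#'   construction).
#' @export
qvol <- function(data, voxdim = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("qvol: 'data' must be a 3-D array")
  if (any(dim(data) < 1L)) stop("qvol: all dimensions must be >= 1")
  voxdim <- as.numeric(voxdim)
  if (length(voxdim) != 3L || any(!is.finite(voxdim)) || any(voxdim <= 0))
    stop("qvol: 'voxdim' must be three strictly positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(voxdim, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("qvol: 'affine' must be a 4x4 matrix")
  bad <- !is.finite(data)
  n_bad <- sum(bad)
  if (n_bad > 0L) data[bad] <- 0
  structure(list(data = data, voxdim = voxdim, affine = affine,
                 n_nonfinite = n_bad),
            class = "qvol")
}

#' @export
print.qvol <- function(x, ...) {
  cat("qvol:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(signif(x$voxdim, 4), collapse = " x "), "mm\n")
  cat("  range:", paste(signif(range(x$data), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.qvol <- function(x) dim(x$data)

is_qvol <- function(x) inherits(x, "qvol")

# coerce array-or-qvol to array; used by voxelwise map operations so that
# they accept either representation
as_vol_array <- function(x) {
  if (is_qvol(x)) x$data else as.array(x)
}

# carry geometry from a template qvol onto a plain array result
vol_like <- function(data, template) {
  if (is_qvol(template))
    qvol(data, voxdim = template$voxdim, affine = template$affine)
  else
    qvol(data)
}

#' Read a NIfTI volume and its JSON sidecar
#'
#' Loads one NIfTI image as a [qvol]. A JSON sidecar with the same basename
#' (`.json` in place of `.nii`/`.nii.gz`) is read when present and converted
#' to [acq_metadata] (BIDS unit conventions: seconds in the sidecar, ms
#' internally). Non-finite voxels are zeroed and counted in `n_nonfinite`.
#'
#' @param path path to a NIfTI file.
#' @param need_metadata if `TRUE`, a missing or incomplete sidecar is an
#'   error; otherwise the metadata element is `NULL` when unavailable.
#' @return list with elements `volume` ([qvol]) and `meta` ([acq_metadata]
#'   or `NULL`).
#' @export
read_volume <- function(path, need_metadata = FALSE) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  vd <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- as.numeric(img)
  dim(arr) <- dim(img)
  vol <- qvol(arr, voxdim = vd, affine = aff)
  sc <- sidecar_path(path)
  meta <- NULL
  if (file.exists(sc)) {
    meta <- metadata_from_sidecar(jsonlite::read_json(sc),
                                  strict = need_metadata)
  } else if (need_metadata) {
    stop("read_volume: sidecar required but not found: ", sc)
  }
  list(volume = vol, meta = meta)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a volume as NIfTI
#'
#' @param vol a [qvol].
#' @param path output path (`.nii`).
#' @param datatype on-disk datatype; `"float"` (32-bit, the conventional map
#'   storage type) or `"double"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(is_qvol(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxdim
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that inputs share one voxel grid
#'
#' All fitting in this package is voxelwise and assumes pre-aligned inputs;
#' no resampling is performed. This gate runs before any fit.
#'
#' @param ... [qvol] objects and/or [mpm_series] objects (each series
#'   contributes all its echo volumes).
#' @param tol absolute tolerance on affine entries.
#' @return list with `dim` and `affine` of the common grid.
#' @export
assert_common_grid <- function(..., tol = 1e-4) {
  vols <- list()
  for (x in list(...)) {
    if (is.null(x)) next
    if (is_mpm_series(x)) {
      vols <- c(vols, x$volumes)
    } else if (is_qvol(x)) {
      vols <- c(vols, list(x))
    } else if (is.list(x)) {
      for (y in x) {
        if (is_mpm_series(y)) vols <- c(vols, y$volumes)
        else if (is_qvol(y)) vols <- c(vols, list(y))
        else if (!is.null(y)) stop("assert_common_grid: unsupported input")
      }
    } else stop("assert_common_grid: unsupported input")
  }
  if (length(vols) == 0L) stop("assert_common_grid: no inputs")
  ref <- vols[[1L]]
  bad <- character(0)
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    if (!identical(dim(v$data), dim(ref$data)) ||
        max(abs(v$affine - ref$affine)) > tol)
      bad <- c(bad, sprintf("input %d", i))
  }
  if (length(bad) > 0L)
    stop("assert_common_grid: grid mismatch for ", paste(bad, collapse = ", "))
  list(dim = dim(ref$data), affine = ref$affine, voxdim = ref$voxdim)
}
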