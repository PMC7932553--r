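#' Construct an RCM image stack
#'
#' Bundles a 3D intensity volume with its [acquisition_geometry()] and
#' free-form subject/session metadata.  Voxels are stored as a numeric
#' array indexed \code{[row, column, slice]} (column-major, the natural R
#' layout); the third axis runs in acquisition order, shallowest slice
#' first.  Intensities are unitless reflectance counts in [0, 1]; no
#' absolute calibration is attempted.
#'
#' @param voxels numeric 3D array \code{[H, W, n_slices]}, nonnegative.
#' @param geometry an [acquisition_geometry()]; \code{dim(voxels)[3]} must
#'   equal \code{geometry$n_slices}.
#' @param meta named list of subject/session metadata (e.g.
#'   \code{subject_id}, \code{group}, \code{session}).
#' @return an object of class \code{"image_stack"}.
#' @export
image_stack <- function(voxels, geometry, meta = list()) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            is.numeric(voxels), length(dim(voxels)) == 3L)
  d <- dim(voxels)
  if (d[3] != geometry$n_slices)
    stop("third voxel axis (", d[3], ") must equal n_slices (",
         geometry$n_slices, ")")
  if (any(voxels < 0)) stop("voxel intensities must be nonnegative")
  # a stack claiming standard geometry must laterally cover the field
  # to within one pixel
  for (k in 1:2) {
    cover <- d[k] * geometry$pixel_size_um
    if (abs(cover - geometry$field_um) > geometry$pixel_size_um + 1e-9)
      stop(sprintf(
        "axis %d covers %.6g um but geometry declares a %.6g um field",
        k, cover, geometry$field_um))
  }
  structure(list(voxels = voxels, geometry = geometry, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("RCM image stack: %d x %d px x %d slices", d[1], d[2], d[3]))
  if (!is.null(x$meta$subject_id))
    cat(sprintf("  [subject %s%s]", x$meta$subject_id,
                if (!is.null(x$meta$group)) paste0(", ", x$meta$group) else ""))
  cat("\n")
  print(x$geometry)
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read an RCM Z-stack from a multi-page TIFF plus JSON sidecar
#'
#' Pages are read in file order, which is taken to be acquisition order
#' (first page = shallowest slice).  The sidecar supplies
#' \code{pixel_size_um} and \code{step_um} (plus optional
#' \code{subject_id}, \code{group}, \code{session}); when it is absent the
#' documented defaults of 0.5 um/px and a 2.8 um step are assumed with a
#' warning, since neither is recoverable from the TIFF alone.
#'
#' @param path path to a multi-page grayscale TIFF (8- or 16-bit).
#' @param meta_path optional explicit sidecar path; defaults to
#'   \code{path} with a \code{.json} extension.
#' @return an [image_stack()].  Intensities are returned on the [0, 1]
#'   scale native to the TIFF bit depth and are preserved bit-exactly.
#' @export
read_stack <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1L))))
    stop("RGB/multi-channel pages are not supported; ",
         "convert the stack to single-channel grayscale first")
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1L))
  if (length(unique(shapes)) != 1L)
    stop("pages have inconsistent shapes: ",
         paste(unique(shapes), collapse = ", "))

  if (is.null(meta_path)) meta_path <- sidecar_path(path)
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel <- side$pixel_size_um
    step <- side$step_um
    if (is.null(pixel) || is.null(step))
      stop("sidecar ", meta_path,
           " must contain pixel_size_um and step_um")
    meta <- side[setdiff(names(side), c("pixel_size_um", "step_um"))]
  } else {
    warning("no metadata sidecar found for ", path,
            "; assuming defaults 0.5 um/px and 2.8 um step")
    pixel <- 0.5
    step <- 2.8
    meta <- list()
  }

  d <- dim(pages[[1L]])
  voxels <- array(unlist(pages, use.names = FALSE),
                  dim = c(d[1], d[2], length(pages)))
  geom <- acquisition_geometry(pixel_size_um = pixel, step_um = step,
                               n_slices = length(pages),
                               field_um = d[2] * pixel)
  image_stack(voxels, geom, meta)
}

#' Write an RCM Z-stack as a multi-page TIFF plus JSON sidecar
#'
#' The inverse of [read_stack()]: page order is slice order and the
#' sidecar records the acquisition geometry and subject metadata.
#' Intensities are written as 16-bit grayscale; values that already lie on
#' the 16-bit grid (as all simulator output does) round-trip bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param path destination TIFF path; the sidecar is written next to it
#'   with a \code{.json} extension.
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write stack to ", path, ": ", attr(ok, "condition")$message)
  side <- c(list(pixel_size_um = stack$geometry$pixel_size_um,
                 step_um = stack$geometry$step_um),
            stack$meta)
  mp <- sidecar_path(path)
  jsonlite::write_json(side, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
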