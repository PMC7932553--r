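#' Papillary-dermis slice band
#'
#' The papillary dermis — the region of maximal crystal accumulation — is
#' quantified over a fixed band of slices; under the standard acquisition
#' (2.8 um step) the default band of slices 15–50 spans depths 42–140 um.
#' Slices above the band suffer epidermal background, slices below it low
#' clarity; both are profiled in 2D but never enter the 3D statistic.
#'
#' @param first_slice,last_slice 1-based inclusive slice bounds; defaults
#'   15 and 50.
#' @return an object of class \code{"band_spec"}.
#' @export
band_spec <- function(first_slice = 15L, last_slice = 50L) {
  stopifnot(first_slice >= 1, last_slice >= first_slice)
  structure(list(first_slice = as.integer(first_slice),
                 last_slice = as.integer(last_slice)),
            class = "band_spec")
}

band_slices <- function(band, geometry) {
  if (band$last_slice > geometry$n_slices)
    stop("band extends beyond the stack (", geometry$n_slices, " slices)")
  seq.int(band$first_slice, band$last_slice)
}

# Run the full per-slice segmentation chain (candidates -> structure ->
# exclusion) over every slice; the single source of both the 2D profile
# and the 3D reconstruction, so area and volume are computed from the
# same masks by construction.
segment_stack <- function(stack, params = segmentation_params(),
                          slices = seq_len(stack$geometry$n_slices)) {
  lapply(slices, function(k) {
    sl <- stack$voxels[, , k]
    cand <- detect_crystal_candidates(sl, stack$geometry, params, k)
    struct <- detect_skin_structure(sl, stack$geometry, params, k)
    iso <- exclude_structure(cand, struct, params)
    list(slice_index = k, isolated = iso, structure = struct)
  })
}

profile_from_segments <- function(segs, geometry) {
  do.call(rbind, lapply(segs, function(s) {
    d <- dim(s$isolated$labels)
    field_area <- prod(d) * pixel_area_um2(geometry)
    structure_area <- sum(s$structure$regions$area_um2)
    crystal_area <- sum(s$isolated$regions$area_um2)
    analyzed <- field_area - structure_area
    data.frame(slice_index = s$slice_index,
               depth_um = depth_of_slice(s$slice_index, geometry),
               crystal_area_um2 = crystal_area,
               analyzed_area_um2 = analyzed,
               normalized_area = if (analyzed > 0) crystal_area / analyzed
                                 else 0)
  }))
}

#' Depth-resolved normalized crystal-area profile
#'
#' Runs the detection–structure–exclusion chain on every slice and
#' reports, per slice, the summed isolated-crystal area, the analyzed
#' area (field minus structure), and their ratio — the normalized crystal
#' area plotted against tissue depth.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()].
#' @return data frame with one row per slice and columns
#'   \code{slice_index}, \code{depth_um}, \code{crystal_area_um2},
#'   \code{analyzed_area_um2}, \code{normalized_area}.
#' @export
area_profile <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  segs <- segment_stack(stack, params)
  prof <- profile_from_segments(segs, stack$geometry)
  rownames(prof) <- NULL
  prof
}

labels3d_from_segments <- function(segs, stack, band) {
  ks <- band_slices(band, stack$geometry)
  d <- dim(stack$voxels)
  mask <- array(FALSE, c(d[1], d[2], length(ks)))
  for (i in seq_along(ks))
    mask[, , i] <- segs[[i]]$isolated$labels > 0L
  lab <- label_components(mask)
  attr(lab, "band") <- band
  attr(lab, "slice_indices") <- ks
  lab
}

#' 3D reconstruction of isolated crystals within the band
#'
#' Stacks the per-slice isolated-crystal masks for the band slices and
#' labels 3D connected components with 26-connectivity.  The axial step
#' (2.8 um) exceeds the pixel size, so conservative diagonal linking
#' avoids fragmenting single crystals across slices; anisotropy enters the
#' volume computation, not the connectivity.
#'
#' @param stack an [image_stack()].
#' @param band a [band_spec()] lying within the stack.
#' @param params a [segmentation_params()].
#' @return integer 3D label array (band slices only) with attributes
#'   \code{band} and \code{slice_indices}.
#' @export
reconstruct_3d <- function(stack, band = band_spec(),
                           params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  ks <- band_slices(band, stack$geometry)
  segs <- segment_stack(stack, params, slices = ks)
  labels3d_from_segments(segs, stack, band)
}

#' Normalized confocal crystal volume (nCCV) of a Z-stack
#'
#' The pipeline's summary statistic: every slice is segmented
#' (bright-object detection, papilla detection, overlap exclusion), the
#' isolated-crystal masks of the papillary-dermis band are reconstructed
#' in 3D, and the summed crystal volume is normalized against the total
#' region of analysis — the band volume excluding skin structure.
#'
#' Writing \eqn{V_c} for the summed crystal volume, \eqn{V_a} for the
#' analyzed volume (band gross volume minus structure volume) and
#' \eqn{V_{ref}} for the nominal reference volume of the standard
#' acquisition (\code{field_um^2 x band slice count x step_um} of
#' \code{geometry_ref}),
#' \deqn{nCCV = V_c \cdot V_{ref} / V_a \quad [\mu m^3].}
#' On a standard-geometry stack with no detected structure the factor is
#' 1 and nCCV equals the raw crystal volume; stacks whose analyzed volume
#' is reduced by structure (or by a cropped field) are scaled up to the
#' common reference, keeping values comparable across stacks.
#'
#' @param stack an [image_stack()].
#' @param band a [band_spec()]; default slices 15–50.
#' @param params a [segmentation_params()].
#' @param geometry_ref [acquisition_geometry()] defining the nominal
#'   reference volume; defaults to the stack's own geometry.
#' @param keep_labels keep the 3D label array in the result (can be
#'   large); default \code{FALSE}.
#' @return an object of class \code{"nccv"}: a list with the band, the
#'   per-component table (\code{component_id}, \code{voxel_count},
#'   \code{volume_um3}), \code{crystal_volume_um3},
#'   \code{structure_volume_um3}, \code{analyzed_volume_um3},
#'   \code{reference_volume_um3}, \code{nccv_um3}, and the full-depth
#'   \code{profile} data frame.
#' @seealso [area_profile()], [reconstruct_3d()]
#' @export
compute_nccv <- function(stack, band = band_spec(),
                         params = segmentation_params(),
                         geometry_ref = stack$geometry,
                         keep_labels = FALSE) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(geometry_ref, "acquisition_geometry"))
  ks <- band_slices(band, stack$geometry)
  segs <- segment_stack(stack, params)
  prof <- profile_from_segments(segs, stack$geometry)
  lab <- labels3d_from_segments(segs[ks], stack, band)

  vox_vol <- voxel_volume_um3(stack$geometry)
  ncomp <- max(lab)
  counts <- if (ncomp > 0) tabulate(lab[lab > 0L], nbins = ncomp)
            else integer(0)
  components <- data.frame(component_id = seq_len(ncomp),
                           voxel_count = counts,
                           volume_um3 = counts * vox_vol)
  crystal_volume <- sum(components$volume_um3)

  d <- dim(stack$voxels)
  gross <- prod(d[1:2]) * pixel_area_um2(stack$geometry) *
    length(ks) * stack$geometry$step_um
  structure_volume <- sum(vapply(
    segs[ks], function(s) sum(s$structure$regions$area_um2),
    numeric(1L))) * stack$geometry$step_um
  analyzed <- gross - structure_volume
  if (analyzed <= 0)
    stop("analyzed volume is zero: structure covers the whole band; ",
         "nCCV is undefined for this stack")
  v_ref <- geometry_ref$field_um^2 * length(ks) * geometry_ref$step_um

  out <- list(band = band,
              components = components,
              crystal_volume_um3 = crystal_volume,
              structure_volume_um3 = structure_volume,
              analyzed_volume_um3 = analyzed,
              reference_volume_um3 = v_ref,
              nccv_um3 = crystal_volume * v_ref / analyzed,
              profile = prof,
              params = params,
              geometry = stack$geometry,
              meta = stack$meta)
  if (keep_labels) out$labels3d <- lab
  structure(out, class = "nccv")
}

#' @export
print.nccv <- function(x, ...) {
  cat(sprintf("nCCV = %.1f um^3  (%d crystal component(s), band slices %d-%d)\n",
              x$nccv_um3, nrow(x$components),
              x$band$first_slice, x$band$last_slice))
  invisible(x)
}

#' @export
summary.nccv <- function(object, ...) {
  ks <- band_slices(object$band, object$geometry)
  band_prof <- object$profile[object$profile$slice_index %in% ks, ]
  structure(list(
    nccv_um3 = object$nccv_um3,
    n_components = nrow(object$components),
    crystal_volume_um3 = object$crystal_volume_um3,
    structure_volume_um3 = object$structure_volume_um3,
    analyzed_volume_um3 = object$analyzed_volume_um3,
    reference_volume_um3 = object$reference_volume_um3,
    band = object$band,
    depth_range_um = range(band_prof$depth_um),
    peak_slice = object$profile$slice_index[
      which.max(object$profile$normalized_area)],
    mean_normalized_area_band = mean(band_prof$normalized_area),
    meta = object$meta), class = "summary.nccv")
}

#' @export
print.summary.nccv <- function(x, ...) {
  cat("Normalized confocal crystal volume\n")
  if (!is.null(x$meta$subject_id))
    cat(sprintf("  subject:            %s (%s)\n", x$meta$subject_id,
                if (is.null(x$meta$group)) "?" else x$meta$group))
  cat(sprintf("  band:               slices %d-%d (%.0f-%.0f um)\n",
              x$band$first_slice, x$band$last_slice,
              x$depth_range_um[1], x$depth_range_um[2]))
  cat(sprintf("  crystal components: %d\n", x$n_components))
  cat(sprintf("  crystal volume:     %.1f um^3\n", x$crystal_volume_um3))
  cat(sprintf("  structure volume:   %.1f um^3\n", x$structure_volume_um3))
  cat(sprintf("  analyzed volume:    %.4g um^3\n", x$analyzed_volume_um3))
  cat(sprintf("  peak profile slice: %d\n", x$peak_slice))
  cat(sprintf("  nCCV:               %.1f um^3\n", x$nccv_um3))
  invisible(x)
}

#' @export
as.data.frame.nccv <- function(x, ...) x$profile

#' Plot the depth-resolved normalized crystal-area profile
#'
#' Normalized crystal area versus tissue depth, with the papillary-dermis
#' band shaded — the per-stack analogue of the cohort depth profiles.
#'
#' @param x an object returned by [compute_nccv()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.nccv <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$depth_um, p$normalized_area, type = "n",
                 xlab = "depth (um)", ylab = "normalized crystal area", ...)
  b <- c(depth_of_slice(x$band$first_slice, x$geometry),
         depth_of_slice(x$band$last_slice, x$geometry))
  graphics::rect(b[1], graphics::par("usr")[3], b[2],
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("steelblue", 0.15),
                 border = NA)
  graphics::lines(p$depth_um, p$normalized_area, type = "o", pch = 16,
                  cex = 0.5)
  graphics::mtext(sprintf("nCCV = %.1f um^3", x$nccv_um3), side = 3,
                  line = 0.2, cex = 0.9)
  invisible(x)
}

#' Export a label image or volume as 16-bit TIFF
#'
#' Writes integer region labels (a 2D matrix from per-slice segmentation
#' or a 3D array from [reconstruct_3d()]) as one or more 16-bit
#' grayscale TIFF pages, with label k stored as gray level k — readable
#' back as \code{round(readTIFF(...) * 65535)}.
#'
#' @param labels integer matrix or 3D array of labels (0 = background),
#'   all below 65536.
#' @param path destination TIFF path.
#' @return invisibly, \code{path}.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(is.numeric(labels) || is.integer(labels),
            all(labels >= 0), max(labels) < 65536)
  d <- dim(labels)
  pages <- if (length(d) == 3L)
    lapply(seq_len(d[3]), function(k) labels[, , k] / 65535)
  else list(labels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Serialize an nCCV result to JSON
#'
#' @param x an \code{"nccv"} object.
#' @param path destination file.
#' @return invisibly, \code{path}.
#' @export
write_nccv_json <- function(x, path) {
  stopifnot(inherits(x, "nccv"))
  obj <- list(nccv_um3 = x$nccv_um3,
              crystal_volume_um3 = x$crystal_volume_um3,
              structure_volume_um3 = x$structure_volume_um3,
              analyzed_volume_um3 = x$analyzed_volume_um3,
              reference_volume_um3 = x$reference_volume_um3,
              band = unclass(x$band),
              components = x$components,
              profile = x$profile,
              meta = x$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
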