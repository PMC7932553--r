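#' Segmentation parameters for crystal and structure detection
#'
#' Numeric thresholds driving per-slice detection.  None of these is a
#' physical constant: RCM gain varies between sessions, so brightness is
#' gated on a robust z-score rather than a fixed gray level, and the size
#' gates are configuration with defaults tuned on the bundled simulator.
#'
#' @param bright_z_min robust z-score (median/MAD) a pixel must exceed to
#'   count as bright.  Default 5.5, calibrated on simulated noise-only
#'   stacks as the smallest level whose expected false-positive yield is
#'   zero while retaining full sensitivity to band-depth crystals (the
#'   minimum-area gate admits single pixels at coarse pixel sizes, so the
#'   brightness gate must carry the specificity).
#' @param crystal_area_min_um2,crystal_area_max_um2 in-plane area bounds
#'   (um^2) for a crystal candidate; defaults 1 and 150.  Objects above the
#'   maximum are not crystals (and set the background-flattening scale).
#' @param structure_smooth_sigma_um Gaussian smoothing scale (um) used
#'   before structure thresholding.  Default 5.
#' @param structure_area_min_um2 minimum area (um^2) for a region to count
#'   as skin structure (dermal papilla cross-section).  Default 500.
#' @param overlap_rule how candidate/structure overlap triggers exclusion:
#'   \code{"any_pixel"} (default, remove on any overlap),
#'   \code{"centroid_inside"}, or \code{"fraction"} (remove when the
#'   overlapping fraction of the candidate reaches \code{overlap_fraction}).
#' @param overlap_fraction overlap fraction for \code{overlap_rule =
#'   "fraction"}; default 0.5.
#' @return an object of class \code{"segmentation_params"}.
#' @export
segmentation_params <- function(bright_z_min = 5.5,
                                crystal_area_min_um2 = 1,
                                crystal_area_max_um2 = 150,
                                structure_smooth_sigma_um = 5,
                                structure_area_min_um2 = 500,
                                overlap_rule = c("any_pixel",
                                                 "centroid_inside",
                                                 "fraction"),
                                overlap_fraction = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(bright_z_min > 0,
            crystal_area_min_um2 > 0,
            crystal_area_min_um2 < crystal_area_max_um2,
            crystal_area_max_um2 < structure_area_min_um2,
            structure_smooth_sigma_um > 0,
            overlap_fraction > 0, overlap_fraction <= 1)
  structure(list(bright_z_min = bright_z_min,
                 crystal_area_min_um2 = crystal_area_min_um2,
                 crystal_area_max_um2 = crystal_area_max_um2,
                 structure_smooth_sigma_um = structure_smooth_sigma_um,
                 structure_area_min_um2 = structure_area_min_um2,
                 overlap_rule = overlap_rule,
                 overlap_fraction = overlap_fraction),
            class = "segmentation_params")
}

# Build a region_set from an integer label matrix.  Region statistics:
# area in um^2 (pixel count x pixel area), centroid in pixel coordinates
# (x = column, y = row), mean raw intensity.
region_set <- function(labels, slice, slice_index, kind, pixel_size_um) {
  nlab <- max(labels)
  if (nlab == 0L) {
    regions <- data.frame(label = integer(0), area_um2 = numeric(0),
                          centroid_x_px = numeric(0),
                          centroid_y_px = numeric(0),
                          mean_intensity = numeric(0))
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    npx <- tabulate(lab, nbins = nlab)
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    regions <- data.frame(
      label = seq_len(nlab),
      area_um2 = npx * pixel_size_um^2,
      centroid_x_px = as.numeric(rowsum(cols, lab)) / npx,
      centroid_y_px = as.numeric(rowsum(rows, lab)) / npx,
      mean_intensity = as.numeric(rowsum(slice[idx], lab)) / npx)
  }
  structure(list(slice_index = as.integer(slice_index),
                 labels = labels, regions = regions, kind = kind),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set (%s): slice %d, %d region(s), total area %.1f um2\n",
              x$kind, x$slice_index, nrow(x$regions),
              sum(x$regions$area_um2)))
  invisible(x)
}

# Robust per-slice noise scale: MAD of horizontal first differences,
# scaled to the SD of the underlying pixel noise.  Immune to slowly
# varying illumination and to bright plateaus (papillae), whose edges are
# sparse; a plain slice MAD would inflate on strongly bimodal slices.
noise_scale <- function(slice) {
  mad(slice[, -1L] - slice[, -ncol(slice)]) / sqrt(2)
}

# Keep only the listed labels and renumber them 1..k contiguously,
# preserving order.  Region table rows follow.
relabel_regions <- function(rs, keep, kind = rs$kind) {
  labels <- rs$labels
  map <- integer(max(labels, 1L))
  map[keep] <- seq_along(keep)
  sel <- labels > 0L
  labels[sel] <- map[labels[sel]]
  regions <- rs$regions[match(keep, rs$regions$label), , drop = FALSE]
  regions$label <- seq_along(keep)
  rownames(regions) <- NULL
  structure(list(slice_index = rs$slice_index, labels = labels,
                 regions = regions, kind = kind),
            class = "region_set")
}

#' Flatten the background of one en-face slice
#'
#' White top-hat transform with a disc structuring element whose radius
#' matches the upper crystal size scale
#' (\code{sqrt(crystal_area_max_um2 / pi)}): objects at or below crystal
#' scale survive, while slowly varying illumination and large structures
#' are removed.  A flat slice maps to all zeros.
#'
#' @param slice nonnegative numeric matrix (one en-face slice).
#' @param geometry the stack's [acquisition_geometry()] (supplies the
#'   pixel size used to convert the radius to pixels).
#' @param params a [segmentation_params()].
#' @return nonnegative matrix of the same shape.
#' @export
preprocess_slice <- function(slice, geometry, params = segmentation_params()) {
  stopifnot(is.matrix(slice), all(slice >= 0))
  r_um <- sqrt(params$crystal_area_max_um2 / pi)
  r_px <- max(1L, as.integer(round(r_um / geometry$pixel_size_um)))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  out <- EBImage::whiteTopHat(slice, brush)
  out[out < 0] <- 0
  out
}

#' Detect crystal candidates on one slice
#'
#' Selects all small bright objects: after background flattening
#' ([preprocess_slice()]), pixels whose robust z-score against the slice
#' median/MAD exceeds \code{bright_z_min} are labelled with in-plane
#' 8-connectivity, and components are kept iff their area lies within the
#' configured crystal bounds.  The robust z-score makes detection
#' invariant to affine intensity rescaling of the slice.
#'
#' Objects brighter than the threshold but larger than the crystal upper
#' bound are not crystals, and neither are the thin rim residuals the
#' top-hat leaves at their boundaries; candidates touching the (slightly
#' dilated) footprint of such over-size bright objects are discarded.
#'
#' @inheritParams preprocess_slice
#' @param slice_index 1-based slice index recorded in the result.
#' @return a \code{region_set} of kind \code{"crystal_candidate"}; empty
#'   when nothing qualifies (degenerate slices are not an error).
#' @export
detect_crystal_candidates <- function(slice, geometry,
                                      params = segmentation_params(),
                                      slice_index = 1L) {
  flat <- preprocess_slice(slice, geometry, params)
  # noise scale from the raw slice: the top-hat residual compresses the
  # bulk of the noise, so its own MAD understates the tail spread
  s <- noise_scale(slice)
  m <- median(flat)
  mask <- flat > m + params$bright_z_min * s
  labels <- label_components(mask)
  rs <- region_set(labels, slice, slice_index, "crystal_candidate",
                   geometry$pixel_size_um)
  keep <- rs$regions$label[
    rs$regions$area_um2 >= params$crystal_area_min_um2 &
    rs$regions$area_um2 <= params$crystal_area_max_um2]

  # rim-artifact guard: bright regions of the *raw* slice whose area
  # exceeds the crystal maximum (papilla rims, plateaus) veto any
  # candidate within 2 px of their footprint
  if (length(keep)) {
    raw_mask <- slice > median(slice) + params$bright_z_min * max(s, 1e-12)
    rl <- label_components(raw_mask)
    if (max(rl) > 0L) {
      a_px <- tabulate(rl[rl > 0L], nbins = max(rl))
      big <- a_px * pixel_area_um2(geometry) > params$crystal_area_max_um2
      if (any(big)) {
        big_mask <- matrix(0L, nrow(rl), ncol(rl))
        sel <- rl > 0L
        big_mask[sel] <- as.integer(big[rl[sel]])
        veto <- EBImage::dilate(big_mask,
                                EBImage::makeBrush(5L, "disc")) > 0
        hit <- tabulate(rs$labels[veto], nbins = max(rs$labels))
        keep <- setdiff(keep, which(hit > 0L))
      }
    }
  }
  relabel_regions(rs, keep)
}

#' Detect skin structure (dermal papillae) on one slice
#'
#' Dermal papillae appear in en-face RCM as large bright rings.  The slice
#' is Gaussian-smoothed at \code{structure_smooth_sigma_um}, thresholded
#' by Otsu's method, morphologically closed and hole-filled (so annular
#' rims become filled footprints), and components with area at least
#' \code{structure_area_min_um2} are kept.  Otsu's threshold always splits
#' a histogram, even a unimodal noise-only one, so a slice is treated as
#' structure-free unless the split genuinely separates two intensity
#' classes: the above/below-threshold means must differ by at least four
#' times the robust spread of the below-threshold class (factor 4).
#'
#' @inheritParams detect_crystal_candidates
#' @return a \code{region_set} of kind \code{"structure"}, possibly empty.
#' @export
detect_skin_structure <- function(slice, geometry,
                                  params = segmentation_params(),
                                  slice_index = 1L) {
  stopifnot(is.matrix(slice), all(slice >= 0))
  empty <- function() region_set(matrix(0L, nrow(slice), ncol(slice)),
                                 slice, slice_index, "structure",
                                 geometry$pixel_size_um)
  sigma_px <- params$structure_smooth_sigma_um / geometry$pixel_size_um
  g <- EBImage::gblur(slice, sigma = sigma_px)
  rg <- range(g)
  if (diff(rg) <= 0) return(empty())
  thr <- EBImage::otsu(EBImage::Image(g), range = rg)
  lo <- g[g <= thr]
  hi <- g[g > thr]
  if (length(hi) == 0L ||
      mean(hi) - mean(lo) < 4 * max(mad(lo), 1e-12)) return(empty())
  mask <- g > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(7L, shape = "disc"))
  mask <- EBImage::fillHull(mask) > 0
  labels <- label_components(mask)
  rs <- region_set(labels, slice, slice_index, "structure",
                   geometry$pixel_size_um)
  keep <- rs$regions$label[
    rs$regions$area_um2 >= params$structure_area_min_um2]
  relabel_regions(rs, keep)
}

#' Remove crystal candidates overlapping skin structure
#'
#' Dermal papillae produce bright false-positive objects; any candidate
#' that overlaps a structure region (under the configured overlap rule) is
#' eliminated, leaving only isolated crystals.  Surviving regions are
#' relabelled contiguously with their areas unchanged.
#'
#' @param candidates \code{region_set} of kind \code{"crystal_candidate"}.
#' @param structure \code{region_set} of kind \code{"structure"} on the
#'   same slice and grid.
#' @param params a [segmentation_params()]; \code{overlap_rule} selects
#'   the exclusion rule.
#' @return a \code{region_set} of kind \code{"isolated_crystal"}.
#' @export
exclude_structure <- function(candidates, structure,
                              params = segmentation_params()) {
  stopifnot(inherits(candidates, "region_set"),
            inherits(structure, "region_set"))
  if (candidates$slice_index != structure$slice_index)
    stop("candidate and structure region sets are from different slices")
  if (!identical(dim(candidates$labels), dim(structure$labels)))
    stop("candidate and structure label grids have different shapes")
  nlab <- max(candidates$labels)
  if (nlab == 0L)
    return(relabel_regions(candidates, integer(0), "isolated_crystal"))
  smask <- structure$labels > 0L
  overlap_px <- tabulate(candidates$labels[smask], nbins = nlab)
  npx <- tabulate(candidates$labels[candidates$labels > 0L], nbins = nlab)
  remove <- switch(params$overlap_rule,
    any_pixel = overlap_px > 0L,
    fraction = overlap_px / npx >= params$overlap_fraction,
    centroid_inside = {
      cx <- pmin(pmax(round(candidates$regions$centroid_x_px), 1L),
                 ncol(smask))
      cy <- pmin(pmax(round(candidates$regions$centroid_y_px), 1L),
                 nrow(smask))
      smask[cbind(cy, cx)][order(candidates$regions$label)]
    })
  keep <- which(!remove)
  relabel_regions(candidates, keep, "isolated_crystal")
}

#' Export a region table as a data frame
#'
#' @param x a \code{region_set}.
#' @param ... unused.
#' @return data frame with columns slice_index, label, kind, area_um2,
#'   centroid_x_px, centroid_y_px, mean_intensity — the per-region CSV
#'   schema used by the command-line tools.
#' @export
as.data.frame.region_set <- function(x, ...) {
  if (nrow(x$regions) == 0L)
    return(cbind(data.frame(slice_index = integer(0), label = integer(0),
                            kind = character(0)),
                 x$regions[, -1, drop = FALSE]))
  data.frame(slice_index = x$slice_index, label = x$regions$label,
             kind = x$kind, x$regions[, -1, drop = FALSE])
}
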