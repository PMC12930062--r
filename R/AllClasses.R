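#' @import methods
NULL

#' Calibrated single-channel intensity stack
#'
#' A \code{VoxelGrid} holds one fluorescence channel of a confocal z-stack
#' together with its voxel calibration. Values are stored as a numeric array
#' with dimensions \code{(ny, nx, nz)} (row = y, column = x, slice = z); all
#' coordinates reported by the package follow the \code{(z, y, x)} convention,
#' 0-based, with half-open voxel extents, so the physical centre of voxel
#' \code{(z, y, x)} is \code{((z + 0.5) * dz, (y + 0.5) * dy, (x + 0.5) * dx)}
#' micrometres.
#'
#' @slot values numeric array \code{(ny, nx, nz)} of non-negative, finite
#'   intensities (native detector units until normalization).
#' @slot spacing named numeric of length 3, \code{c(dz =, dy =, dx =)}, voxel
#'   edge lengths in micrometres, all strictly positive.
#'
#' @seealso [VoxelGrid()] for the constructor, [TwoChannelStack-class].
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
  v <- object@values
  sp <- object@spacing
  msg <- character()
  if (length(dim(v)) != 3L)
    msg <- c(msg, "'values' must be a 3D array with dimensions (ny, nx, nz)")
  else if (any(dim(v) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "intensities must be finite and non-missing")
  else if (any(v < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(sp) != 3L || !identical(names(sp), c("dz", "dy", "dx")))
    msg <- c(msg, "'spacing' must be named c(dz, dy, dx)")
  else if (anyNA(sp) || any(sp <= 0))
    msg <- c(msg, "voxel sizes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values numeric 3D array, dimensions \code{(ny, nx, nz)}.
#' @param dz,dy,dx voxel edge lengths in micrometres. Defaults follow the
#'   acquisition geometry used throughout the package: 0.30 um z-step and
#'   0.06013 um (60.13 nm) in-plane pixels.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(0, dim = c(8, 8, 3)))
#' dim(intensities(g))
#' @export
VoxelGrid <- function(values, dz = 0.30, dy = 0.06013, dx = 0.06013) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  new("VoxelGrid", values = values,
      spacing = c(dz = dz, dy = dy, dx = dx))
}

#' Dual-channel synaptic-marker stack
#'
#' Pairs the pre-synaptic (vGluT1) and post-synaptic (Homer1) channels of one
#' acquired image with its provenance metadata (mouse, group, region of
#' interest, hemisphere, section). Both channels must share dimensions and
#' voxel calibration.
#'
#' @slot pre,post [VoxelGrid-class] objects for the pre-/post-synaptic
#'   channel.
#' @slot meta named list; recognised entries are \code{image_id},
#'   \code{mouse}, \code{group}, \code{roi} (one of \code{"MO"}, \code{"VO"}),
#'   \code{hemisphere} (\code{"left"}/\code{"right"}) and \code{section}.
#'   Missing hemisphere/section are allowed (the image then counts as one of
#'   the available replicates during aggregation) but are flagged with a
#'   warning at construction.
#' @export
setClass("TwoChannelStack",
  representation(pre = "VoxelGrid", post = "VoxelGrid", meta = "list"))

setValidity("TwoChannelStack", function(object) {
  msg <- character()
  if (!identical(dim(object@pre@values), dim(object@post@values)))
    msg <- c(msg, "'pre' and 'post' must have identical dimensions")
  if (!isTRUE(all.equal(object@pre@spacing, object@post@spacing)))
    msg <- c(msg, "'pre' and 'post' must have identical voxel sizes")
  roi <- object@meta$roi
  if (!is.null(roi) && !is.na(roi) && !roi %in% c("MO", "VO"))
    msg <- c(msg, "meta$roi must be one of 'MO', 'VO'")
  hemi <- object@meta$hemisphere
  if (!is.null(hemi) && !is.na(hemi) && !hemi %in% c("left", "right"))
    msg <- c(msg, "meta$hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a TwoChannelStack
#'
#' @param pre,post [VoxelGrid-class] channels (pre-/post-synaptic marker).
#' @param meta named list of image metadata; see [TwoChannelStack-class].
#' @return A [TwoChannelStack-class] object.
#' @export
TwoChannelStack <- function(pre, post, meta = list()) {
  obj <- new("TwoChannelStack", pre = pre, post = post, meta = meta)
  if (is.null(meta$hemisphere) || is.null(meta$section))
    warning("stack metadata lacks hemisphere and/or section; ",
            "the image is treated as one of the available replicates",
            call. = FALSE)
  obj
}

#' Detection-chain parameters
#'
#' Free parameters of the per-channel detection chain (normalization,
#' white top-hat, Wiener denoising, multi-scale LoG, median mask refinement,
#' size/intensity quality filtering). Defaults target puncta of roughly
#' 0.2--0.6 um diameter at 60 nm pixels and are this package's choices; they
#' can all be overridden.
#'
#' @slot p_low,p_high normalization percentiles, in percent.
#' @slot tophat_radius disc structuring-element radius, pixels.
#' @slot wiener_window odd Wiener window edge, pixels.
#' @slot wiener_noise noise-variance estimate, or \code{NA} for the adaptive
#'   default (mean of the local variances).
#' @slot log_sigmas LoG scales, pixels; the per-voxel response is the maximum
#'   over scales.
#' @slot response_threshold minimum scale-normalized LoG response, in
#'   normalized-intensity units.
#' @slot median_window odd binary-median window edge, pixels.
#' @slot min_voxels,max_voxels punctum size bounds, voxels.
#' @slot min_mean_intensity floor on punctum mean normalized intensity.
#' @export
setClass("DetectionParams",
  representation(
    p_low = "numeric", p_high = "numeric",
    tophat_radius = "numeric",
    wiener_window = "integer", wiener_noise = "numeric",
    log_sigmas = "numeric", response_threshold = "numeric",
    median_window = "integer",
    min_voxels = "integer", max_voxels = "numeric",
    min_mean_intensity = "numeric"))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (!(object@p_low >= 0 && object@p_low < object@p_high &&
        object@p_high <= 100))
    msg <- c(msg, "need 0 <= p_low < p_high <= 100")
  if (object@tophat_radius < 1)
    msg <- c(msg, "tophat_radius must be >= 1")
  if (object@wiener_window < 3L || object@wiener_window %% 2L == 0L)
    msg <- c(msg, "wiener_window must be odd and >= 3")
  if (!is.na(object@wiener_noise) && object@wiener_noise < 0)
    msg <- c(msg, "wiener_noise must be >= 0 or NA for adaptive")
  if (any(object@log_sigmas <= 0))
    msg <- c(msg, "log_sigmas must be > 0")
  if (object@response_threshold < 0)
    msg <- c(msg, "response_threshold must be >= 0")
  if (object@median_window < 1L || object@median_window %% 2L == 0L)
    msg <- c(msg, "median_window must be odd and >= 1")
  if (object@min_voxels < 1L)
    msg <- c(msg, "min_voxels must be >= 1")
  if (object@min_voxels > object@max_voxels)
    msg <- c(msg, "min_voxels must be <= max_voxels")
  if (object@min_mean_intensity < 0)
    msg <- c(msg, "min_mean_intensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct detection parameters
#'
#' @param p_low,p_high normalization percentiles (percent).
#' @param tophat_radius disc radius in pixels for the white top-hat.
#' @param wiener_window odd Wiener window edge (pixels).
#' @param wiener_noise noise variance, or \code{"auto"}/\code{NA} to estimate
#'   it as the mean of the local variances.
#' @param log_sigmas LoG scales in pixels.
#' @param response_threshold minimum scale-normalized LoG response.
#' @param median_window odd window edge for binary median refinement.
#' @param min_voxels,max_voxels size bounds in voxels.
#' @param min_mean_intensity minimum mean normalized intensity.
#' @return A [DetectionParams-class] object.
#' @examples
#' detectionParams(response_threshold = 0.2)
#' @export
detectionParams <- function(p_low = 0.1, p_high = 99.9,
                            tophat_radius = 8,
                            wiener_window = 3L, wiener_noise = "auto",
                            log_sigmas = c(1.5, 2, 3),
                            response_threshold = 0.12,
                            median_window = 3L,
                            min_voxels = 4L, max_voxels = 500,
                            min_mean_intensity = 0.05) {
  if (identical(wiener_noise, "auto")) wiener_noise <- NA_real_
  new("DetectionParams",
      p_low = p_low, p_high = p_high, tophat_radius = tophat_radius,
      wiener_window = as.integer(wiener_window),
      wiener_noise = as.numeric(wiener_noise),
      log_sigmas = log_sigmas, response_threshold = response_threshold,
      median_window = as.integer(median_window),
      min_voxels = as.integer(min_voxels), max_voxels = max_voxels,
      min_mean_intensity = min_mean_intensity)
}

#' Detected puncta of one channel
#'
#' Container for the puncta detected in one channel of one image. Each
#' punctum is a 3D object assembled from per-slice 2D footprints linked
#' across contiguous z-slices; measurements live in a data frame (one row
#' per punctum) and the pixel-level footprints in a parallel list.
#'
#' @slot channel \code{"pre"} or \code{"post"}.
#' @slot image_id source image identifier.
#' @slot puncta data.frame with columns \code{id}, \code{z_min}, \code{z_max}
#'   (0-based slice indices), \code{centroid_z_um}, \code{centroid_y_um},
#'   \code{centroid_x_um} (intensity-weighted, micrometres),
#'   \code{n_voxels}, \code{volume_um3}, \code{mean_intensity} (mean
#'   normalized intensity over member voxels) and \code{peak_response}
#'   (maximum LoG response).
#' @slot footprints list, one element per punctum: a list keyed by z-slice
#'   (names are 0-based slice indices) of sorted integer vectors of linear
#'   in-slice pixel indices (1-based, column-major over \code{(ny, nx)}).
#' @slot dims integer \code{(ny, nx, nz)} of the source grid.
#' @slot spacing voxel sizes \code{c(dz, dy, dx)} in micrometres.
#' @slot params the [DetectionParams-class] used.
#' @export
setClass("PunctaSet",
  representation(channel = "character", image_id = "character",
                 puncta = "data.frame", footprints = "list",
                 dims = "integer", spacing = "numeric",
                 params = "DetectionParams"))

setValidity("PunctaSet", function(object) {
  msg <- character()
  p <- object@puncta
  need <- c("id", "z_min", "z_max", "centroid_z_um", "centroid_y_um",
            "centroid_x_um", "n_voxels", "volume_um3", "mean_intensity",
            "peak_response")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("puncta table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(p$id)) msg <- c(msg, "punctum ids must be unique")
    if (nrow(p) != length(object@footprints))
      msg <- c(msg, "one footprint entry per punctum required")
    if (nrow(p) > 0) {
      if (any(p$n_voxels < 1)) msg <- c(msg, "puncta must have >= 1 voxel")
      if (any(p$volume_um3 <= 0)) msg <- c(msg, "punctum volume must be > 0")
      span <- p$z_max - p$z_min + 1L
      nsl <- vapply(object@footprints, length, integer(1))
      if (any(span != nsl))
        msg <- c(msg, "footprints must cover a contiguous z-range")
      if (any(vapply(object@footprints,
                     function(f) any(!vapply(f, length, integer(1))),
                     logical(1))))
        msg <- c(msg, "every per-slice footprint must be non-empty")
    }
  }
  if (!object@channel %in% c("pre", "post"))
    msg <- c(msg, "channel must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})
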