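#' @describeIn VoxelGrid-class intensity array accessor
#' @param x a \code{VoxelGrid}.
#' @export
setMethod("intensities", "VoxelGrid", function(x) x@values)

#' @describeIn VoxelGrid-class voxel sizes \code{c(dz, dy, dx)} in um
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@spacing)

#' @describeIn TwoChannelStack-class voxel sizes of the shared geometry
#' @param x a \code{TwoChannelStack}.
#' @export
setMethod("voxelSize", "TwoChannelStack", function(x) x@pre@spacing)

#' @describeIn TwoChannelStack-class metadata list accessor
#' @export
setMethod("stackMeta", "TwoChannelStack", function(x) x@meta)

#' Extract one channel of a dual-channel stack
#'
#' @param x a [TwoChannelStack-class].
#' @param which \code{"pre"} or \code{"post"}.
#' @return the requested [VoxelGrid-class].
#' @export
channelGrid <- function(x, which = c("pre", "post")) {
  which <- match.arg(which)
  slot(x, which)
}

#' @describeIn PunctaSet-class measurement table accessor
#' @param x a \code{PunctaSet}.
#' @export
setMethod("puncta", "PunctaSet", function(x) x@puncta)

#' @describeIn PunctaSet-class footprint accessor
#' @export
setMethod("footprints", "PunctaSet", function(x) x@footprints)

#' @describeIn PunctaSet-class number of puncta
#' @export
setMethod("nPuncta", "PunctaSet", function(x) nrow(x@puncta))

#' @describeIn PunctaSet-class channel label accessor
#' @export
setMethod("channelLabel", "PunctaSet", function(x) x@channel)

#' @describeIn PunctaSet-class voxel sizes
#' @export
setMethod("voxelSize", "PunctaSet", function(x) x@spacing)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  sp <- object@spacing
  cat(sprintf("VoxelGrid: %d x %d px, %d z-slices\n", d[2], d[1], d[3]))
  cat(sprintf("  voxel %.5g x %.5g x %.5g um (dx, dy, dz)\n",
              sp["dx"], sp["dy"], sp["dz"]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "TwoChannelStack", function(object) {
  d <- dim(object@pre@values)
  m <- object@meta
  cat(sprintf("TwoChannelStack: %d x %d px, %d z-slices, 2 channels\n",
              d[2], d[1], d[3]))
  lab <- function(k) if (is.null(m[[k]])) "<NA>" else as.character(m[[k]])
  cat(sprintf("  image %s | mouse %s | group %s | ROI %s | %s hemi | section %s\n",
              lab("image_id"), lab("mouse"), lab("group"), lab("roi"),
              lab("hemisphere"), lab("section")))
})

setMethod("show", "DetectionParams", function(object) {
  cat("DetectionParams\n")
  cat(sprintf("  normalize: p%.4g-p%.4g  top-hat r=%g px  wiener %dx%d (noise %s)\n",
              object@p_low, object@p_high, object@tophat_radius,
              object@wiener_window, object@wiener_window,
              if (is.na(object@wiener_noise)) "auto"
              else format(object@wiener_noise)))
  cat(sprintf("  LoG sigmas {%s} px  response >= %g  median %dx%d\n",
              paste(object@log_sigmas, collapse = ", "),
              object@response_threshold,
              object@median_window, object@median_window))
  cat(sprintf("  size %d-%g voxels  mean intensity >= %g\n",
              object@min_voxels, object@max_voxels,
              object@min_mean_intensity))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet: %d %s-channel puncta (image %s)\n",
              nrow(object@puncta), object@channel, object@image_id))
  if (nrow(object@puncta)) {
    cat(sprintf("  voxels per punctum: median %g [%g, %g]\n",
                stats::median(object@puncta$n_voxels),
                min(object@puncta$n_voxels), max(object@puncta$n_voxels)))
    cat(sprintf("  mean intensity: median %.3g\n",
                stats::median(object@puncta$mean_intensity)))
  }
})
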