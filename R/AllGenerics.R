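#' Intensity array of a grid or stack channel
#'
#' @param x a [VoxelGrid-class].
#' @return numeric array \code{(ny, nx, nz)}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Voxel sizes in micrometres
#'
#' @param x a [VoxelGrid-class], [TwoChannelStack-class] or
#'   [PunctaSet-class].
#' @return named numeric \code{c(dz, dy, dx)}.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Punctum measurement table
#'
#' @param x a [PunctaSet-class].
#' @return data.frame, one row per punctum (see [PunctaSet-class]).
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))

#' Per-slice pixel footprints of detected puncta
#'
#' @param x a [PunctaSet-class].
#' @return list, one element per punctum (see [PunctaSet-class]).
#' @export
setGeneric("footprints", function(x) standardGeneric("footprints"))

#' Number of detected puncta
#'
#' @param x a [PunctaSet-class].
#' @return integer count.
#' @export
setGeneric("nPuncta", function(x) standardGeneric("nPuncta"))

#' Channel label of a puncta set
#'
#' @param x a [PunctaSet-class].
#' @return \code{"pre"} or \code{"post"}.
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' Image metadata
#'
#' @param x a [TwoChannelStack-class].
#' @return named list of metadata.
#' @export
setGeneric("stackMeta", function(x) standardGeneric("stackMeta"))
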