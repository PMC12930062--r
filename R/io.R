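# Sidecar path for a stack file.
.sidecarPath <- function(path) paste0(path, ".yaml")

# Parse voxel sizes / layout from an OME-XML ImageDescription, if present.
.parseOME <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(dx = at("PhysicalSizeX"), dy = at("PhysicalSizeY"),
       dz = at("PhysicalSizeZ"),
       size_c = at("SizeC"), size_z = at("SizeZ"),
       dimension_order = xml2::xml_attr(px, "DimensionOrder"))
}

#' Write a dual-channel stack to TIFF with a calibration sidecar
#'
#' Stores both channels as a multi-page 16-bit grayscale TIFF (pages
#' ordered channel-fastest, i.e. pre/post interleaved per z-slice, the
#' XYCZT convention) and writes a YAML sidecar (\code{<path>.yaml})
#' carrying the voxel calibration, channel map, page order and image
#' metadata. Intensities must be integer detector counts in
#' \code{[0, 65535]}; the write/read round trip is then bit-identical.
#'
#' @param stack a [TwoChannelStack-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "TwoChannelStack"))
  pre <- stack@pre@values
  post <- stack@post@values
  if (any(pre != round(pre)) || any(post != round(post)) ||
      max(pre, post) > 65535)
    stop("stack intensities must be integer counts in [0, 65535]")
  nz <- dim(pre)[3]
  pages <- vector("list", 2L * nz)
  for (k in seq_len(nz)) {
    pages[[2L * k - 1L]] <- pre[, , k] / 65535
    pages[[2L * k]] <- post[, , k] / 65535
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "LZW", reduce = FALSE)
  if (ok != 2L * nz) stop("failed to write all pages to ", path)
  sp <- stack@pre@spacing
  side <- list(
    format = "synaptoscope-stack-v1",
    ny = dim(pre)[1], nx = dim(pre)[2], nz = nz, n_channels = 2L,
    page_order = "czt",
    channels = list(pre = 1L, post = 2L),
    spacing_um = list(dz = unname(sp["dz"]), dy = unname(sp["dy"]),
                      dx = unname(sp["dx"])),
    intensity = "uint16 counts",
    meta = stack@meta)
  yaml::write_yaml(side, .sidecarPath(path))
  invisible(path)
}

#' Read a dual-channel stack from TIFF
#'
#' Reads a multi-page TIFF and assembles the pre- and post-synaptic
#' channels with their voxel calibration. Calibration and channel layout
#' are resolved, in order of precedence, from (1) explicit arguments,
#' (2) the YAML sidecar written by [writeStack()], (3) an OME-XML
#' ImageDescription embedded in the file. Missing calibration is an error,
#' never a silent default. Files holding fewer than two channels are
#' rejected.
#'
#' @param path TIFF path.
#' @param channel_map named integer vector mapping \code{pre}/\code{post}
#'   to 1-based channel indices.
#' @param spacing optional explicit voxel sizes, named \code{c(dz =, dy =,
#'   dx =)} in micrometres.
#' @param n_channels optional explicit channel count of the file.
#' @param page_order page layout: \code{"czt"} (channel fastest, default)
#'   or \code{"zct"} (slice fastest).
#' @param meta metadata list for the stack; entries present in a sidecar
#'   are used as defaults.
#' @return A [TwoChannelStack-class].
#' @export
readStack <- function(path, channel_map = c(pre = 1L, post = 2L),
                      spacing = NULL, n_channels = NULL,
                      page_order = NULL, meta = list()) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- NULL
  if (file.exists(.sidecarPath(path)))
    side <- yaml::read_yaml(.sidecarPath(path))
  ome <- .parseOME(attr(pages[[1]], "description"))

  if (is.null(spacing)) {
    if (!is.null(side)) {
      spacing <- c(dz = as.numeric(side$spacing_um$dz),
                   dy = as.numeric(side$spacing_um$dy),
                   dx = as.numeric(side$spacing_um$dx))
    } else if (!is.null(ome) && !anyNA(c(ome$dz, ome$dy, ome$dx))) {
      spacing <- c(dz = ome$dz, dy = ome$dy, dx = ome$dx)
    }
  }
  if (is.null(spacing) || anyNA(spacing) || any(spacing <= 0))
    stop("missing voxel calibration for ", path,
         ": supply 'spacing' or provide a sidecar/OME metadata")
  if (is.null(n_channels)) {
    n_channels <- if (!is.null(side)) as.integer(side$n_channels)
      else if (!is.null(ome) && !is.na(ome$size_c)) as.integer(ome$size_c)
      else 2L
  }
  if (n_channels < 2L)
    stop("requires two channels: ", path, " holds ", n_channels)
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages), " not divisible by ", n_channels,
         " channels")
  if (is.null(page_order)) {
    page_order <- if (!is.null(side)) side$page_order
      else if (!is.null(ome) && !is.na(ome$dimension_order) &&
               startsWith(ome$dimension_order, "XYZ")) "zct"
      else "czt"
  }
  nz <- length(pages) %/% n_channels
  dims <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), dims), logical(1))))
    stop("channel/page shape mismatch in ", path)

  grab <- function(ch) {
    idx <- if (page_order == "czt") ch + n_channels * (seq_len(nz) - 1L)
           else (ch - 1L) * nz + seq_len(nz)
    arr <- array(0, dim = c(dims, nz))
    for (k in seq_len(nz))
      arr[, , k] <- round(pages[[idx[k]]] * 65535)
    arr
  }
  if (!all(c("pre", "post") %in% names(channel_map)))
    stop("channel_map must name 'pre' and 'post'")
  if (max(channel_map) > n_channels)
    stop("channel_map index exceeds channel count")
  if (!is.null(side) && length(side$meta))
    meta <- utils::modifyList(side$meta, meta)
  suppressWarnings(TwoChannelStack(
    VoxelGrid(grab(channel_map[["pre"]]), dz = spacing[["dz"]],
              dy = spacing[["dy"]], dx = spacing[["dx"]]),
    VoxelGrid(grab(channel_map[["post"]]), dz = spacing[["dz"]],
              dy = spacing[["dy"]], dx = spacing[["dx"]]),
    meta = meta))
}

#' Write a table as lossless CSV
#'
#' Writes a data.frame as UTF-8 CSV with a header row and \code{'.'}
#' decimal separator. Double columns are rendered with 17 significant
#' digits so that [readRecords()] reproduces them exactly; a zero-row table
#' yields a header-only file.
#'
#' @param records data.frame with at least one column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecords <- function(records, path) {
  stopifnot(is.data.frame(records), ncol(records) >= 1L)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, file = path, sep = ",", dec = ".",
                     quote = TRUE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [writeRecords()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored at full precision.
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
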