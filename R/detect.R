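# 8-connected labelling of a binary slice: 4-connected bwlabel, then a
# union-find merge of diagonally adjacent label pairs.
.label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  nmax <- max(L)
  if (nmax < 2) return(L)
  nr <- nrow(L)
  nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]     # down-right diagonal
  a2 <- L[-nr, -1];  b2 <- L[-1, -nc]    # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0) return(L)
  parent <- seq_len(nmax)
  findroot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- findroot(pairs[r, 1]); rb <- findroot(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nmax), findroot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  L[L > 0] <- remap[L[L > 0]]
  L
}

# Link per-slice 2D components into 3D puncta. Components in slice z join
# the punctum of the previous slice they overlap most (ties: lower punctum
# id); otherwise they found a new punctum. Returns a list of puncta, each a
# list of per-slice integer pixel-index vectors named by 0-based z.
.linkComponents <- function(mask) {
  d <- dim(mask)
  npix <- d[1] * d[2]
  puncta <- list()          # punctum -> list of per-slice pixel vectors
  prev_map <- integer(npix) # punctum id per pixel of previous slice
  for (k in seq_len(d[3])) {
    cur_map <- integer(npix)
    sl <- mask[, , k]
    if (!any(sl)) {
      prev_map <- cur_map
      next
    }
    L <- .label8(sl)
    idx <- which(L > 0)
    comp_pix <- split(idx, L[idx])
    for (pix in comp_pix) {
      hits <- prev_map[pix]
      hits <- hits[hits > 0]
      if (length(hits)) {
        tab <- table(hits)
        best <- max(tab)
        pid <- min(as.integer(names(tab)[tab == best]))
        zkey <- as.character(k - 1L)
        old <- puncta[[pid]][[zkey]]
        puncta[[pid]][[zkey]] <- if (is.null(old)) sort(pix)
                                 else sort(unique(c(old, pix)))
      } else {
        pid <- length(puncta) + 1L
        puncta[[pid]] <- stats::setNames(list(sort(pix)),
                                         as.character(k - 1L))
      }
      cur_map[pix] <- pid
    }
    prev_map <- cur_map
  }
  puncta
}

# Measure linked puncta against the normalized intensity grid and the LoG
# response array. Returns list(puncta = data.frame, footprints = list).
.measurePuncta <- function(fps, norm_values, response, dims, spacing) {
  n <- length(fps)
  if (n == 0) {
    return(list(puncta = .emptyPunctaTable(), footprints = list()))
  }
  ny <- dims[1]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- fps[[i]]
    zs <- as.integer(names(fp))            # 0-based slice indices
    nv <- 0L
    wsum <- 0; wz <- 0; wy <- 0; wx <- 0
    isum <- 0; pk <- -Inf
    for (j in seq_along(fp)) {
      pix <- fp[[j]]                       # 1-based in-slice linear indices
      z1 <- zs[j] + 1L
      ints <- norm_values[pix + (z1 - 1L) * ny * dims[2]]
      resp <- response[pix + (z1 - 1L) * ny * dims[2]]
      yy <- ((pix - 1L) %% ny)             # 0-based row (y)
      xx <- ((pix - 1L) %/% ny)            # 0-based col (x)
      w <- ints
      wsum <- wsum + sum(w)
      wz <- wz + sum(w) * (zs[j] + 0.5)
      wy <- wy + sum(w * (yy + 0.5))
      wx <- wx + sum(w * (xx + 0.5))
      isum <- isum + sum(ints)
      pk <- max(pk, max(resp))
      nv <- nv + length(pix)
    }
    if (wsum <= 0) {                       # fall back to unweighted centroid
      wsum <- nv
      wz <- 0; wy <- 0; wx <- 0
      for (j in seq_along(fp)) {
        pix <- fp[[j]]
        wz <- wz + length(pix) * (zs[j] + 0.5)
        wy <- wy + sum((pix - 1L) %% ny + 0.5)
        wx <- wx + sum((pix - 1L) %/% ny + 0.5)
      }
    }
    rows[[i]] <- data.frame(
      id = i, z_min = min(zs), z_max = max(zs),
      centroid_z_um = wz / wsum * spacing["dz"],
      centroid_y_um = wy / wsum * spacing["dy"],
      centroid_x_um = wx / wsum * spacing["dx"],
      n_voxels = nv,
      volume_um3 = nv * prod(spacing),
      mean_intensity = isum / nv,
      peak_response = pk)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(puncta = tab, footprints = fps)
}

.emptyPunctaTable <- function() {
  data.frame(id = integer(), z_min = integer(), z_max = integer(),
             centroid_z_um = numeric(), centroid_y_um = numeric(),
             centroid_x_um = numeric(), n_voxels = integer(),
             volume_um3 = numeric(), mean_intensity = numeric(),
             peak_response = numeric())
}

#' Detect synaptic puncta in one channel
#'
#' Runs the full per-channel detection chain: percentile intensity
#' normalization, per-slice white top-hat background removal, adaptive
#' Wiener denoising, multi-scale LoG filtering (per-voxel maximum over
#' scales), thresholding of the response into a binary candidate mask,
#' per-slice binary median refinement, 8-connected in-plane component
#' labelling, and linking of components across adjacent z-slices (footprint
#' overlap of at least one pixel; a component overlapping several existing
#' puncta joins the one with the larger overlap, ties to the lower id).
#' Surviving objects are measured and passed through [qualityFilter()].
#' The result is deterministic for fixed input and parameters.
#'
#' @param channel a [VoxelGrid-class] (one fluorescence channel).
#' @param params a [DetectionParams-class].
#' @param channel_label \code{"pre"} or \code{"post"}.
#' @param image_id source image identifier.
#' @return A [PunctaSet-class]. An empty result is not an error.
#' @examples
#' g <- VoxelGrid(array(0, dim = c(32, 32, 4)))
#' nPuncta(detectPuncta(g, detectionParams(), "pre", "blank"))
#' @export
detectPuncta <- function(channel, params = detectionParams(),
                         channel_label = c("pre", "post"),
                         image_id = "image") {
  stopifnot(is(channel, "VoxelGrid"), is(params, "DetectionParams"))
  channel_label <- match.arg(channel_label)
  validObject(params)
  d <- dim(channel@values)

  norm <- normalizeIntensity(channel, params@p_low, params@p_high)
  th <- topHatFilter(norm, params@tophat_radius)
  wn <- wienerFilter(th, params@wiener_window,
                     if (is.na(params@wiener_noise)) "auto"
                     else params@wiener_noise)
  resp <- logResponse(wn, params@log_sigmas[1])
  for (s in params@log_sigmas[-1])
    resp <- pmax(resp, logResponse(wn, s))
  mask <- resp >= params@response_threshold
  if (params@median_window > 1L) {
    # median of a binary mask == majority vote over the window; use the
    # separable running-sum box filter (replicate boundary)
    w <- params@median_window
    bm <- .boxMean(array(as.numeric(mask), dim = d), w)
    for (k in seq_len(d[3]))
      mask[, , k] <- bm[[k]] * w * w >= (w * w + 1) / 2
  }
  fps <- .linkComponents(mask)
  meas <- .measurePuncta(fps, norm@values, resp, d, channel@spacing)
  ps <- new("PunctaSet", channel = channel_label,
            image_id = as.character(image_id),
            puncta = meas$puncta, footprints = meas$footprints,
            dims = as.integer(d), spacing = channel@spacing,
            params = params)
  qualityFilter(ps, params)
}

#' Size and intensity quality filtering
#'
#' Keeps exactly the puncta whose voxel count lies in
#' \code{[min_voxels, max_voxels]} and whose mean normalized intensity is at
#' least \code{min_mean_intensity}. Order and ids of survivors are
#' preserved.
#'
#' @param x a [PunctaSet-class].
#' @param params a [DetectionParams-class] supplying the bounds (defaults to
#'   the parameters stored in \code{x}).
#' @return A filtered [PunctaSet-class].
#' @export
qualityFilter <- function(x, params = NULL) {
  stopifnot(is(x, "PunctaSet"))
  if (is.null(params)) params <- x@params
  p <- x@puncta
  keep <- p$n_voxels >= params@min_voxels &
          p$n_voxels <= params@max_voxels &
          p$mean_intensity >= params@min_mean_intensity
  out <- x
  out@puncta <- p[keep, , drop = FALSE]
  rownames(out@puncta) <- NULL
  out@footprints <- x@footprints[keep]
  out@params <- params
  out
}
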