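#' Volumetric overlap of two puncta
#'
#' Sums, over the z-slices present in both puncta, the area of the 2D
#' footprint intersection, converted to a volume with the known voxel
#' dimensions: \eqn{V = \sum_z |A_z \cap B_z| \cdot dx\,dy\,dz}. Returns 0
#' when the z-ranges or the footprints are disjoint.
#'
#' @param a,b punctum footprints: lists keyed by 0-based z-slice of integer
#'   vectors of in-slice pixel indices (as stored in a [PunctaSet-class];
#'   see [footprints()]), or a [PunctaSet-class] together with \code{ida} /
#'   \code{idb} to select puncta by id.
#' @param spacing voxel sizes \code{c(dz, dy, dx)} in micrometres; taken
#'   from the sets when \code{a}, \code{b} are \code{PunctaSet}s (which must
#'   then agree).
#' @param ida,idb punctum ids when \code{a}/\code{b} are \code{PunctaSet}s.
#' @return overlap volume in cubic micrometres.
#' @examples
#' fp <- list(`2` = 1:9, `3` = 1:9)
#' pairOverlap(fp, fp, spacing = c(dz = .3, dy = .06, dx = .06))
#' @export
pairOverlap <- function(a, b, spacing = NULL, ida = NULL, idb = NULL) {
  if (is(a, "PunctaSet")) {
    if (!isTRUE(all.equal(voxelSize(a), voxelSize(b))))
      stop("mismatched voxel dimensions")
    spacing <- voxelSize(a)
    a <- footprints(a)[[match(ida, puncta(a)$id)]]
    b <- footprints(b)[[match(idb, puncta(b)$id)]]
  }
  if (is.null(spacing)) stop("voxel spacing required")
  zs <- intersect(names(a), names(b))
  if (!length(zs)) return(0)
  vox <- sum(vapply(zs, function(z)
    length(intersect(a[[z]], b[[z]])), integer(1)))
  vox * prod(spacing)
}

# Overlap voxel counts for every pre/post punctum pair with any overlap.
# Returns data.frame(pre_id, post_id, overlap_voxels, n_shared_z).
.allOverlaps <- function(pre_set, post_set) {
  d <- pre_set@dims
  npix <- d[1] * d[2]
  pre_fp <- footprints(pre_set)
  post_fp <- footprints(post_set)
  pre_ids <- puncta(pre_set)$id
  post_ids <- puncta(post_set)$id
  # per-slice map of post punctum membership
  post_map <- vector("list", d[3])
  for (j in seq_along(post_fp)) {
    for (z in names(post_fp[[j]])) {
      zi <- as.integer(z) + 1L
      if (is.null(post_map[[zi]])) post_map[[zi]] <- integer(npix)
      post_map[[zi]][post_fp[[j]][[z]]] <- j
    }
  }
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(pre_fp)) {
    for (z in names(pre_fp[[i]])) {
      zi <- as.integer(z) + 1L
      pm <- post_map[[zi]]
      if (is.null(pm)) next
      hits <- pm[pre_fp[[i]][[z]]]
      hits <- hits[hits > 0L]
      if (!length(hits)) next
      for (j in unique(hits)) {
        key <- paste0(i, "_", j)
        prev <- acc[[key]]
        cnt <- sum(hits == j)
        acc[[key]] <- if (is.null(prev)) c(cnt, 1L) else prev + c(cnt, 1L)
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(pre_id = integer(), post_id = integer(),
                      overlap_voxels = integer(), n_shared_z = integer()))
  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  vals <- do.call(rbind, mget(keys, envir = acc))
  data.frame(pre_id = pre_ids[as.integer(ij[, 1])],
             post_id = post_ids[as.integer(ij[, 2])],
             overlap_voxels = as.integer(vals[, 1]),
             n_shared_z = as.integer(vals[, 2]))
}

#' Match pre- and post-channel puncta one-to-one by overlap volume
#'
#' Computes the volumetric overlap of every pre/post punctum pair and
#' greedily selects pairs in descending overlap order (ties broken by
#' ascending pre id, then post id), so that each punctum takes part in at
#' most one colocalized pair. The pair count is therefore bounded by the
#' smaller channel count, keeping "number of colocalized puncta" well
#' defined. Deterministic.
#'
#' @param pre_set,post_set [PunctaSet-class] objects from the same image
#'   (same \code{image_id}, geometry and voxel sizes).
#' @param min_overlap_voxels minimum overlap, voxels, for a candidate pair
#'   (default 1: any positive overlap).
#' @return data.frame of matched pairs with columns \code{pre_id},
#'   \code{post_id}, \code{n_shared_z}, \code{overlap_voxels},
#'   \code{overlap_volume_um3}, ordered as selected.
#' @export
matchPuncta <- function(pre_set, post_set, min_overlap_voxels = 1L) {
  stopifnot(is(pre_set, "PunctaSet"), is(post_set, "PunctaSet"))
  if (!identical(pre_set@image_id, post_set@image_id))
    stop("puncta sets come from different images")
  if (!identical(pre_set@dims, post_set@dims) ||
      !isTRUE(all.equal(pre_set@spacing, post_set@spacing)))
    stop("puncta sets have mismatched geometry")
  cand <- .allOverlaps(pre_set, post_set)
  cand <- cand[cand$overlap_voxels >= min_overlap_voxels, , drop = FALSE]
  empty <- data.frame(pre_id = integer(), post_id = integer(),
                      n_shared_z = integer(), overlap_voxels = integer(),
                      overlap_volume_um3 = numeric())
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$overlap_voxels, cand$pre_id, cand$post_id), ,
               drop = FALSE]
  used_pre <- integer(0)
  used_post <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$pre_id[r] %in% used_pre || cand$post_id[r] %in% used_post)
      next
    keep[r] <- TRUE
    used_pre <- c(used_pre, cand$pre_id[r])
    used_post <- c(used_post, cand$post_id[r])
  }
  out <- cand[keep, , drop = FALSE]
  out$overlap_volume_um3 <- out$overlap_voxels * prod(pre_set@spacing)
  rownames(out) <- NULL
  out[, c("pre_id", "post_id", "n_shared_z", "overlap_voxels",
          "overlap_volume_um3")]
}

#' Per-image colocalization summary
#'
#' Condenses one image's detections and matched pairs into the image-level
#' record used downstream: puncta counts per channel, number of colocalized
#' pairs, total colocalized volume, and the mean over puncta of the punctum
#' mean normalized intensity, per channel. Empty channels give zero counts
#' and missing (\code{NA}) means.
#'
#' @param pre_set,post_set [PunctaSet-class] objects of the image.
#' @param pairs data.frame from [matchPuncta()] on these sets.
#' @param image_id image identifier (defaults to the sets' id).
#' @return one-row data.frame: \code{image_id}, \code{n_pre}, \code{n_post},
#'   \code{n_coloc}, \code{mean_intensity_pre}, \code{mean_intensity_post},
#'   \code{coloc_volume_total}.
#' @export
summarizeImage <- function(pre_set, post_set,
                           pairs = matchPuncta(pre_set, post_set),
                           image_id = pre_set@image_id) {
  stopifnot(is(pre_set, "PunctaSet"), is(post_set, "PunctaSet"))
  if (nrow(pairs)) {
    if (!all(pairs$pre_id %in% puncta(pre_set)$id) ||
        !all(pairs$post_id %in% puncta(post_set)$id))
      stop("pairs reference unknown punctum ids")
  }
  mi <- function(s) if (nPuncta(s)) mean(puncta(s)$mean_intensity)
                    else NA_real_
  data.frame(
    image_id = as.character(image_id),
    n_pre = nPuncta(pre_set),
    n_post = nPuncta(post_set),
    n_coloc = nrow(pairs),
    mean_intensity_pre = mi(pre_set),
    mean_intensity_post = mi(post_set),
    coloc_volume_total = if (nrow(pairs)) sum(pairs$overlap_volume_um3)
                         else 0)
}
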