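# Shared helpers: independent oracles and small fixture builders.

# Greedy nearest-first matching of detected puncta to planted ground truth.
# Returns recall/precision with a match radius in voxel units.
matchToTruth <- function(ps, truth, max_dist = 3) {
  p <- puncta(ps)
  sp <- voxelSize(ps)
  if (nrow(p) == 0 || nrow(truth) == 0)
    return(c(recall = 0, precision = if (nrow(p)) 0 else NA_real_))
  dy <- outer(p$centroid_y_um / sp[["dy"]], truth$cy_px, "-")
  dx <- outer(p$centroid_x_um / sp[["dx"]], truth$cx_px, "-")
  dz <- outer(p$centroid_z_um / sp[["dz"]], truth$cz_slice + 0.5, "-")
  D <- sqrt(dy^2 + dx^2 + dz^2)
  ok <- D <= max_dist
  md <- rep(FALSE, nrow(p))
  mt <- rep(FALSE, nrow(truth))
  idx <- which(ok, arr.ind = TRUE)
  idx <- idx[order(D[ok]), , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (!md[i] && !mt[j]) { md[i] <- TRUE; mt[j] <- TRUE }
  }
  c(recall = mean(mt), precision = mean(md))
}

# Exhaustive maximum-cardinality bipartite matching on a boolean overlap
# matrix (rows = pre, cols = post), by augmenting-path search.
bruteMaxMatching <- function(adj) {
  if (!length(adj) || !any(adj)) return(0L)
  n_post <- ncol(adj)
  match_post <- rep(0L, n_post)
  seen <- rep(FALSE, n_post)
  aug <- function(u) {
    for (j in seq_len(n_post)) {
      if (adj[u, j] && !seen[j]) {
        seen[j] <<- TRUE
        if (match_post[j] == 0L || aug(match_post[j])) {
          match_post[j] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(nrow(adj))) {
    seen <- rep(FALSE, n_post)
    if (aug(i)) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive window-enumeration oracle for the learning criterion: the
# earliest t with ANY window of length 8..10, inside one session, ending at
# t and holding >= 8 correct outcomes.
criterionOracle <- function(outcomes, sessions = rep(1L, length(outcomes))) {
  n <- length(outcomes)
  corr <- outcomes == "correct"
  for (t in seq_len(n)) {
    for (w in 8:10) {
      a <- t - w + 1L
      if (a < 1L || sessions[a] != sessions[t]) next
      if (sum(corr[a:t]) >= 8L) return(t)
    }
  }
  NA_integer_
}

# Direct, loop-based reimplementation of the univariate ROUT rank/threshold
# rule, kept deliberately naive.
routBrute <- function(values, Q = 1) {
  n <- length(values)
  med <- median(values)
  r <- abs(values - med)
  rsdr <- unname(quantile(r, 0.6827, type = 7)) * n / (n - 1)
  ord <- order(r, decreasing = TRUE)
  flag_rank <- 0L
  for (i in seq_len(n)) {
    ti <- if (rsdr > 0) r[ord[i]] / rsdr else if (r[ord[i]] > 0) Inf else 0
    pi <- 2 * pt(-ti, df = n - 1)
    if (pi < Q / 100 * (n - (i - 1)) / n) flag_rank <- i
  }
  flags <- rep(FALSE, n)
  if (flag_rank > 0L) flags <- r >= r[ord[flag_rank]] & r > 0
  flags
}

# A grid containing one isotropic Gaussian blob (single slice unless nz
# given), amplitude on top of an optional base image.
blobGrid <- function(ny = 64, nx = 64, nz = 1, cy = 32, cx = 32,
                     sigma = 2, amp = 1, base = 0) {
  arr <- array(base, dim = c(ny, nx, nz))
  yy <- matrix(seq_len(ny) - 0.5, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  blob <- amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
  for (k in seq_len(nz)) arr[, , k] <- arr[, , k] + blob
  VoxelGrid(arr)
}

# Minimal synthetic PunctaSet built directly from footprints (bypassing
# detection), for geometry-level tests.
punctaSetFromFootprints <- function(fps, dims = c(32L, 32L, 8L),
                                    spacing = c(dz = 0.3, dy = 0.06013,
                                                dx = 0.06013),
                                    channel = "pre", image_id = "fix") {
  if (!length(fps)) {
    return(new("PunctaSet", channel = channel, image_id = image_id,
               puncta = synaptoscope:::.emptyPunctaTable(),
               footprints = list(), dims = as.integer(dims),
               spacing = spacing, params = detectionParams()))
  }
  rows <- lapply(seq_along(fps), function(i) {
    fp <- fps[[i]]
    zs <- as.integer(names(fp))
    nv <- sum(lengths(fp))
    data.frame(id = i, z_min = min(zs), z_max = max(zs),
               centroid_z_um = mean(zs + 0.5) * spacing[["dz"]],
               centroid_y_um = 0.5, centroid_x_um = 0.5,
               n_voxels = nv, volume_um3 = nv * prod(spacing),
               mean_intensity = 0.5, peak_response = 1)
  })
  new("PunctaSet", channel = channel, image_id = image_id,
      puncta = do.call(rbind, rows), footprints = fps,
      dims = as.integer(dims), spacing = spacing,
      params = detectionParams())
}

# Rectangular footprint helper: pixels of rows y0..y1 x cols x0..x1 (1-based)
# as in-slice linear indices for an ny-row slice.
rectPixels <- function(y0, y1, x0, x1, ny = 32L) {
  as.integer(outer(y0:y1, (x0:x1 - 1L) * ny, "+"))
}
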