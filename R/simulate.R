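# Run code under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample a point at least min_sep (euclidean, px) from previous points,
# inside [lo, hi] in both axes; bounded retries.
.placePoint <- function(ys, xs, lo, hi, min_sep, retries = 2000L) {
  for (i in seq_len(retries)) {
    cy <- stats::runif(1, lo, hi)
    cx <- stats::runif(1, lo, hi)
    if (!length(ys) || min((ys - cy)^2 + (xs - cx)^2) >= min_sep^2)
      return(c(cy, cx))
  }
  stop("infeasible punctum placement after bounded retries; ",
       "reduce counts or min_sep")
}

# Add one Gaussian-profile punctum (triangular z-profile) to the expected-
# photon array in place (returns modified array).
.renderPunctum <- function(img, cy, cx, zc, sigma, zext, amp) {
  d <- dim(img)
  r <- ceiling(4 * sigma)
  yy <- max(1L, floor(cy - r)):min(d[1], ceiling(cy + r))
  xx <- max(1L, floor(cx - r)):min(d[2], ceiling(cx + r))
  # pixel centres at index - 0.5 in 1-based terms
  gy <- exp(-((yy - 0.5) - cy)^2 / (2 * sigma^2))
  gx <- exp(-((xx - 0.5) - cx)^2 / (2 * sigma^2))
  patch <- outer(gy, gx)
  half <- (zext + 1) / 2
  for (dz in -(zext %/% 2):(zext %/% 2)) {
    z <- zc + dz
    if (z < 1 || z > d[3]) next
    wz <- 1 - abs(dz) / half
    img[yy, xx, z] <- img[yy, xx, z] + amp * wz * patch
  }
  img
}

#' Simulate a dual-channel synaptic-puncta stack with ground truth
#'
#' Generates a two-channel confocal-like z-stack containing Gaussian-profile
#' puncta (isotropic in-plane, triangular intensity profile across the
#' punctum's z-extent) on a smooth background (constant plus linear
#' gradient), with Poisson shot noise on the expected photon counts plus
#' additive Gaussian read noise, digitized to integer counts. A fraction
#' \code{f} of the post-channel puncta is placed within \code{delta} pixels
#' (laterally, same central slice) of a pre-channel punctum and labelled as
#' a colocalized pair; all other puncta keep a minimum separation from every
#' other punctum so that the planted labels are unambiguous ground truth.
#' Deterministic given \code{seed}.
#'
#' Signal-to-noise ratio is defined as punctum peak amplitude divided by the
#' background noise standard deviation \eqn{\sqrt{b_0 + \sigma_{read}^2}};
#' \code{snr} is the minimum over planted puncta (individual amplitudes are
#' jittered upward by up to 50 percent).
#'
#' @param n_pre,n_post puncta counts per channel.
#' @param f fraction (0..1) of \code{min(n_pre, n_post)} post puncta planted
#'   as colocalized partners.
#' @param ny,nx,nz stack dimensions (pixels / slices).
#' @param dz,dy,dx voxel sizes in micrometres (defaults: 0.30 um z-step,
#'   60.13 nm pixels).
#' @param snr minimum peak signal-to-noise ratio of planted puncta.
#' @param background mean background level, counts.
#' @param gradient relative amplitude of the linear background gradient.
#' @param read_noise Gaussian read-noise standard deviation, counts.
#' @param sigma_range in-plane Gaussian sigma range, pixels.
#' @param z_extents candidate punctum z-extents, slices (odd).
#' @param delta maximum lateral centre offset of a colocalized pair, pixels.
#' @param min_sep minimum centre separation between non-paired puncta,
#'   pixels.
#' @param seed integer seed.
#' @param meta metadata list passed to [TwoChannelStack()].
#' @return list with elements \code{stack} (a [TwoChannelStack-class]) and
#'   \code{truth} (list: \code{puncta} data.frame with one row per planted
#'   punctum -- channel, id, centre in um and px, sigma, z-extent,
#'   amplitude, \code{pair_id} labelling colocalized pairs -- and
#'   \code{params}, the echoed generator parameters).
#' @examples
#' sim <- simulateStack(n_pre = 5, n_post = 5, f = 0.4, ny = 64, nx = 64,
#'                      nz = 6, seed = 1)
#' table(sim$truth$puncta$channel)
#' @export
simulateStack <- function(n_pre = 150, n_post = 150, f = 0.5,
                          ny = 256, nx = 256, nz = 15,
                          dz = 0.30, dy = 0.06013, dx = 0.06013,
                          snr = 5, background = 20, gradient = 0.3,
                          read_noise = 2,
                          sigma_range = c(1.5, 2.5), z_extents = c(3, 5),
                          delta = 2, min_sep = 8,
                          seed = 1, meta = list()) {
  stopifnot(n_pre >= 0, n_post >= 0, f >= 0, f <= 1,
            ny >= 16, nx >= 16, nz >= 3, snr > 0, background >= 0)
  n_coloc <- floor(f * min(n_pre, n_post))
  noise_sd <- sqrt(background + read_noise^2)
  amp0 <- snr * noise_sd

  .withSeed(seed, {
    margin <- 4 * max(sigma_range) + 1
    if (2 * margin >= min(ny, nx))
      stop("image too small for the requested puncta geometry")

    draw_shape <- function(n) {
      data.frame(sigma = stats::runif(n, sigma_range[1], sigma_range[2]),
                 zext = z_extents[sample.int(length(z_extents), n,
                                             replace = TRUE)],
                 amp = amp0 * stats::runif(n, 1, 1.5))
    }

    # pre-channel centres, mutually separated
    ys <- numeric(0); xs <- numeric(0); zs <- integer(0)
    for (i in seq_len(n_pre)) {
      p <- .placePoint(ys, xs, margin, min(ny, nx) - margin, min_sep)
      ys <- c(ys, p[1]); xs <- c(xs, p[2])
    }
    pre_shape <- draw_shape(n_pre)
    zs <- if (n_pre) sample(seq(2L, nz - 1L), n_pre, replace = TRUE)
          else integer(0)

    # post-channel: first n_coloc are partners of pre 1..n_coloc
    pys <- numeric(0); pxs <- numeric(0); pzs <- integer(0)
    pair_of <- rep(NA_integer_, n_post)
    if (n_coloc > 0) {
      ang <- stats::runif(n_coloc, 0, 2 * pi)
      rad <- delta * sqrt(stats::runif(n_coloc))
      pys <- ys[seq_len(n_coloc)] + rad * sin(ang)
      pxs <- xs[seq_len(n_coloc)] + rad * cos(ang)
      pzs <- zs[seq_len(n_coloc)]
      pair_of[seq_len(n_coloc)] <- seq_len(n_coloc)
    }
    # remaining post puncta keep min_sep from all pre and post centres
    for (i in seq_len(n_post - n_coloc)) {
      p <- .placePoint(c(ys, pys), c(xs, pxs),
                       margin, min(ny, nx) - margin, min_sep)
      pys <- c(pys, p[1]); pxs <- c(pxs, p[2])
    }
    if (n_post > n_coloc)
      pzs <- c(pzs, sample(seq(2L, nz - 1L), n_post - n_coloc,
                           replace = TRUE))
    post_shape <- draw_shape(n_post)

    # expected-photon images: constant + linear diagonal gradient
    ramp_y <- matrix(seq(0, 1, length.out = ny), ny, nx)
    ramp_x <- matrix(seq(0, 1, length.out = nx), ny, nx, byrow = TRUE)
    bg2d <- background * (1 + gradient * (ramp_y + ramp_x) / 2)
    mk_expected <- function(cy, cx, cz, shape) {
      img <- array(rep(bg2d, nz), dim = c(ny, nx, nz))
      for (i in seq_along(cy))
        img <- .renderPunctum(img, cy[i], cx[i], cz[i],
                              shape$sigma[i], shape$zext[i], shape$amp[i])
      img
    }
    digitize <- function(expected) {
      counts <- stats::rpois(length(expected), lambda = expected) +
        round(stats::rnorm(length(expected), 0, read_noise))
      array(pmin(pmax(counts, 0), 65535), dim = dim(expected))
    }
    pre_img <- digitize(mk_expected(ys, xs, zs, pre_shape))
    post_img <- digitize(mk_expected(pys, pxs, pzs, post_shape))

    truth <- rbind(
      if (n_pre) data.frame(
        channel = "pre", id = seq_len(n_pre),
        cz_um = (zs - 0.5) * dz, cy_um = ys * dy, cx_um = xs * dx,
        cz_slice = zs - 1L, cy_px = ys, cx_px = xs,
        sigma_px = pre_shape$sigma, z_extent = pre_shape$zext,
        amplitude = pre_shape$amp,
        pair_id = c(seq_len(n_coloc), rep(NA_integer_, n_pre - n_coloc))),
      if (n_post) data.frame(
        channel = "post", id = seq_len(n_post),
        cz_um = (pzs - 0.5) * dz, cy_um = pys * dy, cx_um = pxs * dx,
        cz_slice = pzs - 1L, cy_px = pys, cx_px = pxs,
        sigma_px = post_shape$sigma, z_extent = post_shape$zext,
        amplitude = post_shape$amp, pair_id = pair_of))

    stack <- suppressWarnings(TwoChannelStack(
      VoxelGrid(pre_img, dz = dz, dy = dy, dx = dx),
      VoxelGrid(post_img, dz = dz, dy = dy, dx = dx),
      meta = meta))
    params <- list(n_pre = n_pre, n_post = n_post, f = f,
                   n_coloc_planted = n_coloc,
                   ny = ny, nx = nx, nz = nz, dz = dz, dy = dy, dx = dx,
                   snr = snr, background = background, gradient = gradient,
                   read_noise = read_noise, sigma_range = sigma_range,
                   z_extents = z_extents, delta = delta, min_sep = min_sep,
                   seed = seed)
    list(stack = stack,
         truth = list(puncta = truth, params = params))
  })
}

#' Simulate complex-sensory-learning-task session logs with known truth
#'
#' Emits per-trial session logs for one mouse and stage under an
#' exponential learning curve: the probability of a correct closed-trial
#' choice at cumulative closed trial \eqn{t} is
#' \deqn{p_t = p_\infty - (p_\infty - p_0)\, e^{-t/\tau}.}
#' Omissions (no bowl choice within the 120 s limit) are drawn
#' independently per trial and carry no latency; choice latencies are
#' log-normal, capped at 120 s. Each session holds 4 free trials followed
#' by up to 30 closed trials; a session ends early when the learning
#' criterion (see [detectCriterion()]) is met, otherwise the mouse returns
#' for another session up to \code{max_sessions}. Deterministic given
#' \code{seed}.
#'
#' @param mouse,group,stage identifiers written into the log; stage one of
#'   \code{"SD"}, \code{"CD"}, \code{"CDR"}, \code{"IDS"}.
#' @param p0,pinf,tau learning-curve parameters: initial and asymptotic
#'   probability of a correct choice and the trial constant of approach.
#' @param p_omit per-trial omission probability.
#' @param lat_meanlog,lat_sdlog log-normal latency parameters (seconds).
#' @param max_sessions maximum daily sessions before giving up.
#' @param seed integer seed.
#' @return list with \code{log} (data.frame: mouse, group, stage, session,
#'   trial_index, trial_type, outcome, latency_s) and \code{truth} (the
#'   echoed parameters).
#' @examples
#' sim <- simulateBehavior(p0 = 1, pinf = 1, p_omit = 0, seed = 3)
#' sum(sim$log$trial_type == "closed")
#' @export
simulateBehavior <- function(mouse = "m1", group = "g1", stage = "SD",
                             p0 = 0.5, pinf = 0.95, tau = 10,
                             p_omit = 0.01,
                             lat_meanlog = log(10), lat_sdlog = 0.5,
                             max_sessions = 5, seed = 1) {
  stopifnot(p0 >= 0, p0 <= 1, pinf >= 0, pinf <= 1, tau > 0,
            p_omit >= 0, p_omit <= 1, max_sessions >= 1)
  stage <- match.arg(stage, c("SD", "CD", "CDR", "IDS"))
  .withSeed(seed, {
    rows <- list()
    t_global <- 0L
    done <- FALSE
    for (s in seq_len(max_sessions)) {
      lat_free <- pmin(stats::rlnorm(4, lat_meanlog, lat_sdlog), 120)
      omit_free <- stats::runif(4) < p_omit
      free_correct <- stats::runif(4) < p0
      rows[[length(rows) + 1L]] <- data.frame(
        mouse = mouse, group = group, stage = stage, session = s,
        trial_index = 1:4, trial_type = "free",
        outcome = ifelse(omit_free, "omission",
                         ifelse(free_correct, "correct", "incorrect")),
        latency_s = ifelse(omit_free, NA_real_, lat_free))
      outcomes <- character(0)
      for (i in 1:30) {
        t_global <- t_global + 1L
        p_t <- pinf - (pinf - p0) * exp(-t_global / tau)
        omit <- stats::runif(1) < p_omit
        out <- if (omit) "omission"
               else if (stats::runif(1) < p_t) "correct" else "incorrect"
        lat <- if (omit) NA_real_
               else pmin(stats::rlnorm(1, lat_meanlog, lat_sdlog), 120)
        outcomes <- c(outcomes, out)
        rows[[length(rows) + 1L]] <- data.frame(
          mouse = mouse, group = group, stage = stage, session = s,
          trial_index = i, trial_type = "closed",
          outcome = out, latency_s = lat)
        crit <- detectCriterion(outcomes, rep(s, length(outcomes)))
        if (!is.na(crit)) {
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    log <- do.call(rbind, rows)
    rownames(log) <- NULL
    truth <- list(mouse = mouse, group = group, stage = stage,
                  p0 = p0, pinf = pinf, tau = tau, p_omit = p_omit,
                  lat_meanlog = lat_meanlog, lat_sdlog = lat_sdlog,
                  max_sessions = max_sessions, seed = seed)
    list(log = log, truth = truth)
  })
}
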