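sp <- c(dz = 0.3, dy = 0.06013, dx = 0.06013)

test_that("pair overlap volume matches hand-counted geometry", {
  # identical punctum vs itself: its own volume exactly
  fp <- list(`2` = rectPixels(4, 6, 4, 6), `3` = rectPixels(4, 6, 4, 6))
  expect_identical(pairOverlap(fp, fp, spacing = sp), 18 * prod(sp))

  # z-disjoint ranges: overlap 0
  a <- list(`0` = rectPixels(1, 3, 1, 3), `1` = rectPixels(1, 3, 1, 3),
            `2` = rectPixels(1, 3, 1, 3))
  b <- list(`5` = rectPixels(1, 3, 1, 3), `6` = rectPixels(1, 3, 1, 3),
            `7` = rectPixels(1, 3, 1, 3))
  expect_identical(pairOverlap(a, b, spacing = sp), 0)

  # two 3x3 footprints offset by 1 px in x on 2 shared slices:
  # 6-px intersection per slice -> 12 * dx*dy*dz
  f1 <- list(`1` = rectPixels(4, 6, 4, 6), `2` = rectPixels(4, 6, 4, 6))
  f2 <- list(`1` = rectPixels(4, 6, 5, 7), `2` = rectPixels(4, 6, 5, 7))
  expect_identical(pairOverlap(f1, f2, spacing = sp), 12 * prod(sp))
})

test_that("greedy matching picks the larger overlap and stays one-to-one", {
  # one pre punctum overlapping two post puncta by 10 vs 4 pixels
  pre <- punctaSetFromFootprints(
    list(list(`2` = rectPixels(5, 9, 5, 9))), channel = "pre")
  post <- punctaSetFromFootprints(
    list(list(`2` = rectPixels(5, 9, 5, 6)),    # 10-px overlap
         list(`2` = rectPixels(5, 8, 9, 10))),  # 4-px overlap
    channel = "post")
  pairs <- matchPuncta(pre, post)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$post_id, 1L)
  expect_identical(pairs$overlap_voxels, 10L)

  # either set empty: empty result
  empty <- punctaSetFromFootprints(list(), channel = "post")
  expect_identical(nrow(matchPuncta(pre, empty)), 0L)

  # sets from different images are rejected
  other <- post
  other@image_id <- "other"
  expect_error(matchPuncta(pre, other), "different images")
})

test_that("matching respects the maximum-matching bound on random instances",
{
  set.seed(101)
  for (rep in 1:200) {
    n_a <- sample(0:6, 1)
    n_b <- sample(0:6, 1)
    mk <- function(n) {
      lapply(seq_len(n), function(i) {
        z0 <- sample(0:5, 1)
        y0 <- sample(1:26, 1); x0 <- sample(1:26, 1)
        zs <- z0:min(z0 + sample(0:2, 1), 7)
        fp <- lapply(zs, function(z) rectPixels(y0, y0 + sample(1:4, 1),
                                                x0, x0 + sample(1:4, 1)))
        names(fp) <- as.character(zs)
        fp
      })
    }
    pre <- punctaSetFromFootprints(mk(n_a), channel = "pre")
    post <- punctaSetFromFootprints(mk(n_b), channel = "post")
    pairs <- matchPuncta(pre, post)
    adj <- matrix(FALSE, n_a, n_b)
    for (i in seq_len(n_a)) for (j in seq_len(n_b))
      adj[i, j] <- pairOverlap(footprints(pre)[[i]],
                               footprints(post)[[j]], spacing = sp) > 0
    expect_lte(nrow(pairs), bruteMaxMatching(adj))
    expect_lte(nrow(pairs), min(n_a, n_b))
    # every selected pair really overlaps; selection is one-to-one
    expect_false(anyDuplicated(pairs$pre_id) > 0)
    expect_false(anyDuplicated(pairs$post_id) > 0)
    # greedy matches the maximum when the overlap graph is conflict-free
    if (all(rowSums(adj) <= 1) && all(colSums(adj) <= 1))
      expect_identical(nrow(pairs), bruteMaxMatching(adj))
  }
})

test_that("channel symmetry and dilation monotonicity hold", {
  set.seed(77)
  sim <- simulateStack(n_pre = 20, n_post = 20, f = 0.5, ny = 128,
                       nx = 128, nz = 8, seed = 55)
  pre <- detectPuncta(channelGrid(sim$stack, "pre"), detectionParams(),
                      "pre", "s")
  post <- detectPuncta(channelGrid(sim$stack, "post"), detectionParams(),
                       "post", "s")
  fwd <- matchPuncta(pre, post)
  swapped_pre <- post; swapped_pre@channel <- "pre"
  swapped_post <- pre; swapped_post@channel <- "post"
  rev <- matchPuncta(swapped_pre, swapped_post)
  expect_identical(nrow(fwd), nrow(rev))
  expect_equal(sum(fwd$overlap_volume_um3), sum(rev$overlap_volume_um3))
  expect_setequal(paste(fwd$pre_id, fwd$post_id),
                  paste(rev$post_id, rev$pre_id))

  # total matched overlap is bounded by either channel's total volume
  expect_lte(sum(fwd$overlap_volume_um3), sum(puncta(pre)$volume_um3))
  expect_lte(sum(fwd$overlap_volume_um3), sum(puncta(post)$volume_um3))

  # dilating every post footprint by 1 px never decreases total overlap
  dil <- footprints(post)
  ny <- post@dims[1]; nx <- post@dims[2]
  dilate1 <- function(pix) {
    yy <- (pix - 1L) %% ny + 1L
    xx <- (pix - 1L) %/% ny + 1L
    out <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      y2 <- yy + dy; x2 <- xx + dx
      keep <- y2 >= 1 & y2 <= ny & x2 >= 1 & x2 <= nx
      out <- c(out, (x2[keep] - 1L) * ny + y2[keep])
    }
    sort(unique(out))
  }
  for (i in seq_along(dil)) dil[[i]] <- lapply(dil[[i]], dilate1)
  post2 <- post
  post2@footprints <- dil
  nv <- vapply(dil, function(f) sum(lengths(f)), integer(1))
  post2@puncta$n_voxels <- nv
  post2@puncta$volume_um3 <- nv * prod(voxelSize(post))
  expect_gte(sum(matchPuncta(pre, post2)$overlap_volume_um3),
             sum(fwd$overlap_volume_um3))
})

test_that("image summaries count and bound correctly", {
  pre <- punctaSetFromFootprints(
    list(list(`1` = rectPixels(2, 4, 2, 4)),
         list(`3` = rectPixels(10, 12, 10, 12)),
         list(`5` = rectPixels(20, 22, 20, 22))), channel = "pre")
  post <- punctaSetFromFootprints(
    list(list(`1` = rectPixels(3, 5, 3, 5)),
         list(`6` = rectPixels(25, 27, 25, 27))), channel = "post")
  pairs <- matchPuncta(pre, post)
  s <- summarizeImage(pre, post, pairs)
  expect_identical(c(s$n_pre, s$n_post, s$n_coloc), c(3L, 2L, 1L))
  expect_lte(s$n_coloc, min(s$n_pre, s$n_post))

  empty <- punctaSetFromFootprints(list(), channel = "pre")
  empty_post <- punctaSetFromFootprints(list(), channel = "post")
  s0 <- summarizeImage(empty, empty_post,
                       matchPuncta(empty, empty_post))
  expect_identical(c(s0$n_pre, s0$n_post, s0$n_coloc), c(0L, 0L, 0L))
  expect_true(is.na(s0$mean_intensity_pre))

  bad <- pairs; bad$pre_id <- 99L
  expect_error(summarizeImage(pre, post, bad), "unknown punctum ids")
})
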