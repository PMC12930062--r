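test_that("stack write/read round-trips bit-identically with calibration", {
  set.seed(11)
  pre <- array(sample(0:500, 8 * 8 * 3, TRUE), dim = c(8, 8, 3))
  post <- array(sample(0:500, 8 * 8 * 3, TRUE), dim = c(8, 8, 3))
  stk <- suppressWarnings(TwoChannelStack(
    VoxelGrid(pre), VoxelGrid(post),
    meta = list(image_id = "t1", mouse = "m1", group = "g1", roi = "MO",
                hemisphere = "left", section = 1L)))
  path <- file.path(tempdir(), "roundtrip.tif")
  writeStack(stk, path)
  back <- readStack(path)
  expect_identical(intensities(channelGrid(back, "pre")), pre + 0)
  expect_identical(intensities(channelGrid(back, "post")), post + 0)
  expect_identical(voxelSize(back)[["dz"]], 0.30)
  expect_identical(stackMeta(back)$roi, "MO")
})

test_that("generator output survives the disk round trip bit-identically", {
  sim <- simulateStack(n_pre = 10, n_post = 10, f = 0.5, ny = 64, nx = 64,
                       nz = 5, seed = 21,
                       meta = list(image_id = "sim1", hemisphere = "left",
                                   section = 1L))
  path <- file.path(tempdir(), "sim-roundtrip.tif")
  writeStack(sim$stack, path)
  back <- readStack(path)
  expect_identical(intensities(channelGrid(back, "pre")),
                   intensities(channelGrid(sim$stack, "pre")))
  expect_identical(intensities(channelGrid(back, "post")),
                   intensities(channelGrid(sim$stack, "post")))
})

test_that("single-channel files and missing calibration are rejected", {
  path <- file.path(tempdir(), "single.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), path,
                  bits.per.sample = 16L, reduce = FALSE)
  side <- list(format = "synaptoscope-stack-v1", ny = 8, nx = 8, nz = 2,
               n_channels = 1L, page_order = "czt",
               spacing_um = list(dz = 0.3, dy = 0.06, dx = 0.06))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  expect_error(readStack(path), "two channels")

  # bare TIFF, no sidecar, no OME, no explicit spacing
  bare <- file.path(tempdir(), "bare.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), bare,
                  bits.per.sample = 16L, reduce = FALSE)
  expect_error(readStack(bare), "calibration")
  # explicit spacing rescues it
  stk <- readStack(bare, spacing = c(dz = 0.3, dy = 0.06, dx = 0.06))
  expect_identical(dim(intensities(channelGrid(stk, "pre"))),
                   c(8L, 8L, 1L))

  expect_error(readStack(file.path(tempdir(), "nope.tif")), "cannot read")
})

test_that("OME-XML voxel calibration is honored when present", {
  # simulate an externally produced OME-TIFF: pages + OME ImageDescription
  # (the tiff package cannot write description tags, so parse directly)
  ome <- paste0(
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels DimensionOrder="XYCZT" PhysicalSizeX="0.06013" ',
    'PhysicalSizeY="0.06013" PhysicalSizeZ="0.3" SizeC="2" SizeZ="3" ',
    'SizeT="1"/></Image></OME>')
  parsed <- synaptoscope:::.parseOME(ome)
  expect_equal(parsed$dx, 0.06013)
  expect_equal(parsed$dz, 0.3)
  expect_equal(parsed$size_c, 2)
  expect_identical(parsed$dimension_order, "XYCZT")
  expect_null(synaptoscope:::.parseOME("not xml"))
})

test_that("record tables round-trip losslessly including zero rows", {
  tab <- data.frame(image_id = c("a", "b"),
                    n_pre = c(1523L, 980L),
                    mean_intensity_pre = c(1 / 3, pi * 1e-7),
                    coloc_volume_total = c(0.123456789012345678, 1e308))
  path <- file.path(tempdir(), "tab.csv")
  writeRecords(tab, path)
  back <- readRecords(path)
  expect_identical(back$mean_intensity_pre, tab$mean_intensity_pre)
  expect_identical(back$coloc_volume_total, tab$coloc_volume_total)
  expect_identical(back$n_pre, tab$n_pre)

  zero <- tab[0, ]
  writeRecords(zero, path)
  lines <- readLines(path)
  expect_identical(length(lines), 1L)
  expect_identical(nrow(readRecords(path)), 0L)
})

test_that("per-image summary table has the documented schema", {
  sim <- simulateStack(n_pre = 8, n_post = 8, f = 0.5, ny = 96, nx = 96,
                       nz = 6, seed = 31)
  pre <- detectPuncta(channelGrid(sim$stack, "pre"), detectionParams(),
                      "pre", "schema")
  post <- detectPuncta(channelGrid(sim$stack, "post"), detectionParams(),
                       "post", "schema")
  s <- summarizeImage(pre, post)
  expect_identical(names(s),
                   c("image_id", "n_pre", "n_post", "n_coloc",
                     "mean_intensity_pre", "mean_intensity_post",
                     "coloc_volume_total"))
})

test_that("axis-order and calibration invariants are enforced", {
  expect_error(VoxelGrid(array(-1, dim = c(4, 4, 2))), ">= 0")
  expect_error(VoxelGrid(array(NA_real_, dim = c(4, 4, 2))), "finite")
  expect_error(VoxelGrid(array(0, dim = c(4, 4, 2)), dz = 0), "> 0")
  # permuted-axis stack (z first) fails the dual-channel validity check
  a <- VoxelGrid(array(0, dim = c(3, 8, 8)))
  b <- VoxelGrid(array(0, dim = c(8, 8, 3)))
  expect_error(suppressWarnings(TwoChannelStack(a, b)), "identical dim")
  expect_error(suppressWarnings(TwoChannelStack(
    b, VoxelGrid(array(0, dim = c(8, 8, 3)), dz = 0.5))), "voxel size")
  expect_error(suppressWarnings(TwoChannelStack(
    b, VoxelGrid(array(0, dim = c(8, 8, 3))),
    meta = list(roi = "XX"))), "MO")
  expect_warning(TwoChannelStack(b, VoxelGrid(array(0, dim = c(8, 8, 3)))),
                 "hemisphere")
})
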