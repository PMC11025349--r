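test_that("an exact-fit image yields a single tile at the origin", {
  ts <- tile_image(matrix(runif(512^2), 512, 512))
  expect_length(ts$tiles, 1)
  expect_equal(unname(ts$origins[1, ]), c(0, 0))
})

test_that("1024x1024 at defaults tiles at origins {0, 409, 512} per axis", {
  ts <- tile_image(matrix(0, 1024, 1024))
  expect_length(ts$tiles, 9)
  expect_equal(sort(unique(ts$origins[, 1])), c(0L, 409L, 512L))
  expect_equal(sort(unique(ts$origins[, 2])), c(0L, 409L, 512L))
})

test_that("small images are zero-padded into one tile", {
  img <- matrix(runif(100 * 100), 100, 100)
  ts <- tile_image(img)
  expect_length(ts$tiles, 1)
  expect_equal(dim(ts$tiles[[1]]), c(512, 512))
  expect_equal(ts$tiles[[1]][1:100, 1:100], img)
  expect_true(all(ts$tiles[[1]][101:512, ] == 0))
})

test_that("tile then stitch is the identity on arbitrary probability maps", {
  for (d in list(c(512, 512), c(700, 650), c(1024, 1024), c(90, 120))) {
    p <- matrix(runif(prod(d)), d[1], d[2])
    ts <- tile_image(p)
    expect_equal(stitch(ts, ts$tiles), p)
  }
})

test_that("stitch averages overlapping predictions", {
  cfg <- tiling_config(tile_size = 4, overlap_fraction = 0.5)
  img <- matrix(0, 4, 6)  # two tiles overlapping in columns 3:4
  ts <- tile_image(img, cfg)
  expect_length(ts$tiles, 2)
  preds <- list(matrix(0.2, 4, 4), matrix(0.8, 4, 4))
  out <- stitch(ts, preds)
  expect_equal(out[1, 1], 0.2)
  expect_equal(out[1, 6], 0.8)
  expect_equal(out[1, 3], 0.5)  # covered by both
  expect_error(stitch(ts, preds[1]), "expected")
})

test_that("every pixel is covered and interior borders are multiply covered", {
  ts <- tile_image(matrix(0, 900, 900))
  cov <- matrix(0, 900, 900)
  for (i in seq_along(ts$tiles)) {
    r <- ts$origins[i, 1]; c <- ts$origins[i, 2]
    cov[(r + 1):(r + 512), (c + 1):(c + 512)] <-
      cov[(r + 1):(r + 512), (c + 1):(c + 512)] + 1
  }
  expect_true(all(cov >= 1))
  expect_true(any(cov >= 2))
})

test_that("binarize uses a strict threshold", {
  p <- matrix(c(0.4, 0.5, 0.6, 0.9), 2, 2)
  expect_equal(binarize(p, 0.5), matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 0))
  expect_true(all(binarize(matrix(0.9, 3, 3), 0.5) == 1))
})

test_that("load_pair normalizes, binarizes and validates shapes", {
  d <- withr::local_tempdir()
  img <- matrix(128 / 255, 8, 8)
  png::writePNG(img, file.path(d, "const.png"))
  grad <- matrix(seq(0, 1, length.out = 64), 8, 8)
  png::writePNG(grad, file.path(d, "grad.png"))
  msk <- matrix(c(0, 1), 8, 8)
  png::writePNG(msk, file.path(d, "mask.png"))
  bad <- matrix(0, 4, 4)
  png::writePNG(bad, file.path(d, "bad.png"))

  const <- load_pair(file.path(d, "const.png"))
  expect_true(all(const$mammogram$image == 0))  # constant maps to zeros
  g <- load_pair(file.path(d, "grad.png"), file.path(d, "mask.png"))
  expect_equal(range(g$mammogram$image), c(0, 1))
  expect_true(all(g$mask %in% c(0, 1)))
  expect_error(load_pair(file.path(d, "grad.png"), file.path(d, "bad.png")),
               "shape")
  expect_error(load_pair(file.path(d, "missing.png")), "cannot read")
  expect_error(load_pair(file.path(d, "x.dcm")), "cannot read|DICOM")
})

test_that("phantom cohorts and specs round-trip through disk", {
  d <- withr::local_tempdir()
  coh <- generate_cohort(tiny_spec("benign"), tiny_spec("malignant"),
                         n_each = 1, seed = 2)
  labels <- write_cohort(coh, d)
  expect_equal(nrow(labels), 2)
  spec2 <- read_phantom_spec(file.path(d, "spec_benign.yaml"))
  expect_equal(spec2[names(spec2) != "background"],
               coh[[1]]$spec[names(coh[[1]]$spec) != "background"])
  p <- load_pair(file.path(d, "images", "phantom_0001.tif"),
                 file.path(d, "masks", "phantom_0001.png"))
  expect_equal(dim(p$mammogram$image), dim(coh[[1]]$image))
  expect_equal(p$mask, unname(coh[[1]]$mask))
})
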