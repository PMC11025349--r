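make_blob_pair <- function(seed = 1, size = 96, n = 4) {
  set.seed(seed)
  mask <- random_lesion_mask(size, n, seed)
  image <- matrix(runif(size^2, 0.2, 0.5), size, size)
  image[mask == 1] <- image[mask == 1] + 0.4
  list(image = pmin(image, 1), mask = mask)
}

test_that("all-probability-zero config is the identity", {
  p <- make_blob_pair()
  out <- augment(p$image, p$mask, no_aug_config(), seed = 5)
  expect_identical(out$image, p$image)
  expect_identical(out$mask, p$mask)
})

test_that("photometric ops leave the mask bitwise unchanged", {
  p <- make_blob_pair()
  cfg <- no_aug_config()
  for (op in c("gaussian_blur", "sharpen", "grayscale", "histogram")) {
    cfg2 <- cfg
    cfg2[[op]]$prob <- 1
    out <- augment(p$image, p$mask, cfg2, seed = 2)
    expect_identical(out$mask, p$mask)
    expect_false(isTRUE(all.equal(out$image, p$image)))
  }
})

test_that("a pure 90-degree rotation preserves mask topology", {
  p <- make_blob_pair(seed = 3)
  cfg <- no_aug_config()
  cfg$affine <- list(prob = 1, rotation = c(90, 90), shear = c(0, 0),
                     translate = c(0, 0))
  out <- augment(p$image, p$mask, cfg, seed = 1)
  expect_equal(max(oracle_label(out$mask)), max(oracle_label(p$mask)))
  expect_equal(sum(out$mask), sum(p$mask))  # lossless on the grid
  expect_true(all(out$mask %in% c(0, 1)))
})

test_that("augmentation is deterministic per seed and keeps masks binary", {
  p <- make_blob_pair(seed = 4)
  cfg <- aug_config()
  a <- augment(p$image, p$mask, cfg, seed = 11)
  b <- augment(p$image, p$mask, cfg, seed = 11)
  expect_identical(a, b)
  c <- augment(p$image, p$mask, cfg, seed = 12)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(c$mask %in% c(0, 1)))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_equal(dim(a$image), dim(p$image))
})

test_that("affine transform co-registers image and mask centroids", {
  size <- 96
  mask <- matrix(0L, size, size)
  mask[40:44, 20:24] <- 1L  # one square blob away from the border
  image <- matrix(0, size, size)
  image[mask == 1] <- 1
  rot <- 12; sh <- 0.05; tx <- 4; ty <- -3
  wi <- calcseg:::warp_affine(image, rot, sh, tx, ty, nearest = FALSE)
  wm <- calcseg:::warp_affine(mask, rot, sh, tx, ty, nearest = TRUE)
  cen0 <- colMeans(which(mask == 1, arr.ind = TRUE)) - 1  # 0-based
  pred <- calcseg:::affine_points(matrix(cen0, 1, 2), dim(mask),
                                  rot, sh, tx, ty)
  cen_m <- colMeans(which(wm == 1, arr.ind = TRUE)) - 1
  cen_i <- colMeans(which(wi > 0.5, arr.ind = TRUE)) - 1
  expect_lt(max(abs(pred - cen_m)), 1)
  expect_lt(max(abs(cen_i - cen_m)), 1)
})

test_that("copy_paste with ratio 0 or an empty donor changes nothing", {
  p <- make_blob_pair(seed = 6)
  empty <- list(image = p$image * 0.5, mask = p$mask * 0L)
  out <- copy_paste(p, empty, ratio = 0, seed = 1)
  expect_identical(out$mask, empty$mask)
  out2 <- copy_paste(empty, p, ratio = 1, seed = 1)
  expect_identical(out2$mask, calcseg:::as_int_mask(p$mask))
  expect_equal(out2$n_pasted, 0L)
})

test_that("copy_paste adds the selected components and conserves area", {
  donor_mask <- matrix(0L, 64, 64)
  donor_mask[5:7, 5:7] <- 1L
  donor_mask[20:21, 40:42] <- 1L
  donor_mask[50, 50] <- 1L
  donor_mask[35:39, 10:12] <- 1L
  donor <- list(image = matrix(0.9, 64, 64), mask = donor_mask)
  recipient <- list(image = matrix(0.3, 64, 64),
                    mask = matrix(0L, 64, 64))
  out <- copy_paste(donor, recipient, ratio = 1, seed = 3)
  expect_equal(out$n_pasted, 4L)
  expect_equal(max(oracle_label(out$mask)), 4)
  expect_equal(sum(out$mask), sum(donor_mask))
  # pasted image pixels carry donor intensities
  expect_true(all(out$image[out$mask == 1] == 0.9))
  # half selection pastes round(ratio * C) components
  out2 <- copy_paste(donor, recipient, ratio = 0.5, seed = 3)
  expect_equal(max(oracle_label(out2$mask)), 2)
})

test_that("copy_paste skips unplaceable components with a warning", {
  donor_mask <- matrix(1L, 20, 20)  # one giant component
  donor <- list(image = matrix(1, 20, 20), mask = donor_mask)
  recipient <- list(image = matrix(0, 20, 20),
                    mask = matrix(1L, 20, 20))  # fully occupied
  expect_warning(out <- copy_paste(donor, recipient, ratio = 1, seed = 1),
                 "skipped")
  expect_equal(out$n_pasted, 0L)
})
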