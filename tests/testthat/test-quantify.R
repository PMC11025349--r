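test_that("component labelling matches connectivity semantics", {
  m <- matrix(0L, 12, 12)
  m[2:3, 2:3] <- 1L; m[2:3, 8:9] <- 1L; m[8:9, 5:6] <- 1L
  comps <- find_components(m)
  expect_length(comps, 3)
  expect_equal(vapply(comps, `[[`, 1L, "area_px"), rep(4L, 3))
  diag2 <- matrix(0L, 5, 5)
  diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_length(find_components(diag2, 8), 1)
  expect_length(find_components(diag2, 4), 2)
  expect_length(find_components(matrix(0L, 4, 4)), 0)
})

test_that("labelling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:10) {
    m <- random_lesion_mask(64, 10, seed)
    expect_equal(length(find_components(m)), max(oracle_label(m, 8)))
    expect_equal(length(find_components(m, 4)), max(oracle_label(m, 4)))
  }
})

test_that("a 10x10 square reproduces the closed-form shape features", {
  m <- matrix(0L, 20, 20)
  m[6:15, 4:13] <- 1L
  img <- matrix(0.5, 20, 20)
  cf <- component_features(find_components(m)[[1]], img)
  expect_equal(cf$perimeter_px, 40)
  expect_equal(cf$min_rect$long, 10)
  expect_equal(cf$min_rect$short, 10)
  expect_equal(cf$aspect_ratio, 1)
  expect_equal(cf$rectangularity, 1)
  expect_equal(cf$roundness, 4 * pi * 100 / 40^2)
  expect_equal(cf$perimeter_ratio, 1)
})

test_that("a single pixel degenerates to a 1x1 rectangle", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  cf <- component_features(find_components(m)[[1]], matrix(0.3, 9, 9))
  expect_equal(cf$area_px, 1L)
  expect_equal(cf$min_rect$long, 1)
  expect_equal(cf$min_rect$short, 1)
  expect_equal(cf$aspect_ratio, 1)
  expect_equal(cf$perimeter_px, 4)
})

test_that("densities on a constant image equal that constant", {
  m <- matrix(0L, 40, 40); m[18:22, 18:22] <- 1L
  img <- matrix(0.42, 40, 40)
  cf <- component_features(find_components(m)[[1]], img)
  expect_equal(cf$mean_intensity, 0.42)
  expect_equal(cf$ring_mean_32, 0.42)
  expect_equal(cf$ring_mean_8, 0.42)
})

test_that("ring means exclude the component and respect the radius", {
  img <- matrix(0, 60, 60)
  m <- matrix(0L, 60, 60); m[30, 30] <- 1L
  img[30, 30] <- 1            # bright lesion itself
  img[30, 35] <- 0.8          # inside both rings (distance 5)
  cf <- component_features(find_components(m)[[1]], img)
  expect_lt(cf$ring_mean_8, 0.8)  # averaged with zeros, lesion excluded
  expect_gt(cf$ring_mean_8, cf$ring_mean_32)  # same mass, smaller ring
})

test_that("the dilation cluster rule matches its boundary cases", {
  mk <- function(n, spacing) {
    m <- matrix(0L, 64, 256)
    for (i in seq_len(n)) m[32, 10 + (i - 1) * spacing] <- 1L
    m
  }
  m6 <- mk(6, 10)
  cl6 <- find_clusters(m6, find_components(m6))
  expect_equal(cl6$clu_num, 1L)
  expect_equal(cl6$clu_max_num, 6L)
  m5 <- mk(5, 10)  # 5 members: not > 5, not a cluster
  cl5 <- find_clusters(m5, find_components(m5))
  expect_equal(cl5$clu_num, 0L)
  m_far <- mk(6, 40)  # spaced beyond the 16 px kernel reach
  cl_far <- find_clusters(m_far, find_components(m_far))
  expect_equal(cl_far$clu_num, 0L)
})

test_that("cluster detection equals the literal dilation oracle", {
  for (seed in 1:10) {
    m <- random_lesion_mask(96, 14, seed + 100)
    comps <- find_components(m)
    got <- find_clusters(m, comps)
    want <- oracle_clusters(m)
    expect_equal(got$clu_num, want$clu_num)
    expect_equal(got$clu_max_num, want$clu_max_num)
    got_members <- lapply(got$clusters, `[[`, "members")
    expect_setequal(lapply(got_members, sort), lapply(want$members, sort))
  }
})

test_that("cluster areas equal their dilated-domain pixel counts", {
  m <- matrix(0L, 64, 64)
  for (j in seq(10, 50, by = 8)) m[32, j] <- 1L  # 6 points, one cluster
  cl <- find_clusters(m, find_components(m))
  expect_equal(cl$clu_num, 1L)
  dil <- oracle_dilate(m, 16)
  expect_equal(cl$clu_max_area, sum(dil))
})

test_that("quantify handles empty masks and bins sizes by area", {
  fv <- quantify(matrix(0.5, 32, 32), matrix(0L, 32, 32))
  expect_equal(fv$calc_num, 0)
  expect_true(fv$empty_flag)
  expect_equal(fv$density, 0)

  m <- matrix(0L, 64, 64)
  m[2:6, 2:2] <- 1L              # area 5
  m[20:23, 20:24] <- 1L          # area 20
  m[40:44, 40:47] <- 1L          # area 40
  img <- matrix(0.5, 64, 64)
  fv2 <- quantify(img, m)
  expect_equal(fv2$calc_num, 3)
  expect_equal(fv2$size_10, 1)
  expect_equal(fv2$size_10_30, 1)
  expect_equal(fv2$size_30, 1)
  expect_equal(fv2$calc_area, 65)
})

test_that("feature triples partition the components on random phantoms", {
  for (seed in 1:10) {
    s <- generate_phantom(tiny_spec(n_micro = 10, n_macro = 3,
                                    n_clusters = 1), seed)
    fv <- quantify(s$image, s$mask)
    n <- fv$calc_num
    expect_equal(fv$size_10 + fv$size_10_30 + fv$size_30, n)
    for (trip in list(c("density_l", "density_m", "density_s"),
                      c("length_l", "length_m", "length_s"),
                      c("perimeter_s", "perimeter_m", "perimeter_l"),
                      c("round_s", "round_m", "round_l"),
                      c("long_l", "long_m", "long_s"),
                      c("rectangularity_l", "rectangularity_m",
                        "rectangularity_s"),
                      c("lenratio_l", "lenratio_m", "lenratio_s")))
      expect_equal(sum(unlist(fv[trip])), n)
    clu_members <- sum(unlist(fv[c("clu_density_l", "clu_density_m",
                                   "clu_density_s")]))
    expect_lte(clu_members, n)
    areas <- vapply(find_components(s$mask), `[[`, 1L, "area_px")
    expect_equal(fv$calc_area, sum(areas))
  }
})

test_that("count features ignore intensity rescaling, density follows it", {
  s <- generate_phantom(tiny_spec(), 77)
  fv1 <- quantify(s$image, s$mask)
  fv2 <- quantify(s$image * 0.5, s$mask)
  expect_equal(fv2$calc_num, fv1$calc_num)
  expect_equal(fv2$size_10, fv1$size_10)
  expect_equal(fv2$clu_num, fv1$clu_num)
  expect_equal(fv2$density, fv1$density * 0.5)
  expect_equal(fv2$density_32, fv1$density_32 * 0.5)
})
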