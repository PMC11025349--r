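#' Augmentation configuration for calcification tiles
#'
#' The suite is tailored to sparse bright lesions: geometric ops (scale,
#' crop, affine) are applied identically to image and mask (nearest-neighbour
#' interpolation for the mask, so it stays binary), photometric ops
#' (Gaussian blur, unsharp sharpening, gamma grayscale transform, CLAHE
#' histogram transform) touch the image only. Connected-component copy-paste
#' is configured here but applied at the dataset level (it needs a donor
#' image); see [copy_paste()].
#'
#' Each op is a list with an application probability `prob` and a parameter
#' range; `prob = 0` disables the op.
#'
#' @param scale list(prob, range): isotropic resize factor range.
#' @param crop list(prob): random crop back to the pre-scale shape (applied
#'   whenever scaling changed the shape, to keep tile dimensions fixed).
#' @param gaussian_blur list(prob, sigma): blur sigma range in px.
#' @param sharpen list(prob, amount): unsharp-mask amount range.
#' @param grayscale list(prob, gamma): gamma-correction exponent range.
#' @param affine list(prob, rotation, shear, translate): rotation in
#'   degrees, shear coefficient, translation in px (each a range).
#' @param histogram list(prob, clip, grid): CLAHE clip limit and grid size.
#' @param copy_paste list(prob, ratio): fraction of donor components pasted.
#' @return an `aug_config` list.
#' @export
aug_config <- function(scale = list(prob = 0.5, range = c(0.8, 1.25)),
                       crop = list(prob = 1),
                       gaussian_blur = list(prob = 0.3, sigma = c(0.5, 1.5)),
                       sharpen = list(prob = 0.3, amount = c(0.5, 1.5)),
                       grayscale = list(prob = 0.3, gamma = c(0.7, 1.4)),
                       affine = list(prob = 0.5, rotation = c(-15, 15),
                                     shear = c(-0.1, 0.1),
                                     translate = c(-10, 10)),
                       histogram = list(prob = 0.2, clip = 2, grid = 8),
                       copy_paste = list(prob = 0.3, ratio = c(0, 1))) {
  cfg <- list(scale = scale, crop = crop, gaussian_blur = gaussian_blur,
              sharpen = sharpen, grayscale = grayscale, affine = affine,
              histogram = histogram, copy_paste = copy_paste)
  for (op in names(cfg)) {
    p <- cfg[[op]]$prob %||% 0
    if (p < 0 || p > 1) stop("aug_config: probability for ", op,
                             " outside [0,1]")
  }
  structure(cfg, class = "aug_config")
}

#' @rdname aug_config
#' @export
no_aug_config <- function() {
  cfg <- aug_config()
  for (op in names(cfg)) cfg[[op]]$prob <- 0
  cfg
}

# forward map of 0-based (row, col) points under the augmentation affine:
# rotation (degrees, about the image centre) + shear + translation
affine_points <- function(pts, shape, rot_deg, shear, tx, ty) {
  th <- rot_deg * pi / 180
  cr <- (shape[1] - 1) / 2; cc <- (shape[2] - 1) / 2
  r <- pts[, 1] - cr; c <- pts[, 2] - cc
  # shear along the column axis, then rotate
  c2 <- c + shear * r
  r2 <- r
  rr <- cos(th) * r2 - sin(th) * c2
  cc2 <- sin(th) * r2 + cos(th) * c2
  cbind(rr + cr + ty, cc2 + cc + tx)
}

# inverse-mapped resampling shared by image (bilinear) and mask (nearest)
warp_affine <- function(x, rot_deg, shear, tx, ty, nearest = FALSE) {
  H <- nrow(x); W <- ncol(x)
  g <- as.matrix(expand.grid(r = seq_len(H) - 1, c = seq_len(W) - 1))
  th <- -rot_deg * pi / 180  # inverse rotation
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  r <- g[, 1] - cr - ty; c <- g[, 2] - cc - tx
  r2 <- cos(th) * r - sin(th) * c
  c2 <- sin(th) * r + cos(th) * c
  c2 <- c2 - shear * r2  # inverse shear
  sr <- r2 + cr; sc <- c2 + cc
  out <- numeric(H * W)
  if (nearest) {
    ir <- round(sr); ic <- round(sc)
    ok <- ir >= 0 & ir <= H - 1 & ic >= 0 & ic <= W - 1
    out[ok] <- x[cbind(ir[ok] + 1, ic[ok] + 1)]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    for (dr in 0:1) for (dc in 0:1) {
      ir <- r0 + dr; ic <- c0 + dc
      wgt <- (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc)
      ok <- ir >= 0 & ir <= H - 1 & ic >= 0 & ic <= W - 1 & wgt > 0
      out[ok] <- out[ok] + wgt[ok] * x[cbind(ir[ok] + 1, ic[ok] + 1)]
    }
  }
  matrix(out, H, W)
}

resize_pair <- function(image, mask, factor) {
  H <- max(2L, round(nrow(image) * factor))
  W <- max(2L, round(ncol(image) * factor))
  img <- as.matrix(EBImage::resize(image, w = H, h = W))
  msk <- as.matrix(EBImage::resize(mask, w = H, h = W, filter = "none"))
  list(image = img, mask = (msk > 0.5) * 1L)
}

crop_or_pad <- function(image, mask, target) {
  d <- dim(image)
  if (all(d == target)) return(list(image = image, mask = mask))
  out_i <- matrix(0, target[1], target[2])
  out_m <- matrix(0L, target[1], target[2])
  r0 <- if (d[1] > target[1]) sample.int(d[1] - target[1] + 1, 1) else 1L
  c0 <- if (d[2] > target[2]) sample.int(d[2] - target[2] + 1, 1) else 1L
  rows <- r0:min(d[1], r0 + target[1] - 1)
  cols <- c0:min(d[2], c0 + target[2] - 1)
  out_i[seq_along(rows), seq_along(cols)] <- image[rows, cols]
  out_m[seq_along(rows), seq_along(cols)] <- mask[rows, cols]
  list(image = out_i, mask = out_m)
}

#' Apply the augmentation suite to an image/mask pair
#'
#' Deterministic for a fixed seed. Scaling is applied before cropping; the
#' output always has the input shape, and the output mask is binary.
#'
#' @param image intensity matrix in \[0,1\].
#' @param mask paired binary mask.
#' @param config an [aug_config()].
#' @param seed integer seed.
#' @return list(image, mask).
#' @export
augment <- function(image, mask, config = aug_config(), seed = 1L) {
  stopifnot(all(dim(image) == dim(mask)), is_binary(mask))
  target <- dim(image)
  with_seed(seed, {
    fire <- function(op) runif(1) < (config[[op]]$prob %||% 0)
    draw <- function(rng) if (length(rng) == 2) runif(1, rng[1], rng[2]) else rng

    if (fire("scale")) {
      s <- resize_pair(image, mask, draw(config$scale$range))
      image <- s$image; mask <- s$mask
      cp <- crop_or_pad(image, mask, target)  # restore tile shape
      image <- cp$image; mask <- cp$mask
    }
    if (fire("affine")) {
      rot <- draw(config$affine$rotation)
      sh <- draw(config$affine$shear)
      tx <- draw(config$affine$translate)
      ty <- draw(config$affine$translate)
      image <- warp_affine(image, rot, sh, tx, ty, nearest = FALSE)
      mask <- warp_affine(mask, rot, sh, tx, ty, nearest = TRUE)
      mask <- (mask > 0.5) * 1L
    }
    if (fire("gaussian_blur"))
      image <- as.matrix(EBImage::gblur(image,
                                        sigma = draw(config$gaussian_blur$sigma)))
    if (fire("sharpen")) {
      amt <- draw(config$sharpen$amount)
      image <- clamp01(image + amt * (image - as.matrix(
        EBImage::gblur(image, sigma = 1))))
    }
    if (fire("grayscale"))
      image <- clamp01(image)^draw(config$grayscale$gamma)
    if (fire("histogram"))
      image <- as.matrix(EBImage::clahe(EBImage::Image(clamp01(image)),
                                        nx = config$histogram$grid,
                                        ny = config$histogram$grid,
                                        limit = config$histogram$clip))
    list(image = clamp01(image), mask = mask)
  })
}

#' Copy-paste augmentation of calcification components
#'
#' Copies a random fraction of the donor's connected calcification
#' components and pastes each (image pixels alpha-blended by its mask,
#' mask pixels set) at a uniformly random location in the recipient where
#' the component's bounding box fits and does not touch an existing mask
#' component. The number of selected components is `round(ratio * C)` for a
#' donor with `C` components.
#'
#' @param donor,recipient lists with `image` and binary `mask` of equal shape.
#' @param ratio fraction of donor components to paste, in \[0,1\].
#' @param seed integer seed.
#' @param retry placement attempts per component before skipping it with a
#'   warning.
#' @return list(image, mask, n_pasted).
#' @export
copy_paste <- function(donor, recipient, ratio, seed = 1L, retry = 100L) {
  stopifnot(ratio >= 0, ratio <= 1,
            all(dim(donor$image) == dim(recipient$image)))
  lab <- cpp_label_components(as_int_mask(donor$mask), 8L)
  C <- max(lab)
  k <- round(ratio * C)
  if (k == 0) return(list(image = recipient$image, mask = recipient$mask,
                          n_pasted = 0L))
  with_seed(seed, {
    sel <- sample.int(C, k)
    img <- recipient$image
    msk <- as_int_mask(recipient$mask)
    H <- nrow(img); W <- ncol(img)
    n_pasted <- 0L
    for (comp in sel) {
      idx <- which(lab == comp, arr.ind = TRUE)
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      bh <- r1 - r0 + 1; bw <- c1 - c0 + 1
      patch_i <- donor$image[r0:r1, c0:c1, drop = FALSE]
      patch_m <- (lab[r0:r1, c0:c1, drop = FALSE] == comp) * 1L
      # forbid touching: check against the recipient mask grown by 1 px
      grown <- cpp_dilate_ones(msk, 3L)
      placed <- FALSE
      for (t in seq_len(retry)) {
        pr <- sample.int(H - bh + 1, 1)
        pc <- sample.int(W - bw + 1, 1)
        rows <- pr:(pr + bh - 1); cols <- pc:(pc + bw - 1)
        if (sum(grown[rows, cols] * patch_m) == 0) {
          img[rows, cols] <- patch_i * patch_m +
            img[rows, cols] * (1 - patch_m)
          msk[rows, cols] <- pmax(msk[rows, cols], patch_m)
          n_pasted <- n_pasted + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed)
        warning("copy_paste: no valid placement for a component of ",
                bh, "x", bw, " px; skipped")
    }
    list(image = img, mask = msk, n_pasted = n_pasted)
  })
}

as_int_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}
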