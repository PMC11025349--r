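#' Specification of a phantom mammogram
#'
#' A phantom emulates the aspects of a mammogram that matter for
#' calcification analysis: a smooth low-frequency tissue background, sparse
#' bright lesions of two size classes (micro-calcifications, below 0.5 mm at
#' the 0.068 mm/pixel detector pitch, hence at most about 7 px across, and
#' larger macro-calcifications), optional spatial clusters of
#' micro-calcifications, optic blur and detector noise. Two generative
#' profiles ([benign_phantom_spec()] and [malignant_phantom_spec()]) encode
#' the radiological convention the downstream features target: benign
#' lesions tend to be few, large, round and scattered; malignant ones many,
#' small, irregular and clustered.
#'
#' @param image_size image side length in pixels.
#' @param pixel_pitch_mm detector pixel pitch in mm/pixel (default 0.068).
#' @param background list with `base` intensity, two-scale texture
#'   `amplitude` (length 2) and `corr_len` correlation lengths in px
#'   (length 2); the texture is the sum of Gaussian-blurred white noise at
#'   the two correlation lengths.
#' @param n_micro,n_macro number of isolated micro/macro calcifications.
#' @param micro_diameter_px,macro_diameter_px diameter ranges `c(lo, hi)` in
#'   px; the micro upper bound must respect `hi * pixel_pitch_mm <= 0.5`.
#' @param lesion_contrast additive intensity range `c(lo, hi)` in \[0,1\].
#' @param n_clusters number of seeded micro-calcification clusters.
#' @param cluster_members range `c(lo, hi)` of members per cluster.
#' @param cluster_radius_px spatial spread of a cluster around its seed.
#' @param eccentricity range of lesion axis ratios (1 = circle).
#' @param irregularity range of radial boundary perturbation (0 = smooth).
#' @param blur_sigma_px Gaussian optic blur applied to the lesion field.
#' @param noise_sd additive Gaussian noise scale.
#' @param label `"benign"` or `"malignant"`.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(image_size = 256,
                         pixel_pitch_mm = 0.068,
                         background = list(base = 0.35,
                                           amplitude = c(0.04, 0.08),
                                           corr_len = c(4, 32)),
                         n_micro = 8, n_macro = 2,
                         micro_diameter_px = c(2, 6),
                         macro_diameter_px = c(8, 16),
                         lesion_contrast = c(0.15, 0.45),
                         n_clusters = 0,
                         cluster_members = c(6, 10),
                         cluster_radius_px = 20,
                         eccentricity = c(1, 1.5),
                         irregularity = c(0, 0.2),
                         blur_sigma_px = 0.7,
                         noise_sd = 0.01,
                         label = c("benign", "malignant")) {
  label <- match.arg(label)
  spec <- list(image_size = as.integer(image_size),
               pixel_pitch_mm = pixel_pitch_mm, background = background,
               n_micro = as.integer(n_micro), n_macro = as.integer(n_macro),
               micro_diameter_px = micro_diameter_px,
               macro_diameter_px = macro_diameter_px,
               lesion_contrast = lesion_contrast,
               n_clusters = as.integer(n_clusters),
               cluster_members = as.integer(cluster_members),
               cluster_radius_px = cluster_radius_px,
               eccentricity = eccentricity, irregularity = irregularity,
               blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
               label = label)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$image_size >= 16,
            spec$n_micro >= 0, spec$n_macro >= 0, spec$n_clusters >= 0)
  rng <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng(spec$micro_diameter_px) || !rng(spec$macro_diameter_px) ||
      !rng(spec$lesion_contrast) || !rng(spec$cluster_members) ||
      !rng(spec$eccentricity) || !rng(spec$irregularity))
    stop("phantom_spec ranges must be c(lo, hi) with lo <= hi")
  if (spec$micro_diameter_px[2] * spec$pixel_pitch_mm > 0.5)
    stop("micro_diameter_px upper bound exceeds the 0.5 mm ",
         "micro-calcification definition at this pixel pitch")
  if (spec$lesion_contrast[1] < 0 || spec$lesion_contrast[2] > 1)
    stop("lesion_contrast must lie within [0, 1]")
  invisible(spec)
}

#' @rdname phantom_spec
#' @export
benign_phantom_spec <- function(image_size = 256) {
  phantom_spec(image_size = image_size,
               n_micro = 4, n_macro = 6,
               micro_diameter_px = c(3, 6),
               macro_diameter_px = c(9, 16),
               n_clusters = 0,
               eccentricity = c(1, 1.3), irregularity = c(0, 0.1),
               label = "benign")
}

#' @rdname phantom_spec
#' @export
malignant_phantom_spec <- function(image_size = 256) {
  phantom_spec(image_size = image_size,
               n_micro = 22, n_macro = 1,
               micro_diameter_px = c(2, 5),
               macro_diameter_px = c(8, 12),
               n_clusters = 3, cluster_members = c(6, 9),
               cluster_radius_px = 22,
               eccentricity = c(1.2, 2.5), irregularity = c(0.2, 0.5),
               label = "malignant")
}

# two-scale blurred white-noise tissue texture
phantom_background <- function(size, bg) {
  tex <- matrix(bg$base, size, size)
  for (k in seq_along(bg$amplitude)) {
    w <- matrix(rnorm(size * size), size, size)
    # cap so the Gaussian brush fits inside small phantoms
    s <- min(bg$corr_len[k] / 2, (size - 1) / 7)
    w <- as.matrix(EBImage::gblur(w, sigma = s))
    w <- w / max(sd(as.numeric(w)), 1e-12)
    tex <- tex + bg$amplitude[k] * w
  }
  tex
}

# anti-aliased irregular ellipse; returns local coverage patch + binary mask
render_lesion <- function(diam, ecc, irr) {
  a <- diam / 2
  b <- max(a / ecc, 0.6)
  theta <- runif(1, 0, pi)
  # radial modulation by a few random harmonics (star-shaped boundary)
  nh <- 3L
  amp <- irr * runif(nh) / seq_len(nh)
  pha <- runif(nh, 0, 2 * pi)
  r_ext <- ceiling(a * (1 + sum(amp)) + 2)
  g <- seq(-r_ext, r_ext)
  n <- length(g)
  xx <- matrix(g, n, n)
  yy <- t(xx)
  xr <- cos(theta) * xx + sin(theta) * yy
  yr <- -sin(theta) * xx + cos(theta) * yy
  phi <- atan2(yr, xr)
  mod <- 1
  for (h in seq_len(nh)) mod <- mod + amp[h] * cos((h + 1) * phi + pha[h])
  f <- sqrt((xr / a)^2 + (yr / b)^2) / pmax(mod, 0.3)
  # soft edge roughly one pixel wide, scaled so tiny lesions stay visible
  edge <- min(b, 1)
  cov <- clamp01(0.5 + (1 - f) * edge)
  list(coverage = cov, mask = (f <= 1) * 1L, radius = r_ext,
       r_eff = a * (1 + sum(amp)))
}

place_ok <- function(cy, cx, r, placed, min_gap = 1.5) {
  if (nrow(placed) == 0) return(TRUE)
  d <- sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2)
  all(d >= placed$r + r + min_gap)
}

#' Generate a phantom mammogram with ground-truth mask
#'
#' Deterministic for a fixed `(spec, seed)` pair. Lesions are placed by
#' rejection sampling (retry budget 100 per lesion) so that no two lesion
#' supports touch, which keeps the ground-truth component count equal to the
#' number of lesions placed. The binary mask records the pre-blur lesion
#' support; optic blur affects the rendered image only.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer random seed.
#' @return A `phantom_sample`: list with `image` (matrix in \[0,1\]), `mask`
#'   (binary matrix), `label`, `seed`, `truth` (per-lesion data frame with
#'   centre, diameter, type, cluster id) and `background` (the lesion-free
#'   image, for testing the lesions-are-bright invariant).
#' @export
generate_phantom <- function(spec, seed) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    n <- spec$image_size
    bg_raw <- phantom_background(n, spec$background) +
      matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
    lesion_field <- matrix(0, n, n)
    mask <- matrix(0L, n, n)
    placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    truth <- list()
    budget <- 100L

    add_lesion <- function(diam, type, cluster, center = NULL, radius = NULL) {
      les <- render_lesion(diam, runif(1, spec$eccentricity[1],
                                       spec$eccentricity[2]),
                           runif(1, spec$irregularity[1],
                                 spec$irregularity[2]))
      r <- les$radius
      for (try in seq_len(budget)) {
        if (is.null(center)) {
          cy <- runif(1, r + 1, n - r)
          cx <- runif(1, r + 1, n - r)
        } else {
          ang <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * radius
          cy <- min(max(center[1] + rad * sin(ang), r + 1), n - r)
          cx <- min(max(center[2] + rad * cos(ang), r + 1), n - r)
        }
        if (place_ok(cy, cx, les$r_eff, placed)) {
          ci <- round(cy); cj <- round(cx)
          rows <- (ci - r):(ci + r)
          cols <- (cj - r):(cj + r)
          contrast <- runif(1, spec$lesion_contrast[1],
                            spec$lesion_contrast[2])
          lesion_field[rows, cols] <<-
            lesion_field[rows, cols] + contrast * les$coverage
          mask[rows, cols] <<- pmax(mask[rows, cols], les$mask)
          placed <<- rbind(placed,
                           data.frame(cy = cy, cx = cx, r = les$r_eff))
          truth[[length(truth) + 1L]] <<-
            data.frame(cy = ci, cx = cj, diameter_px = diam, type = type,
                       cluster = cluster)
          return(TRUE)
        }
      }
      stop("generate_phantom: image_size ", n, " too small to place a ",
           type, " lesion of diameter ", round(diam, 1),
           " px within the retry budget (", budget, ")")
    }

    draw <- function(rng) runif(1, rng[1], rng[2])
    for (i in seq_len(spec$n_macro))
      add_lesion(draw(spec$macro_diameter_px), "macro", NA_integer_)
    for (i in seq_len(spec$n_micro))
      add_lesion(draw(spec$micro_diameter_px), "micro", NA_integer_)
    if (spec$n_clusters > 0) {
      for (k in seq_len(spec$n_clusters)) {
        m <- spec$cluster_radius_px + spec$micro_diameter_px[2] + 2
        seed_pt <- c(runif(1, m, n - m), runif(1, m, n - m))
        members <- sample(spec$cluster_members[1]:spec$cluster_members[2], 1)
        for (j in seq_len(members))
          add_lesion(draw(spec$micro_diameter_px), "cluster_micro", k,
                     center = seed_pt, radius = spec$cluster_radius_px)
      }
    }

    if (spec$blur_sigma_px > 0)
      lesion_field <- as.matrix(EBImage::gblur(lesion_field,
                                               sigma = spec$blur_sigma_px))
    image <- clamp01(bg_raw + pmax(lesion_field, 0))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(cy = integer(0), cx = integer(0), diameter_px = numeric(0),
                 type = character(0), cluster = integer(0))
    out <- list(image = image, mask = mask, label = spec$label,
                seed = as.integer(seed), spec = spec, truth = truth,
                background = clamp01(bg_raw))
    class(out) <- "phantom_sample"
    out
  })
}

#' Generate a labelled cohort of benign and malignant phantoms
#'
#' Produces `n_each` phantoms per label with distinct derived seeds, the
#' stand-in for a clinical case collection with pathology labels.
#'
#' @param spec_benign,spec_malignant [phantom_spec()] objects for the two
#'   profiles (defaults: [benign_phantom_spec()], [malignant_phantom_spec()]).
#' @param n_each samples per label (>= 1).
#' @param seed integer seed; each sample gets a distinct seed derived from it.
#' @return list of `2 * n_each` `phantom_sample` objects, benign first.
#' @export
generate_cohort <- function(spec_benign = benign_phantom_spec(),
                            spec_malignant = malignant_phantom_spec(),
                            n_each, seed) {
  stopifnot(n_each >= 1)
  seeds <- (as.integer(seed) + 7919L * seq_len(2L * n_each)) %% 2147483546L
  out <- vector("list", 2L * n_each)
  for (i in seq_len(n_each))
    out[[i]] <- generate_phantom(spec_benign, seeds[i])
  for (i in seq_len(n_each))
    out[[n_each + i]] <- generate_phantom(spec_malignant, seeds[n_each + i])
  out
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("phantom_sample:", nrow(x$image), "x", ncol(x$image),
      "| label:", x$label, "| lesions:", nrow(x$truth),
      "| mask px:", sum(x$mask), "\n")
  invisible(x)
}
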