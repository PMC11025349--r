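#' Cluster-detection configuration
#'
#' A calcification cluster is found by dilating the binary segmentation with
#' a `dilation_kernel_px` x `dilation_kernel_px` all-ones structuring
#' element (anchor at `floor(k/2)`), labelling the dilated connected
#' domains, and counting the original calcification components that fall in
#' each domain: a domain with strictly more than `min_members` components is
#' a cluster.
#'
#' @param dilation_kernel_px kernel side in px (default 16).
#' @param min_members cluster iff members > `min_members` (default 5).
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(dilation_kernel_px = 16, min_members = 5) {
  stopifnot(dilation_kernel_px >= 1, min_members >= 0)
  structure(list(dilation_kernel_px = as.integer(dilation_kernel_px),
                 min_members = as.integer(min_members)),
            class = "cluster_config")
}

#' Category cut points for the relative (_l/_m/_s) feature triples
#'
#' Fixed configuration defaults (not per-image quantiles), so features are
#' comparable across images: a component is `s` below the low cut, `m`
#' between the cuts, `l` at or above the high cut. Units: intensities in
#' \[0,1\] for density, pixels for perimeter and long side, dimensionless
#' ratios otherwise.
#'
#' @param density,aspect,perimeter,roundness,long,rectangularity,
#'   perimeter_ratio two cut points `c(lo, hi)` each, `lo < hi`.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(density = c(0.50, 0.65),
                             aspect = c(1.3, 1.8),
                             perimeter = c(14, 32),
                             roundness = c(0.45, 0.62),
                             long = c(5, 9),
                             rectangularity = c(0.55, 0.70),
                             perimeter_ratio = c(1.02, 1.18)) {
  cuts <- list(density = density, aspect = aspect, perimeter = perimeter,
               roundness = roundness, long = long,
               rectangularity = rectangularity,
               perimeter_ratio = perimeter_ratio)
  for (nm in names(cuts))
    if (length(cuts[[nm]]) != 2 || cuts[[nm]][1] >= cuts[[nm]][2])
      stop("threshold_config: ", nm, " cuts must be c(lo, hi), lo < hi")
  structure(cuts, class = "threshold_config")
}

#' Find connected calcification components in a binary mask
#'
#' 8-connected labelling by default; components are ordered by their
#' top-left-most pixel in row-major order, so the result is deterministic.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return list of components, each a list with `pixels` (2-column index
#'   matrix), `area_px` and the mask `shape`; empty mask gives an empty
#'   list.
#' @export
find_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8), is_binary(mask))
  lab <- cpp_label_components(as_int_mask(mask), as.integer(connectivity))
  k <- max(lab)
  if (k == 0) return(list())
  lapply(seq_len(k), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    list(pixels = px, area_px = nrow(px), shape = dim(mask), label = l)
  })
}

# minimum-area enclosing rectangle by rotating calipers over the convex
# hull of the pixel corner points (each pixel treated as a unit square)
min_area_rect <- function(pixels) {
  r <- pixels[, 1]; c <- pixels[, 2]
  pts <- unique(rbind(cbind(r - 0.5, c - 0.5), cbind(r - 0.5, c + 0.5),
                      cbind(r + 0.5, c - 0.5), cbind(r + 0.5, c + 0.5)))
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 1) return(list(long = 1, short = 1, angle = 0))
  best <- list(area = Inf, long = NA, short = NA, angle = NA)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    if (du * dv < best$area)
      best <- list(area = du * dv, long = max(du, dv), short = min(du, dv),
                   angle = atan2(u[1], u[2]))
  }
  best[c("long", "short", "angle")]
}

#' Compute the shape and density features of one calcification component
#'
#' Perimeter is the crack-edge boundary length of the pixel region (each
#' pixel a unit square; a 10x10 square has perimeter 40). The minimum-area
#' enclosing rectangle is fitted to the pixel corner points, so a single
#' pixel is a 1x1 rectangle. Ring densities are the mean image intensity
#' over the 32 px and 8 px neighbourhoods of the component (Euclidean
#' distance, i.e. disk dilation) excluding the component's own pixels.
#'
#' @param component an element of [find_components()] output.
#' @param image intensity matrix the mask was segmented from.
#' @return the component with added fields: `perimeter_px`,
#'   `mean_intensity`, `ring_mean_32`, `ring_mean_8`, `min_rect`
#'   (long/short/angle), `roundness`, `rectangularity`, `aspect_ratio`,
#'   `perimeter_ratio`, `clipped` (TRUE if a ratio was clipped to 1).
#' @export
component_features <- function(component, image) {
  px <- component$pixels
  shape <- component$shape
  stopifnot(all(px[, 1] >= 1 & px[, 1] <= shape[1]),
            all(px[, 2] >= 1 & px[, 2] <= shape[2]))
  area <- component$area_px
  # local patch with 1-px margin for the crack perimeter
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  patch <- matrix(0L, r1 - r0 + 3, c1 - c0 + 3)
  patch[cbind(px[, 1] - r0 + 2, px[, 2] - c0 + 2)] <- 1L
  perim <- as.numeric(cpp_crack_perimeter(patch, 1L))
  mr <- min_area_rect(px)
  mean_int <- mean(image[px])
  rings <- ring_means(px, shape, image, c(32, 8))
  clipped <- FALSE
  clipratio <- function(x) {
    if (x > 1) { clipped <<- TRUE; pmin(x, 1) } else x
  }
  roundness <- clipratio(4 * pi * area / perim^2)
  rectangularity <- clipratio(area / (mr$long * mr$short))
  c(component,
    list(perimeter_px = perim, mean_intensity = mean_int,
         ring_mean_32 = rings[1], ring_mean_8 = rings[2], min_rect = mr,
         roundness = roundness, rectangularity = rectangularity,
         aspect_ratio = mr$long / mr$short,
         perimeter_ratio = perim / (2 * (mr$long + mr$short)),
         clipped = clipped))
}

# mean intensity over {0 < dist-to-component <= r} for each radius r
ring_means <- function(px, shape, image, radii) {
  rmax <- max(radii)
  r0 <- max(1, min(px[, 1]) - rmax - 1)
  r1 <- min(shape[1], max(px[, 1]) + rmax + 1)
  c0 <- max(1, min(px[, 2]) - rmax - 1)
  c1 <- min(shape[2], max(px[, 2]) + rmax + 1)
  sub <- matrix(0L, r1 - r0 + 1, c1 - c0 + 1)
  sub[cbind(px[, 1] - r0 + 1, px[, 2] - c0 + 1)] <- 1L
  d <- as.matrix(EBImage::distmap(1 - sub))
  img <- image[r0:r1, c0:c1, drop = FALSE]
  vapply(radii, function(r) {
    ring <- d > 0 & d <= r
    if (!any(ring)) return(mean(img))  # pathological: component fills patch
    mean(img[ring])
  }, numeric(1))
}

#' Detect calcification clusters by morphological dilation
#'
#' Implements the all-ones dilation rule described in [cluster_config()].
#'
#' @param mask binary mask the components came from.
#' @param components output of [find_components()] on `mask`.
#' @param config a [cluster_config()].
#' @return list with `clusters` (each: `members` = component indices,
#'   `area` = dilated-domain pixel count), `clu_num`, `clu_max_num`,
#'   `clu_max_area`.
#' @export
find_clusters <- function(mask, components, config = cluster_config()) {
  if (!length(components))
    return(list(clusters = list(), clu_num = 0L, clu_max_num = 0L,
                clu_max_area = 0))
  dil <- cpp_dilate_ones(as_int_mask(mask), config$dilation_kernel_px)
  dlab <- cpp_label_components(dil, 8L)
  dom <- vapply(components, function(cmp)
    dlab[cmp$pixels[1, 1], cmp$pixels[1, 2]], integer(1))
  clusters <- list()
  for (d in unique(dom)) {
    members <- which(dom == d)
    if (length(members) > config$min_members)
      clusters[[length(clusters) + 1L]] <-
        list(members = members, area = sum(dlab == d))
  }
  list(clusters = clusters,
       clu_num = length(clusters),
       clu_max_num = if (length(clusters))
         max(vapply(clusters, function(cl) length(cl$members), integer(1)))
         else 0L,
       clu_max_area = if (length(clusters))
         max(vapply(clusters, function(cl) cl$area, numeric(1))) else 0)
}

lms_counts <- function(values, cuts) {
  s <- sum(values < cuts[1])
  m <- sum(values >= cuts[1] & values < cuts[2])
  l <- sum(values >= cuts[2])
  c(l = l, m = m, s = s)
}

#' Quantify the calcification features of a segmented mammogram
#'
#' Assembles the per-image feature vector: component count, mean lesion
#' density and surround densities, area-based size bins (area < 10 px,
#' 10-30 px, > 30 px), total calcified area, cluster statistics from
#' [find_clusters()], and the relative-category (_l/_m/_s) counts for
#' density, aspect ratio, perimeter, roundness, long side, rectangularity
#' and perimeter ratio. An empty mask yields all counts 0, densities 0 and
#' `empty_flag = TRUE`.
#'
#' @param image intensity matrix in \[0,1\].
#' @param mask paired binary segmentation mask.
#' @param thresholds a [threshold_config()].
#' @param cluster_cfg a [cluster_config()].
#' @param label optional `"benign"`/`"malignant"` label carried through.
#' @return one-row data frame with the feature columns.
#' @export
quantify <- function(image, mask, thresholds = threshold_config(),
                     cluster_cfg = cluster_config(),
                     label = "unknown") {
  stopifnot(all(dim(image) == dim(mask)))
  comps <- find_components(mask)
  n <- length(comps)
  if (n == 0) {
    fv <- empty_feature_row()
    fv$label <- label
    return(fv)
  }
  comps <- lapply(comps, component_features, image = image)
  g <- function(f) vapply(comps, function(cmp) cmp[[f]], numeric(1))
  areas <- g("area_px")
  dens <- g("mean_intensity")
  longs <- vapply(comps, function(cmp) cmp$min_rect$long, numeric(1))
  cl <- find_clusters(mask, comps, cluster_cfg)
  member_idx <- unique(unlist(lapply(cl$clusters, `[[`, "members")))
  clu_dens <- if (length(member_idx)) dens[member_idx] else numeric(0)

  dens_lms <- lms_counts(dens, thresholds$density)
  len_lms <- lms_counts(g("aspect_ratio"), thresholds$aspect)
  per_lms <- lms_counts(g("perimeter_px"), thresholds$perimeter)
  rnd_lms <- lms_counts(g("roundness"), thresholds$roundness)
  long_lms <- lms_counts(longs, thresholds$long)
  rect_lms <- lms_counts(g("rectangularity"), thresholds$rectangularity)
  lr_lms <- lms_counts(g("perimeter_ratio"), thresholds$perimeter_ratio)
  cd_lms <- lms_counts(clu_dens, thresholds$density)

  fv <- data.frame(
    label = label,
    calc_num = n,
    density = mean(dens),
    density_32 = mean(g("ring_mean_32")),
    density_8 = mean(g("ring_mean_8")),
    size_10 = sum(areas < 10),
    size_10_30 = sum(areas >= 10 & areas <= 30),
    size_30 = sum(areas > 30),
    calc_area = sum(areas),
    density_l = dens_lms["l"], density_m = dens_lms["m"],
    density_s = dens_lms["s"],
    length_l = len_lms["l"], length_m = len_lms["m"],
    length_s = len_lms["s"],
    clu_num = cl$clu_num, clu_max_num = cl$clu_max_num,
    clu_max_area = cl$clu_max_area,
    clu_density_l = cd_lms["l"], clu_density_m = cd_lms["m"],
    clu_density_s = cd_lms["s"],
    perimeter_s = per_lms["s"], perimeter_m = per_lms["m"],
    perimeter_l = per_lms["l"],
    round_s = rnd_lms["s"], round_m = rnd_lms["m"], round_l = rnd_lms["l"],
    long_l = long_lms["l"], long_m = long_lms["m"], long_s = long_lms["s"],
    rectangularity_l = rect_lms["l"], rectangularity_m = rect_lms["m"],
    rectangularity_s = rect_lms["s"],
    lenratio_l = lr_lms["l"], lenratio_m = lr_lms["m"],
    lenratio_s = lr_lms["s"],
    empty_flag = FALSE,
    row.names = NULL)
  fv[] <- lapply(fv, unname)
  fv
}

empty_feature_row <- function() {
  fv <- quantify_template
  fv
}

quantify_template <- local({
  cols <- c("label", "calc_num", "density", "density_32", "density_8",
            "size_10", "size_10_30", "size_30", "calc_area",
            "density_l", "density_m", "density_s",
            "length_l", "length_m", "length_s",
            "clu_num", "clu_max_num", "clu_max_area",
            "clu_density_l", "clu_density_m", "clu_density_s",
            "perimeter_s", "perimeter_m", "perimeter_l",
            "round_s", "round_m", "round_l",
            "long_l", "long_m", "long_s",
            "rectangularity_l", "rectangularity_m", "rectangularity_s",
            "lenratio_l", "lenratio_m", "lenratio_s", "empty_flag")
  df <- as.data.frame(as.list(setNames(rep(0, length(cols)), cols)))
  df$label <- "unknown"
  df$empty_flag <- TRUE
  df
})

#' Build a feature table for a cohort of samples
#'
#' @param samples list of `phantom_sample`s (or lists with `image`, `mask`,
#'   optionally `label`).
#' @param thresholds,cluster_cfg see [quantify()].
#' @param masks optional list of predicted masks to quantify instead of the
#'   samples' own (ground-truth) masks.
#' @return data frame, one row per sample, with `id` and the feature
#'   columns.
#' @export
cohort_features <- function(samples, thresholds = threshold_config(),
                            cluster_cfg = cluster_config(), masks = NULL) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    m <- if (is.null(masks)) s$mask else masks[[i]]
    fv <- quantify(s$image, m, thresholds, cluster_cfg,
                   label = s$label %||% "unknown")
    cbind(data.frame(id = sprintf("sample_%04d", i)), fv)
  })
  do.call(rbind, rows)
}
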