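#' Overlapping-tile configuration
#'
#' Large mammograms are processed as overlapping square crops: 512x512 tiles
#' with a 20% overlap between neighbouring crops, so stride =
#' floor(tile_size * (1 - overlap_fraction)) = 409 at the defaults.
#'
#' @param tile_size tile side in pixels (default 512).
#' @param overlap_fraction overlap between neighbouring tiles, in \[0,1).
#' @return a `tiling_config` list.
#' @export
tiling_config <- function(tile_size = 512, overlap_fraction = 0.20) {
  stopifnot(tile_size >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  stride <- max(1L, as.integer(floor(tile_size * (1 - overlap_fraction))))
  structure(list(tile_size = as.integer(tile_size),
                 overlap_fraction = overlap_fraction, stride = stride),
            class = "tiling_config")
}

tile_origins_1d <- function(dim, tile, stride) {
  if (dim <= tile) return(0L)
  o <- seq(0L, dim - tile, by = stride)
  if (tail(o, 1) != dim - tile) o <- c(o, dim - tile)  # flush final tile
  o
}

#' Crop an image into overlapping tiles
#'
#' Tile origins along each axis are 0, stride, 2*stride, ... with the final
#' origin clamped flush to `dim - tile_size` so no margin is left
#' unsegmented. Images smaller than the tile are zero-padded into a single
#' tile.
#'
#' @param image 2-D matrix.
#' @param config a [tiling_config()].
#' @return a `tile_set`: list with `tiles` (list of tile_size^2 matrices),
#'   `origins` (matrix of 0-based (row, col) top-left corners) and
#'   `source_shape`.
#' @export
tile_image <- function(image, config = tiling_config()) {
  ts <- config$tile_size
  d <- dim(image)
  padded <- image
  if (any(d < ts)) {
    padded <- matrix(0, max(d[1], ts), max(d[2], ts))
    padded[seq_len(d[1]), seq_len(d[2])] <- image
  }
  pr <- tile_origins_1d(nrow(padded), ts, config$stride)
  pc <- tile_origins_1d(ncol(padded), ts, config$stride)
  origins <- as.matrix(expand.grid(row = pr, col = pc))
  tiles <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; c <- origins[i, 2]
    padded[(r + 1):(r + ts), (c + 1):(c + ts)]
  })
  structure(list(tiles = tiles, origins = origins, source_shape = d,
                 tile_size = ts), class = "tile_set")
}

#' Stitch per-tile predictions into a full-size probability map
#'
#' Each output pixel is the arithmetic mean of all tile predictions covering
#' it; zero-padded regions outside the source are discarded.
#'
#' @param tileset a `tile_set` from [tile_image()].
#' @param tile_preds list of per-tile prediction matrices in \[0,1\], one per
#'   tile, each `tile_size` square.
#' @return probability matrix of the source shape.
#' @export
stitch <- function(tileset, tile_preds) {
  ts <- tileset$tile_size
  if (length(tile_preds) != length(tileset$tiles))
    stop("stitch: expected ", length(tileset$tiles), " tile predictions, got ",
         length(tile_preds))
  d <- tileset$source_shape
  H <- max(d[1], ts); W <- max(d[2], ts)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(tile_preds)) {
    p <- tile_preds[[i]]
    if (!all(dim(p) == c(ts, ts)))
      stop("stitch: tile prediction ", i, " is not ", ts, "x", ts)
    r <- tileset$origins[i, 1]; c <- tileset$origins[i, 2]
    rows <- (r + 1):(r + ts); cols <- (c + 1):(c + ts)
    acc[rows, cols] <- acc[rows, cols] + p
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  (acc / cnt)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Threshold a probability map into a binary mask
#'
#' Strict inequality: a pixel exactly at the threshold is background.
#'
#' @param probs probability matrix in \[0,1\].
#' @param threshold decision threshold in (0,1), default 0.5.
#' @return binary matrix.
#' @export
binarize <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (probs > threshold) * 1L
}
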