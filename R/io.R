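#' Load a mammogram image and optional paired calcification mask
#'
#' Reads PNG or TIFF, converts to a grayscale matrix and min-max normalizes
#' to \[0,1\] per image (a constant image maps to all zeros). The mask, if
#' given, is binarized at > 0 and must match the image shape.
#'
#' @param image_path path to a PNG/TIFF grayscale image.
#' @param mask_path optional path to a paired binary mask (PNG/TIFF,
#'   typically 0/255).
#' @param pixel_pitch_mm detector pitch recorded on the returned object.
#' @param id identifier; defaults to the file name without extension.
#' @return list with `mammogram` (list: `image`, `pixel_pitch_mm`, `id`) and
#'   `mask` (binary matrix or NULL).
#' @export
load_pair <- function(image_path, mask_path = NULL, pixel_pitch_mm = 0.068,
                      id = NULL) {
  img <- read_gray(image_path)
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, nrow(img), ncol(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- read_gray(mask_path)
    if (!all(dim(mask) == dim(img)))
      stop("load_pair: mask shape (", paste(dim(mask), collapse = "x"),
           ") does not match image shape (", paste(dim(img), collapse = "x"),
           ")")
    mask <- (mask > 0) * 1L
  }
  mam <- list(image = img, pixel_pitch_mm = pixel_pitch_mm,
              id = id %||% sub("\\.[^.]+$", "", basename(image_path)))
  list(mammogram = mam, mask = mask)
}

read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    dcm = , dicom = stop("DICOM input is not supported; convert to ",
                         "PNG or TIFF first"),
    stop("unsupported image format: .", ext))
  if (length(dim(x)) == 3) x <- x[, , 1]  # drop colour/alpha channels
  as.matrix(x)
}

#' Write a binary mask as an 8-bit PNG with values {0, 255}
#' @param mask binary matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is_binary(mask))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write an intensity image in \[0,1\] as a 16-bit grayscale TIFF
#' @param image matrix in \[0,1\].
#' @param path output path.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(clamp01(image), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read or write a phantom specification as YAML
#'
#' @param path YAML file path.
#' @return `read_phantom_spec` returns a validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(phantom_spec, v)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Write a cohort of phantoms to disk
#'
#' Lays out `images/*.tif` (16-bit), `masks/*.png` (0/255), `labels.csv`
#' (id, label, seed) and per-profile `spec_<label>.yaml` copies under
#' `out_dir`.
#'
#' @param samples list of `phantom_sample` objects.
#' @param out_dir output directory (created if needed).
#' @return the labels data frame, invisibly.
#' @export
write_cohort <- function(samples, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  labels <- data.frame(id = character(0), label = character(0),
                       seed = integer(0))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- sprintf("phantom_%04d", i)
    write_image_tiff(s$image, file.path(out_dir, "images",
                                        paste0(id, ".tif")))
    write_mask_png(s$mask, file.path(out_dir, "masks", paste0(id, ".png")))
    labels <- rbind(labels,
                    data.frame(id = id, label = s$label, seed = s$seed))
  }
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  for (lab in unique(labels$label)) {
    i <- match(lab, labels$label)
    write_phantom_spec(samples[[i]]$spec,
                       file.path(out_dir, paste0("spec_", lab, ".yaml")))
  }
  invisible(labels)
}
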