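#' En face slab image
#'
#' Container for a grayscale en face image of the top-25% slab of
#' Haller's layer. Pixels are stored as a numeric matrix on the 0-255
#' scale, row 1 being the superior edge of the scan. The physical pixel
#' pitch defaults to 7/512 mm, the pitch of a 7 x 7 mm scan rendered as
#' a 512 x 512 bitmap.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size_mm edge length of one pixel in mm (> 0).
#' @param eye_side `"OD"` (right) or `"OS"` (left). Left-eye images are
#'   mirrored by [normalize_laterality()] before anatomical angle
#'   classification so that increasing column is always temporal.
#' @param fovea integer `c(row, col)` position of the fovea; defaults to
#'   the image center (macula-centered scans).
#' @param cct_um optional central choroidal thickness in micrometres.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, pixel_size_mm = 7 / 512, eye_side = c("OD", "OS"),
                         fovea = NULL, cct_um = NULL) {
  eye_side <- match.arg(eye_side)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a single positive number", call. = FALSE)
  if (is.null(fovea)) {
    fovea <- c(ceiling(nrow(pixels) / 2), ceiling(ncol(pixels) / 2))
  }
  fovea <- as.integer(round(fovea))
  if (length(fovea) != 2L || fovea[1] < 1L || fovea[2] < 1L ||
      fovea[1] > nrow(pixels) || fovea[2] > ncol(pixels))
    stop("`fovea` must be c(row, col) inside the image", call. = FALSE)
  if (!is.null(cct_um) && (!is.numeric(cct_um) || cct_um <= 0))
    stop("`cct_um` must be positive if given", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size_mm = pixel_size_mm, eye_side = eye_side,
         fovea = fovea, cct_um = cct_um),
    class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.4f mm/px (%.1f x %.1f mm), eye %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              nrow(x$pixels) * x$pixel_size_mm, ncol(x$pixels) * x$pixel_size_mm,
              x$eye_side))
  invisible(x)
}

#' Binary vessel mask
#'
#' A binary raster marking the segmented dark vessel phase (1 = vessel).
#' Shares dimensions and pixel pitch with its source image.
#'
#' @param pixels matrix of 0/1 values.
#' @param pixel_size_mm pixel pitch in mm.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(pixels, pixel_size_mm = 7 / 512) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || !all(pixels %in% c(0L, 1L)))
    stop("mask values must be 0 or 1", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be positive", call. = FALSE)
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d foreground (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

new_skeleton <- function(pixels, pixel_size_mm) {
  out <- vessel_mask(pixels, pixel_size_mm)
  class(out) <- c("vessel_skeleton", class(out))
  out
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d x %d px, %d centerline pixels\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Read an en face slab image from PNG or TIFF
#'
#' Reads an 8-bit grayscale PNG or TIFF raster and, when present, a JSON
#' sidecar `<path>.json` carrying `eye_side`, `pixel_size_mm`, `cct_um`,
#' `fovea_row`/`fovea_col`, `group` and `id`. Explicit arguments override
#' sidecar values.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param eye_side,pixel_size_mm,fovea,cct_um see [enface_image()];
#'   `NULL` means "take from sidecar, else default".
#' @return An `enface_image`; sidecar `group`/`id` are attached as
#'   attributes `group` and `id`.
#' @export
read_enface <- function(path, eye_side = NULL, pixel_size_mm = NULL,
                        fovea = NULL, cct_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # grayscale written as RGB
  pixels <- round(arr * 255)
  side <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) side <- jsonlite::fromJSON(sidecar)
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(side[[key]])) side[[key]] else default
  }
  if (is.null(fovea) && !is.null(side$fovea_row) && !is.null(side$fovea_col))
    fovea <- c(side$fovea_row, side$fovea_col)
  img <- enface_image(
    pixels,
    pixel_size_mm = pick(pixel_size_mm, "pixel_size_mm", 7 / 512),
    eye_side = pick(eye_side, "eye_side", "OD"),
    fovea = fovea,
    cct_um = pick(cct_um, "cct_um", NULL))
  attr(img, "group") <- pick(NULL, "group", NA_character_)
  attr(img, "id") <- pick(NULL, "id", tools::file_path_sans_ext(basename(path)))
  img
}

#' Write an en face image (and optional metadata sidecar) to PNG
#'
#' @param image an `enface_image`.
#' @param path output `.png` path.
#' @param sidecar write `<path>.json` with eye side, pixel pitch, fovea
#'   and CCT? Default `TRUE`.
#' @param extra named list merged into the sidecar (e.g. `group`, `id`).
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path, sidecar = TRUE, extra = list()) {
  stopifnot(inherits(image, "enface_image"))
  png::writePNG(image$pixels / 255, path)
  if (sidecar) {
    meta <- c(list(eye_side = image$eye_side,
                   pixel_size_mm = image$pixel_size_mm,
                   fovea_row = image$fovea[1], fovea_col = image$fovea[2]),
              if (!is.null(image$cct_um)) list(cct_um = image$cct_um),
              extra)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Mirror left-eye rasters into the right-eye anatomical frame
#'
#' Vortex-vein directions ("upper temporal", "lower temporal") are
#' anatomical, not raster, directions. Right-eye (OD) images already have
#' temporal on the increasing-column side under this package's
#' convention; left-eye (OS) images are mirrored horizontally so the same
#' angular bands apply to both eyes. Applying the function twice to an OS
#' raster is the identity.
#'
#' @param x an `enface_image`, `vessel_mask` or `vessel_skeleton`.
#' @param eye_side `"OD"` (returned unchanged) or `"OS"` (mirrored);
#'   defaults to the image's own `eye_side` field when `x` is an
#'   `enface_image`.
#' @return Object of the same class in the laterality-normalized frame.
#' @export
normalize_laterality <- function(x, eye_side = NULL) {
  if (is.null(eye_side)) {
    if (inherits(x, "enface_image")) eye_side <- x$eye_side
    else stop("`eye_side` is required for masks and skeletons", call. = FALSE)
  }
  if (!eye_side %in% c("OD", "OS"))
    stop("`eye_side` must be \"OD\" or \"OS\"", call. = FALSE)
  if (eye_side == "OD") return(x)
  x$pixels <- x$pixels[, rev(seq_len(ncol(x$pixels))), drop = FALSE]
  if (inherits(x, "enface_image")) {
    x$fovea[2] <- ncol(x$pixels) + 1L - x$fovea[2]
    x$eye_side <- "OD"  # now in the canonical frame
  }
  x
}
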