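#' Fundus image container
#'
#' Wraps a colour fundus photograph as an H x W x 3 numeric array with
#' intensities in \[0, 1\]. The package-wide pixel convention is `(row, col)`,
#' 1-based, row 1 at the top of the image; channel 1 is red.
#'
#' @param pixels H x W x 3 numeric array, values in \[0, 1\].
#' @param source_id Character identifier for provenance (e.g. file name).
#' @param resized Logical, whether the image has been through
#'   [standardize_fundus()].
#'
#' @return An object of class `fundus_image`.
#' @seealso [read_fundus()], [standardize_fundus()]
#' @export
fundus_image <- function(pixels, source_id = "image", resized = FALSE) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels, source_id = as.character(source_id),
         resized = isTRUE(resized)),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %s: %d x %d px, 3 channels%s\n",
              x$source_id, d[1], d[2],
              if (x$resized) " (standardized)" else ""))
  invisible(x)
}

#' Read a fundus photograph from disk
#'
#' Reads PNG, TIFF or JPEG via EBImage and returns a [fundus_image()] with
#' intensities rescaled to \[0, 1\]. Greyscale files are refused: the method
#' requires the red channel of a colour image.
#'
#' @param path Path to the image file.
#' @param source_id Identifier; defaults to the file name.
#' @return A `fundus_image`.
#' @export
read_fundus <- function(path, source_id = basename(path)) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) != 3L || dim(dat)[3] < 3L) {
    stop("expected a 3-channel colour image: ", path, call. = FALSE)
  }
  # EBImage stores (x, y, channel); convert to (row, col, channel)
  px <- aperm(dat[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  px <- pmin(pmax(px, 0), 1)
  fundus_image(px, source_id = source_id, resized = FALSE)
}

#' Standardize fundus geometry
#'
#' Resizes a fundus image to the working resolution of 960 x 1440 pixels
#' (height x width) by bilinear interpolation. Images already at that size are
#' returned unchanged, so the operation is idempotent.
#'
#' @param image A [fundus_image()].
#' @return A `fundus_image` with `resized = TRUE`, 960 rows x 1440 columns.
#' @export
standardize_fundus <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  d <- dim(image$pixels)
  if (d[1] == 960L && d[2] == 1440L) {
    image$resized <- TRUE
    return(image)
  }
  ebi <- EBImage::Image(aperm(image$pixels, c(2L, 1L, 3L)), colormode = "Color")
  out <- EBImage::resize(ebi, w = 1440L, h = 960L, filter = "bilinear")
  px <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  px <- pmin(pmax(px, 0), 1)
  fundus_image(px, source_id = image$source_id, resized = TRUE)
}

#' Extract the red channel
#'
#' The optic disc has the highest contrast against the background in the red
#' channel, so all downstream analysis runs on the red plane.
#'
#' @param image A [fundus_image()].
#' @return H x W numeric matrix (the red plane, values unchanged).
#' @export
red_channel <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  image$pixels[, , 1L]
}

#' Disc annotation
#'
#' Ground-truth optic-disc centre and radius in standardized image
#' coordinates (`(row, col)`, 1-based).
#'
#' @param center Numeric length-2 `(row, col)`.
#' @param radius Disc radius in pixels; must be positive.
#' @return An object of class `disc_annotation`.
#' @export
disc_annotation <- function(center, radius) {
  stopifnot(length(center) == 2L, is.finite(radius), radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "disc_annotation")
}

#' Read disc annotations from CSV
#'
#' Expects a header row with columns `source_id, center_row, center_col,
#' radius`; coordinates are `(row, col)`, 1-based, in standardized
#' (960 x 1440) image space.
#'
#' @param path CSV file path.
#' @return A tibble with one row per annotated image.
#' @export
read_disc_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "center_row", "center_col", "radius")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$radius <= 0)) stop("annotation radius must be > 0", call. = FALSE)
  tibble::as_tibble(df[need])
}

#' Detection success criterion
#'
#' A detection counts as successful when the detected centre falls within the
#' circumference of the true optic disc, i.e. when the Euclidean distance to
#' the annotated centre is at most the annotated radius (boundary inclusive).
#'
#' @param detected_center Numeric `(row, col)` of the detected centre.
#' @param truth A [disc_annotation()].
#' @return Logical scalar.
#' @export
detection_success <- function(detected_center, truth) {
  stopifnot(inherits(truth, "disc_annotation"), length(detected_center) == 2L)
  d <- sqrt(sum((as.numeric(detected_center) - truth$center)^2))
  d <= truth$radius
}
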