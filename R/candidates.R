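#' Candidate region container
#'
#' A 300 x 300 single-channel (red plane) sub-image proposed as possibly
#' containing the optic disc, with provenance and an optional class label.
#'
#' @param pixels 300 x 300 numeric matrix, intensities in \[0, 1\].
#' @param center `(row, col)` of the crop centre in the source image
#'   (1-based); for free-standing synthetic candidates this is the region
#'   centre itself.
#' @param source_id Source image identifier.
#' @param label One of `"disc"`, `"non-disc"`, `"unknown"`.
#' @return An object of class `candidate_region`.
#' @export
candidate_region <- function(pixels, center = c(150.5, 150.5),
                             source_id = "synthetic",
                             label = c("unknown", "disc", "non-disc")) {
  label <- match.arg(label)
  if (!is.matrix(pixels) || !all(dim(pixels) == c(300L, 300L))) {
    stop("candidate region must be a 300 x 300 matrix", call. = FALSE)
  }
  structure(
    list(pixels = pixels, center = as.numeric(center),
         source_id = as.character(source_id), label = label),
    class = "candidate_region"
  )
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("<candidate_region> %s [%s], centre (%.1f, %.1f)\n",
              x$source_id, x$label, x$center[1], x$center[2]))
  invisible(x)
}

#' Candidate region side length (fixed by the method)
#' @keywords internal
REGION_SIDE <- 300L

#' Propose candidate regions from a red-channel image
#'
#' A deliberately simple brightness-based proposal stage: the red plane is
#' Gaussian-smoothed and 300 x 300 windows are placed on the brightest local
#' maxima, greedily suppressing peaks closer than `suppress_radius` to an
#' already accepted one. Windows near the border are clamped so they stay
#' fully inside the image. This stands in for a full saliency-based candidate
#' extractor and is intended for screening synthetic or well-behaved images.
#'
#' @param red H x W numeric matrix (red plane of a standardized image).
#' @param n_props Number of candidate regions to return (>= 1).
#' @param sigma Gaussian smoothing bandwidth in pixels.
#' @param suppress_radius Minimum peak separation in pixels.
#' @param source_id Provenance identifier attached to each candidate.
#' @return A list of [candidate_region()] objects, brightest peak first. Each
#'   records the crop centre in image coordinates.
#' @export
propose_candidates <- function(red, n_props, sigma = 15, suppress_radius = 150,
                               source_id = "image") {
  stopifnot(is.matrix(red), n_props >= 1)
  H <- nrow(red); W <- ncol(red)
  if (H < REGION_SIDE || W < REGION_SIDE) {
    stop("image must be at least 300 x 300 to extract candidates",
         call. = FALSE)
  }
  sm <- EBImage::imageData(
    EBImage::gblur(EBImage::Image(t(red)), sigma = sigma, boundary = "replicate")
  )
  sm <- t(sm)

  # rank pixels by smoothed brightness on a stride-3 subgrid (the smoothed
  # map is slowly varying, so +/-1 px peak accuracy is ample); ties broken
  # by row-major scan order
  gr <- seq(2L, H, by = 3L); gc <- seq(2L, W, by = 3L)
  sub <- sm[gr, gc]
  rr <- rep(gr, times = length(gc)); cc <- rep(gc, each = length(gr))
  ord <- order(-as.vector(sub), (rr - 1) * W + cc)

  half <- REGION_SIDE %/% 2L
  peaks <- matrix(numeric(0), ncol = 2)   # accepted peak coords
  tops  <- matrix(integer(0), ncol = 2)   # accepted window top-left corners
  for (idx in ord) {
    r <- rr[idx]; c <- cc[idx]
    if (nrow(peaks) > 0L) {
      d2 <- (peaks[, 1] - r)^2 + (peaks[, 2] - c)^2
      if (any(d2 < suppress_radius^2)) next
    }
    r0 <- min(max(r - half + 1L, 1L), H - REGION_SIDE + 1L)
    c0 <- min(max(c - half + 1L, 1L), W - REGION_SIDE + 1L)
    if (nrow(tops) > 0L &&
        any(abs(tops[, 1] - r0) < REGION_SIDE &
            abs(tops[, 2] - c0) < REGION_SIDE)) next  # window would overlap
    peaks <- rbind(peaks, c(r, c))
    tops <- rbind(tops, c(r0, c0))
    if (nrow(tops) == n_props) break
  }
  if (nrow(tops) < n_props) {
    warning("could only place ", nrow(tops), " non-overlapping candidates")
  }

  out <- vector("list", nrow(tops))
  for (i in seq_len(nrow(tops))) {
    r0 <- tops[i, 1]; c0 <- tops[i, 2]
    win <- red[r0:(r0 + REGION_SIDE - 1L), c0:(c0 + REGION_SIDE - 1L)]
    out[[i]] <- candidate_region(
      win, center = c(r0 + half - 0.5, c0 + half - 0.5),
      source_id = source_id, label = "unknown"
    )
  }
  out
}
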