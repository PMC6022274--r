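#' Configuration for the synthetic fundus generator
#'
#' Bundles the knobs of the synthetic data generator. The generator emulates
#' the appearance cues the detector relies on: a bright quasi-circular disc
#' with dark vessel-like strokes converging on it, and non-disc distractors
#' (bright irregular lesions, vessel-only crossings, plain textured
#' background). All intensities are on \[0, 1\]; identical seed and
#' configuration give bit-identical output.
#'
#' @param seed Integer seed; every generated object is a deterministic
#'   function of `seed` and the other fields.
#' @param image_count Number of full images for batch helpers.
#' @param disc_radius_range Disc radius range in pixels, `c(lo, hi)`.
#' @param disc_brightness Disc contrast above the background, in \[0, 1\].
#' @param vessel_count Number of vessel strokes converging on the disc.
#' @param vessel_width_range Stroke width range in pixels.
#' @param lesion_count Number of bright lesion blobs in lesion-mode non-disc
#'   regions (and distractors in full images).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param background_level Background intensity in \[0, 1\].
#' @param gradient Amplitude of an optional linear brightness gradient
#'   (0 disables it).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, image_count = 1L,
                             disc_radius_range = c(50, 90),
                             disc_brightness = 0.35,
                             vessel_count = 6L,
                             vessel_width_range = c(3, 8),
                             lesion_count = 2L,
                             noise_sd = 0.03,
                             background_level = 0.45,
                             gradient = 0) {
  stopifnot(
    length(disc_radius_range) == 2L, diff(disc_radius_range) >= 0,
    disc_radius_range[1] > 0,
    length(vessel_width_range) == 2L, diff(vessel_width_range) >= 0,
    vessel_width_range[1] > 0,
    noise_sd >= 0, disc_brightness >= 0, disc_brightness <= 1,
    background_level >= 0, background_level <= 1,
    vessel_count >= 0, lesion_count >= 0, image_count >= 1
  )
  structure(
    list(seed = as.integer(seed), image_count = as.integer(image_count),
         disc_radius_range = as.numeric(disc_radius_range),
         disc_brightness = disc_brightness,
         vessel_count = as.integer(vessel_count),
         vessel_width_range = as.numeric(vessel_width_range),
         lesion_count = as.integer(lesion_count),
         noise_sd = noise_sd, background_level = background_level,
         gradient = gradient),
    class = "generator_config"
  )
}

# quadratic Bezier sample points (n x 2 matrix of (row, col))
bezier_points <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# mark pixels within width/2 of the sampled polyline
stroke_mask <- function(nrow, ncol, pts, width) {
  half <- max(width / 2, 0.5)
  s <- ceiling(half)
  off <- expand.grid(dr = -s:s, dc = -s:s)
  off <- off[off$dr^2 + off$dc^2 <= half^2, , drop = FALSE]
  r <- round(rep(pts[, 1], each = nrow(off))) + rep(off$dr, times = nrow(pts))
  c <- round(rep(pts[, 2], each = nrow(off))) + rep(off$dc, times = nrow(pts))
  keep <- r >= 1 & r <= nrow & c >= 1 & c <= ncol
  m <- matrix(FALSE, nrow, ncol)
  m[cbind(r[keep], c[keep])] <- TRUE
  m
}

# additive sigmoid-edged disc profile; rotationally symmetric, max at center
disc_profile <- function(nrow, ncol, center, radius, brightness) {
  r <- sqrt(outer((seq_len(nrow) - center[1])^2,
                  (seq_len(ncol) - center[2])^2, `+`))
  brightness * stats::plogis((radius - r) / (0.06 * radius))
}

# low-frequency intensity field: a coarse random grid bilinearly upsampled
smooth_texture <- function(n, amplitude) {
  if (amplitude <= 0) return(matrix(0, n, n))
  coarse <- matrix(runif(64, -1, 1), 8, 8)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(coarse), w = n,
                                           h = n, filter = "bilinear"))
  amplitude * up
}

# union of a chain of random ellipses: an irregular, non-circular bright blob
lesion_mask <- function(nrow, ncol, center, scale) {
  m <- matrix(FALSE, nrow, ncol)
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  pos <- center
  ang <- runif(1, 0, 2 * pi)
  for (k in 1:4) {
    a <- scale * runif(1, 0.9, 1.4)       # semi-major
    b <- a / runif(1, 2.2, 3.5)           # strongly elongated
    th <- ang + runif(1, -0.5, 0.5)
    dr <- rows - pos[1]; dc <- cols - pos[2]
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    m <- m | (u^2 / a^2 + v^2 / b^2 <= 1)
    step <- a * runif(1, 0.8, 1.2)
    ang <- ang + runif(1, -0.9, 0.9)
    pos <- pos + step * c(cos(ang), sin(ang))
  }
  m
}

# draw vessel_count strokes converging on `target`, starting at the border
# of the (nrow x ncol) canvas; strokes stop ~stop_at px short of the target
# so the disc's brightest point stays at its center
converging_vessels <- function(canvas, target, cfg, stop_at,
                               darken = 0.6) {
  H <- nrow(canvas); W <- ncol(canvas)
  if (cfg$vessel_count < 1L) return(canvas)
  for (v in seq_len(cfg$vessel_count)) {
    th <- runif(1, 0, 2 * pi)
    # border point in direction th from target
    dir <- c(cos(th), sin(th))
    tmax <- suppressWarnings(min(
      if (dir[1] > 0) (H - target[1]) / dir[1] else if (dir[1] < 0) (1 - target[1]) / dir[1] else Inf,
      if (dir[2] > 0) (W - target[2]) / dir[2] else if (dir[2] < 0) (1 - target[2]) / dir[2] else Inf
    ))
    p0 <- target + tmax * dir
    p2 <- target + stop_at * dir * runif(1, 0.9, 1.3)
    mid <- (p0 + p2) / 2
    perp <- c(-dir[2], dir[1]) * runif(1, -0.25, 0.25) * tmax
    p1 <- mid + perp
    w <- runif(1, cfg$vessel_width_range[1], cfg$vessel_width_range[2])
    pts <- bezier_points(p0, p1, p2, n = max(64L, ceiling(2 * tmax)))
    mask <- stroke_mask(H, W, pts, w)
    canvas[mask] <- canvas[mask] * darken
  }
  canvas
}

finish_region <- function(canvas, cfg) {
  if (cfg$noise_sd > 0) {
    canvas <- canvas + matrix(rnorm(length(canvas), 0, cfg$noise_sd),
                              nrow(canvas), ncol(canvas))
  }
  pmin(pmax(canvas, 0), 1)
}

#' Generate a synthetic optic-disc candidate region
#'
#' Renders a 300 x 300 red-channel region containing a bright disc with a
#' sigmoid-edged radial falloff, `vessel_count` dark curved strokes
#' converging on the disc centre, an optional linear brightness gradient, and
#' additive Gaussian noise clipped to \[0, 1\]. The planted centre and radius
#' are returned as a [disc_annotation()] in region coordinates.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `region` (a [candidate_region()],
#'   label `"disc"`) and `annotation` (a [disc_annotation()]).
#' @export
synth_disc_candidate <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- REGION_SIDE
    # candidate extraction does not center discs perfectly, and disc
    # contrast varies between eyes: jitter the planted position
    # substantially and draw a per-candidate contrast factor, so
    # position-invariant features genuinely matter
    center <- c(150L, 150L) + sample(-60:60, 2L, replace = TRUE)
    radius <- runif(1, cfg$disc_radius_range[1], cfg$disc_radius_range[2])
    bright <- cfg$disc_brightness * runif(1, 0.75, 1.25)
    canvas <- matrix(cfg$background_level, n, n)
    if (cfg$gradient != 0) {
      canvas <- canvas + cfg$gradient *
        matrix(seq(-0.5, 0.5, length.out = n), n, n, byrow = TRUE)
    }
    canvas <- canvas + disc_profile(n, n, center, radius, bright)
    canvas <- converging_vessels(canvas, center, cfg, stop_at = 0.2 * radius)
    canvas <- finish_region(canvas, cfg)
    list(
      region = candidate_region(canvas, source_id = sprintf("synth-disc-%d", cfg$seed),
                                label = "disc"),
      annotation = disc_annotation(center, radius)
    )
  })
}

#' Generate a synthetic non-disc candidate region
#'
#' Draws one of three distractor modes, chosen by the seeded RNG among the
#' modes the configuration allows: `"lesion"` (bright irregular blobs with no
#' converging vessels), `"vessel"` (dark strokes crossing a plain background),
#' or `"background"` (noise around the background level). With
#' `lesion_count = 0` and `vessel_count = 0` only the background mode remains.
#'
#' @param cfg A [generator_config()].
#' @return A [candidate_region()] with label `"non-disc"`; the chosen mode is
#'   attached as attribute `"mode"`.
#' @export
synth_nondisc_candidate <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- REGION_SIDE
    modes <- c("background",
               if (cfg$lesion_count > 0L) "lesion",
               if (cfg$vessel_count > 0L) "vessel")
    mode <- modes[sample.int(length(modes), 1L)]
    canvas <- matrix(cfg$background_level, n, n)
    if (cfg$gradient != 0) {
      canvas <- canvas + cfg$gradient *
        matrix(seq(-0.5, 0.5, length.out = n), n, n, byrow = TRUE)
    }
    # non-disc candidates vary widely in the field (the very reason a
    # one-class model is attractive), so each draws its own structural
    # parameters from broad ranges rather than reusing fixed ones
    if (mode == "lesion") {
      n_les <- sample.int(max(1L, 2L * cfg$lesion_count), 1L)
      for (k in seq_len(n_les)) {
        ctr <- runif(2, 50, 250)
        scale <- runif(1, 15, 70)
        mask <- lesion_mask(n, n, ctr, scale)
        canvas[mask] <- canvas[mask] +
          cfg$disc_brightness * runif(1, 0.5, 1.6)
      }
      if (runif(1) < 0.3) canvas <- canvas + smooth_texture(n, runif(1, 0.02, 0.08))
    } else if (mode == "vessel") {
      # strokes crossing the region without a convergence point
      n_str <- sample.int(max(1L, 2L * cfg$vessel_count), 1L)
      for (v in seq_len(n_str)) {
        side <- sample.int(4L, 2L, replace = FALSE)
        rand_edge <- function(s) switch(s,
          c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
          c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
        p0 <- rand_edge(side[1]); p2 <- rand_edge(side[2])
        p1 <- (p0 + p2) / 2 + runif(2, -80, 80)
        w <- runif(1, cfg$vessel_width_range[1], 2 * cfg$vessel_width_range[2])
        mask <- stroke_mask(n, n, bezier_points(p0, p1, p2, 600L), w)
        canvas[mask] <- canvas[mask] * runif(1, 0.4, 0.75)
      }
      if (runif(1) < 0.3) canvas <- canvas + smooth_texture(n, runif(1, 0.02, 0.08))
    } else if (cfg$lesion_count > 0L || cfg$vessel_count > 0L) {
      # textured background; the all-structure-disabled configuration stays
      # pure noise so it can serve as a null reference
      canvas <- canvas + smooth_texture(n, runif(1, 0, 0.08))
    }
    canvas <- finish_region(canvas, cfg)
    out <- candidate_region(canvas,
                            source_id = sprintf("synth-nondisc-%d", cfg$seed),
                            label = "non-disc")
    attr(out, "mode") <- mode
    out
  })
}

#' Generate a labelled synthetic candidate dataset
#'
#' Produces `n_disc` disc and `n_nondisc` non-disc candidate regions. Each
#' candidate is generated from a seed derived deterministically from
#' `cfg$seed` and the candidate's index, so the dataset is reproducible and
#' individual candidates can be regenerated in isolation.
#'
#' @param cfg A [generator_config()].
#' @param n_disc,n_nondisc Number of regions per class (>= 0).
#' @return A list of [candidate_region()] objects (discs first); disc regions
#'   carry their [disc_annotation()] as attribute `"annotation"`.
#' @export
synth_candidate_set <- function(cfg, n_disc, n_nondisc) {
  stopifnot(inherits(cfg, "generator_config"), n_disc >= 0, n_nondisc >= 0)
  discs <- lapply(seq_len(n_disc), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i
    g <- synth_disc_candidate(ci)
    attr(g$region, "annotation") <- g$annotation
    g$region
  })
  nondiscs <- lapply(seq_len(n_nondisc), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + 100000L + i
    synth_nondisc_candidate(ci)
  })
  c(discs, nondiscs)
}

#' Generate a full synthetic fundus image with a known disc
#'
#' Renders a standardized-geometry (960 x 1440) colour fundus image: an
#' elliptical field of view around the background level, one planted bright
#' disc with vessels radiating from it, `lesion_count` bright lesion
#' distractors placed away from the disc, and pixel noise. The green and blue
#' channels are dimmed copies of the red structure; all detection runs on the
#' red plane.
#'
#' @param cfg A [generator_config()].
#' @return A list with `image` (a standardized [fundus_image()]),
#'   `annotation` (a [disc_annotation()] in image coordinates), and
#'   `source_id`.
#' @export
synth_fundus_image <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    H <- 960L; W <- 1440L
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    fov <- ((rows - H / 2) / (0.47 * H))^2 + ((cols - W / 2) / (0.48 * W))^2 <= 1
    canvas <- matrix(0.05, H, W)
    canvas[fov] <- cfg$background_level
    if (cfg$gradient != 0) {
      canvas <- canvas + cfg$gradient * (cols - W / 2) / W
    }
    # keep the disc mid-field (as in real fundus photographs) so its whole
    # candidate window stays inside the field of view
    center <- c(round(runif(1, 330, 630)), round(runif(1, 380, 1060)))
    radius <- runif(1, cfg$disc_radius_range[1], cfg$disc_radius_range[2])
    canvas <- canvas + disc_profile(H, W, center, radius, cfg$disc_brightness)
    canvas <- converging_vessels(canvas, center, cfg, stop_at = 0.2 * radius)
    for (k in seq_len(cfg$lesion_count)) {
      repeat {
        ctr <- c(runif(1, 120, H - 120), runif(1, 140, W - 140))
        if (sqrt(sum((ctr - center)^2)) > 380) break
      }
      mask <- lesion_mask(H, W, ctr, runif(1, 25, 55)) & fov
      canvas[mask] <- canvas[mask] + cfg$disc_brightness * runif(1, 0.7, 1.0)
    }
    canvas <- finish_region(canvas, cfg)
    px <- array(0, dim = c(H, W, 3))
    px[, , 1] <- canvas
    px[, , 2] <- pmin(pmax(canvas * 0.55, 0), 1)
    px[, , 3] <- pmin(pmax(canvas * 0.25, 0), 1)
    sid <- sprintf("synth-fundus-%d", cfg$seed)
    list(image = fundus_image(px, source_id = sid, resized = TRUE),
         annotation = disc_annotation(center, radius),
         source_id = sid)
  })
}
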