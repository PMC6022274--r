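# fixed probe pixels well inside the field of view but away from typical discs
fundus_fov_sample <- function() {
  cbind(rep(c(200, 480, 760), each = 3), rep(c(500, 720, 940), times = 3))
}

test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  cfg <- generator_config(seed = 5)
  a <- synth_disc_candidate(cfg)
  b <- synth_disc_candidate(cfg)
  expect_identical(a$region$pixels, b$region$pixels)
  expect_identical(a$annotation, b$annotation)

  c2 <- synth_disc_candidate(generator_config(seed = 6))
  expect_false(identical(a$region$pixels, c2$region$pixels))

  n1 <- synth_nondisc_candidate(cfg)
  n2 <- synth_nondisc_candidate(cfg)
  expect_identical(n1$pixels, n2$pixels)
})

test_that("noiseless vessel-free disc is brightest at its centre and symmetric", {
  cfg <- generator_config(seed = 9, noise_sd = 0, vessel_count = 0L)
  g <- synth_disc_candidate(cfg)
  px <- g$region$pixels
  ctr <- g$annotation$center
  expect_equal(as.numeric(which(px == max(px), arr.ind = TRUE)[1, ]), ctr)

  # rotational symmetry: any two pixels at the same radius share a value
  rows <- 1:300
  i <- ctr[1] + 40; j <- ctr[2]
  mirror <- c(ctr[1] - 40, ctr[2])
  expect_equal(px[i, j], px[mirror[1], mirror[2]])
  transposed <- c(ctr[1], ctr[2] + 40)
  expect_equal(px[i, j], px[transposed[1], transposed[2]])
})

test_that("planted annotation matches the argmax of the noiseless render", {
  for (seed in c(2, 13, 27)) {
    cfg <- generator_config(seed = seed, noise_sd = 0)  # vessels at default
    g <- synth_disc_candidate(cfg)
    peak <- which(g$region$pixels == max(g$region$pixels), arr.ind = TRUE)[1, ]
    expect_lte(sqrt(sum((as.numeric(peak) - g$annotation$center)^2)), 2)
  }
})

test_that("a zero-contrast disc is indistinguishable from background", {
  cfg_flat <- generator_config(seed = 21, disc_brightness = 0,
                               vessel_count = 0L, lesion_count = 0L)
  disc <- synth_disc_candidate(cfg_flat)$region
  bg <- synth_nondisc_candidate(generator_config(seed = 22, vessel_count = 0L,
                                                 lesion_count = 0L))
  expect_identical(attr(bg, "mode"), "background")
  expect_lt(abs(mean(disc$pixels) - mean(bg$pixels)),
            3 * cfg_flat$noise_sd / sqrt(300^2) * 2)  # two-sample allowance
})

test_that("lesion-mode distractors contain a non-circular bright component", {
  cfg <- generator_config(seed = 1, vessel_count = 0L, noise_sd = 0.01)
  found <- FALSE
  for (seed in 1:12) {
    cfg$seed <- seed
    nd <- synth_nondisc_candidate(cfg)
    if (!identical(attr(nd, "mode"), "lesion")) next
    found <- TRUE
    mask <- nd$pixels > cfg$background_level + 0.5 * cfg$disc_brightness
    lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
    shape <- EBImage::computeFeatures.shape(lab)
    big <- which.max(shape[, "s.area"])
    circ <- 4 * pi * shape[big, "s.area"] / shape[big, "s.perimeter"]^2
    expect_lt(circ, 0.8)
  }
  expect_true(found)
})

test_that("candidate sets have the requested sizes, labels and determinism", {
  cfg <- generator_config(seed = 3)
  set <- synth_candidate_set(cfg, 10, 10)
  expect_length(set, 20L)
  labels <- vapply(set, `[[`, character(1), "label")
  expect_equal(sum(labels == "disc"), 10L)
  expect_equal(sum(labels == "non-disc"), 10L)
  expect_s3_class(attr(set[[1]], "annotation"), "disc_annotation")

  none <- synth_candidate_set(cfg, 0, 4)
  expect_true(all(vapply(none, `[[`, character(1), "label") == "non-disc"))

  set2 <- synth_candidate_set(cfg, 10, 10)
  expect_identical(set[[5]]$pixels, set2[[5]]$pixels)
  set3 <- synth_candidate_set(generator_config(seed = 4), 10, 10)
  expect_false(identical(set[[5]]$pixels, set3[[5]]$pixels))
})

test_that("full synthetic images have standardized geometry and a valid disc", {
  gen <- synth_fundus_image(generator_config(seed = 8))
  expect_equal(dim(gen$image$pixels), c(960L, 1440L, 3L))
  expect_true(gen$image$resized)
  ann <- gen$annotation
  expect_true(ann$center[1] > ann$radius && ann$center[1] < 960 - ann$radius)
  expect_true(ann$center[2] > ann$radius && ann$center[2] < 1440 - ann$radius)
  # corners are outside the field of view, hence dark
  red <- red_channel(gen$image)
  expect_lt(mean(red[1:20, 1:20]), 0.2)
  # disc neighbourhood is brighter than the overall background
  rr <- round(ann$center[1]) + (-10:10); cc <- round(ann$center[2]) + (-10:10)
  expect_gt(mean(red[rr, cc]), mean(red[fundus_fov_sample()]))
})

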