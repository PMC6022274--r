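test_that("the z-score normalizer matches its definition", {
  Fm <- matrix(c(0, 2), 2, 1)
  nm <- fit_normalizer(Fm)
  expect_equal(as.vector(predict(nm, Fm)), c(-1, 1))  # population sd = 1

  set.seed(2)
  Fm2 <- matrix(rnorm(50 * 4, mean = 3, sd = 2), 50, 4)
  nm2 <- fit_normalizer(Fm2)
  Z <- predict(nm2, Fm2)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(colMeans(Z^2) - 1)), 1e-10)

  # a feature equal to the mean maps to the zero vector
  expect_lt(max(abs(predict(nm2, matrix(nm2$mu, 1)))), 1e-12)

  # constant dimensions are floored, not divided by zero
  Fc <- cbind(Fm2[, 1], 7)
  expect_warning(nmc <- fit_normalizer(Fc), "floored")
  expect_true(all(is.finite(predict(nmc, Fc))))

  # sample-sd variant is switchable
  nms <- fit_normalizer(Fm, population = FALSE)
  expect_equal(nms$sigma, stats::sd(c(0, 2)), ignore_attr = TRUE)
})

toy_features <- function(n_per_class = 30, sep = 4, d = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- sprintf("atom_%03d", seq_len(d))
    out <- dplyr::bind_cols(
      tibble::tibble(candidate_id = sprintf("c%03d", seq_len(2 * n_per_class)),
                     label = rep(c("disc", "non-disc"), each = n_per_class)),
      df)
    class(out) <- c("lfsa_features", class(out))
    out
  })
}

test_that("classifiers fit separable data and refuse degenerate input", {
  feats <- toy_features()
  svm <- train_classifier(feats, classifier_spec("svm", seed = 2))
  expect_equal(predict(svm, feats)$.pred, feats$label)

  knn <- train_classifier(feats, classifier_spec("knn", k = 1))
  expect_equal(predict(knn, feats)$.pred, feats$label)  # k=1 self-prediction

  only_disc <- feats[feats$label == "disc", ]
  expect_error(train_classifier(only_disc, classifier_spec("svm")),
               "both classes")
  expect_error(train_classifier(feats, classifier_spec("svm", k = 2)), "k")
})

test_that("svm scores are oriented so that larger means more disc-like", {
  feats <- toy_features()
  model <- train_classifier(feats, classifier_spec("svm", seed = 3))
  pred <- predict(model, feats)
  expect_gt(min(pred$.score[feats$label == "disc"]),
            max(pred$.score[feats$label == "non-disc"]))
})

test_that("svdd learns a data description from positives only", {
  withr::with_seed(9, {
    d <- 4
    inside <- matrix(rnorm(150 * d, sd = 0.35), ncol = d)
    fresh <- matrix(rnorm(200 * d, sd = 0.35), ncol = d)
    shell <- 5 * (matrix(rnorm(200 * d), ncol = d) /
                    sqrt(rowSums(matrix(rnorm(200 * d), ncol = d)^2) + 1e-9))
  })
  mk <- function(X, label) {
    df <- tibble::as_tibble(as.data.frame(X))
    names(df) <- sprintf("atom_%03d", seq_len(ncol(X)))
    out <- dplyr::bind_cols(
      tibble::tibble(candidate_id = sprintf("x%04d", seq_len(nrow(X))),
                     label = label), df)
    class(out) <- c("lfsa_features", class(out))
    out
  }
  train <- mk(inside, "disc")
  model <- train_classifier(
    train, classifier_spec("svdd", nu = 0.05, gamma_scale = 1))
  acc_in <- mean(predict(model, mk(fresh, "disc"))$.pred == "disc")
  acc_out <- mean(predict(model, mk(shell, "non-disc"))$.pred == "non-disc")
  expect_gte(acc_in, 0.9)
  expect_gte(acc_out, 0.9)
})

test_that("repeated holdout evaluation is calibrated and deterministic", {
  # random labels, balanced classes: accuracy compatible with the null
  withr::with_seed(4, {
    feats <- toy_features(n_per_class = 40, sep = 0)
  })
  ev <- evaluate_split(feats, classifier_spec("svm", cost = 1, gamma_scale = 1),
                       repeats = 10, seed = 5)
  gl <- glance(ev)
  # null sd of a 24-sample test accuracy is ~0.10; allow 3 sd around 0.5
  expect_lt(abs(gl$mean_accuracy - 0.5), 0.3)

  ev2 <- evaluate_split(feats, classifier_spec("svm", cost = 1, gamma_scale = 1),
                        repeats = 10, seed = 5)
  expect_identical(ev$accuracy, ev2$accuracy)

  # separable data: near-perfect held-out accuracy
  sep <- toy_features(n_per_class = 20, sep = 5, seed = 8)
  gl2 <- glance(evaluate_split(sep, classifier_spec("svm"), repeats = 5,
                               seed = 2))
  expect_gte(gl2$mean_accuracy, 0.95)
  expect_error(evaluate_split(sep[c(1, 2, 21), ], classifier_spec("svm")),
               "two samples")
})

test_that("learning curves track training size for both svm and svdd", {
  feats <- toy_features(n_per_class = 60, sep = 2.5, seed = 12)
  lc <- learning_curve(feats, sizes = c(5, 25), kinds = c("svm", "svdd"),
                       draws = 4, seed = 3,
                       cost = 1, gamma_scale = 1, nu = 0.05)
  expect_equal(nrow(lc), 2 * 2 * 4)
  expect_true(all(lc$accuracy >= 0 & lc$accuracy <= 1))
  summ <- lc |>
    dplyr::group_by(.data$classifier, .data$size) |>
    dplyr::summarise(m = mean(.data$accuracy), .groups = "drop")
  # more data should not hurt the svm on separable-ish data
  svm_rows <- summ[summ$classifier == "svm", ]
  expect_gte(svm_rows$m[svm_rows$size == 25],
             svm_rows$m[svm_rows$size == 5] - 0.05)
})

test_that("pixel baseline features pool blocks correctly", {
  reg <- candidate_region(matrix(0.5, 300, 300))
  pf <- pixel_features(list(reg), pool = 10)
  expect_equal(ncol(feature_matrix(pf)), 900L)
  expect_true(all(feature_matrix(pf) == 0.5))

  # block means are exact: a region whose top-left 10x10 block is 1
  px <- matrix(0, 300, 300); px[1:10, 1:10] <- 1
  pf2 <- pixel_features(list(candidate_region(px)), pool = 10)
  fm <- feature_matrix(pf2)
  expect_equal(sum(fm == 1), 1L)
  expect_equal(sum(fm), 1)
})
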