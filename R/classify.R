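#' Fit a per-dimension z-score normalizer
#'
#' Records the per-dimension mean and population standard deviation of the
#' training features; applying the model maps each feature `f` to
#' `(f - mu) / sigma`. Constant dimensions get their standard deviation
#' floored at `sigma_floor` (with a warning) so the transform stays defined.
#'
#' @param features An `lfsa_features` tibble (or numeric matrix), one row per
#'   candidate.
#' @param sigma_floor Dimensions whose standard deviation falls below this
#'   are treated as constant.
#' @param population Use the population (divide by S) rather than the sample
#'   standard deviation; the default matches the method's definition.
#' @return An object of class `lfsa_normalizer` with fields `mu`, `sigma`.
#' @export
fit_normalizer <- function(features, sigma_floor = 1e-8, population = TRUE) {
  Fm <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(Fm) < 2L) stop("need at least two feature vectors", call. = FALSE)
  mu <- colMeans(Fm)
  ctr <- sweep(Fm, 2L, mu)
  sigma <- if (population) {
    sqrt(colMeans(ctr^2))
  } else {
    apply(Fm, 2L, stats::sd)
  }
  if (any(sigma < sigma_floor)) {
    # constant training dimensions: scale by the data's typical sigma (or 1
    # if every dimension is constant) so a test deviation in such a
    # dimension registers on the same scale as the informative ones instead
    # of being amplified by a vanishing denominator
    warning("constant feature dimension(s); standard deviation floored")
    fill <- stats::median(sigma[sigma >= sigma_floor])
    if (!is.finite(fill) || fill <= 0) fill <- 1
    sigma[sigma < sigma_floor] <- fill
  }
  structure(list(mu = mu, sigma = sigma), class = "lfsa_normalizer")
}

#' @export
predict.lfsa_normalizer <- function(object, newdata, ...) {
  Fm <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  stopifnot(ncol(Fm) == length(object$mu))
  sweep(sweep(Fm, 2L, object$mu), 2L, object$sigma, `/`)
}

#' Classifier specification
#'
#' Declares which classifier to use and its hyperparameter grid. Grids with
#' more than one cell are resolved by stratified `cv_folds`-fold
#' cross-validated grid search on the training set; length-one grids are used
#' as-is. Kernel classifiers use the RBF kernel with
#' `gamma = gamma_scale / Dsize`.
#'
#' @param kind `"svm"` (binary), `"knn"`, or `"svdd"` (one-class, trained on
#'   disc candidates only).
#' @param cost SVM cost grid.
#' @param gamma_scale Multipliers of the base kernel bandwidth `1/Dsize`
#'   (binary SVM only).
#' @param k kNN neighbourhood sizes; must be odd (vote-tie avoidance).
#' @param nu SVDD `nu` (fraction of training positives allowed outside the
#'   description), a single value in (0, 1]. The SVDD kernel bandwidth is set
#'   by the median-distance heuristic rather than cross-validation:
#'   with positives only, held-out acceptance is monotone in the bandwidth,
#'   so maximizing it degenerately selects a description that accepts
#'   everything.
#' @param cv_folds Number of stratified folds for grid search.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "knn", "svdd"),
                            cost = c(0.1, 1, 10, 100),
                            gamma_scale = c(0.1, 1, 10),
                            k = c(1, 3, 5, 7, 9),
                            nu = 0.05,
                            cv_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(all(k %% 2 == 1), length(nu) == 1L, nu > 0, nu <= 1,
            cv_folds >= 2L)
  structure(list(kind = kind, cost = cost, gamma_scale = gamma_scale,
                 k = as.integer(k), nu = nu, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# median-distance RBF bandwidth: gamma = 1 / median squared pairwise distance
median_gamma <- function(Xn) {
  n <- nrow(Xn)
  if (n > 200L) Xn <- Xn[seq(1L, n, length.out = 200L), , drop = FALSE]
  d2 <- as.vector(stats::dist(Xn))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 / ncol(Xn) else 1 / m
}

# deterministic stratified fold ids
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# fit one configuration; Xn is the normalized feature matrix
fit_one <- function(Xn, y, kind, par) {
  switch(kind,
    svm = e1071::svm(Xn, y, kernel = "radial", cost = par$cost,
                     gamma = par$gamma, scale = FALSE),
    svdd = fit_svdd(Xn[y == "disc", , drop = FALSE], par),
    knn = list(train = Xn, y = y, k = par$k)
  )
}

# one-class SVDD with an out-of-sample-calibrated acceptance threshold.
# The library's own boundary (decision value 0) is calibrated against the
# training points' scores, which include a self-similarity term
# alpha_i * K(x_i, x_i) that fresh points lack; in high dimension that bias
# makes the raw boundary reject essentially every unseen positive. For each
# training point, d(x_i) - alpha_i is exactly the score the model would
# give it without its self-term, so the acceptance threshold is set at the
# nu-quantile of those corrected scores.
fit_svdd <- function(Xpos, par) {
  fit <- e1071::svm(Xpos, type = "one-classification", kernel = "radial",
                    nu = par$nu, gamma = par$gamma, scale = FALSE)
  dtr <- as.numeric(attr(predict(fit, Xpos, decision.values = TRUE),
                         "decision.values"))
  alpha <- rep(0, nrow(Xpos))
  alpha[fit$index] <- fit$coefs
  thr <- stats::quantile(dtr - alpha, par$nu, names = FALSE)
  structure(list(fit = fit, threshold = thr), class = "lfsa_svdd")
}

# predict labels and a disc-oriented score from a fitted configuration
predict_one <- function(fit, kind, Xn) {
  if (kind == "knn") {
    pr <- class::knn(fit$train, Xn, fit$y, k = fit$k, prob = TRUE)
    p <- attr(pr, "prob")
    score <- ifelse(pr == "disc", p, 1 - p)
    return(list(label = as.character(pr), score = as.numeric(score)))
  }
  if (kind == "svdd") {
    dv <- as.numeric(attr(predict(fit$fit, Xn, decision.values = TRUE),
                          "decision.values"))
    score <- dv - fit$threshold
    return(list(label = ifelse(score >= 0, "disc", "non-disc"),
                score = score))
  }
  pv <- predict(fit, Xn, decision.values = TRUE)
  dv <- attr(pv, "decision.values")
  # binary svm: orient the decision value so larger = more disc-like
  flip <- if (startsWith(colnames(dv)[1], "disc")) 1 else -1
  list(label = as.character(pv), score = flip * as.numeric(dv))
}

# cross-validated accuracy of one configuration. For the one-class svdd the
# negatives play no role in fitting; accuracy is the held-out acceptance
# rate of the positive class.
cv_accuracy <- function(Xn, y, kind, par, folds) {
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (kind == "svdd" && sum(y[tr] == "disc") < 2L) return(NA_real_)
    fit <- fit_one(Xn[tr, , drop = FALSE], factor(y[tr], levels(y)), kind, par)
    pred <- predict_one(fit, kind, Xn[!tr, , drop = FALSE])
    if (kind == "svdd") {
      mean(pred$label[y[!tr] == "disc"] == "disc")
    } else {
      mean(pred$label == as.character(y[!tr]))
    }
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

param_grid <- function(spec, Dsize, Xn = NULL) {
  switch(spec$kind,
    svm = expand.grid(cost = spec$cost, gamma = spec$gamma_scale / Dsize),
    svdd = data.frame(nu = spec$nu, gamma = median_gamma(Xn)),
    knn = data.frame(k = spec$k)
  )
}

#' Train a candidate classifier on spectrum features
#'
#' Fits the z-score normalizer on the training features, resolves the
#' hyperparameter grid by stratified cross-validation on the training set
#' only, and fits the final model on all training data. The one-class SVDD
#' is trained on disc-labelled candidates only; binary kinds require both
#' labels.
#'
#' @param features An `lfsa_features` tibble with a `label` column containing
#'   `"disc"`/`"non-disc"`.
#' @param spec A [classifier_spec()].
#' @return An object of class `lfsa_classifier` bundling the normalizer, the
#'   fitted model, and the chosen hyperparameters.
#' @export
train_classifier <- function(features, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  Fm <- feature_matrix(features)
  y <- factor(features$label, levels = c("disc", "non-disc"))
  if (anyNA(y)) stop("labels must be 'disc' or 'non-disc'", call. = FALSE)
  if (spec$kind != "svdd" && length(unique(y)) < 2L) {
    stop("binary classifier needs both classes in training data",
         call. = FALSE)
  }
  if (spec$kind == "svdd" && sum(y == "disc") < 2L) {
    stop("svdd needs at least two disc-labelled candidates", call. = FALSE)
  }
  norm <- suppressWarnings(fit_normalizer(Fm))
  Xn <- predict(norm, Fm)
  grid <- param_grid(spec, ncol(Fm),
                     Xn = Xn[y == "disc", , drop = FALSE])
  if (nrow(grid) > 1L) {
    folds <- stratified_folds(as.character(y),
                              min(spec$cv_folds, max(2L, floor(length(y) / 2))),
                              spec$seed)
    scores <- vapply(seq_len(nrow(grid)), function(i) {
      cv_accuracy(Xn, y, spec$kind, as.list(grid[i, , drop = FALSE]), folds)
    }, numeric(1))
    best <- as.list(grid[which.max(scores), , drop = FALSE])
    cv_best <- max(scores)
  } else {
    best <- as.list(grid[1L, , drop = FALSE])
    cv_best <- NA_real_
  }
  fit <- fit_one(Xn, y, spec$kind, best)
  structure(list(spec = spec, normalizer = norm, fit = fit, kind = spec$kind,
                 hyperparams = best, cv_accuracy = cv_best,
                 Dsize = ncol(Fm)),
            class = "lfsa_classifier")
}

#' @export
print.lfsa_classifier <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              signif(unlist(x$hyperparams), 3), sep = "=", collapse = ", ")
  cat(sprintf("<lfsa_classifier> %s (%s)%s\n", x$kind, hp,
              if (is.na(x$cv_accuracy)) ""
              else sprintf(", cv accuracy %.3f", x$cv_accuracy)))
  invisible(x)
}

#' Predict candidate classes and scores
#'
#' @param object An `lfsa_classifier`.
#' @param newdata An `lfsa_features` tibble or feature matrix.
#' @param ... Unused.
#' @return A tibble with `.pred` (`"disc"`/`"non-disc"`) and `.score`
#'   (higher = more disc-like; for the SVDD, the signed distance to the
#'   learned boundary).
#' @export
predict.lfsa_classifier <- function(object, newdata, ...) {
  Fm <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  Xn <- predict(object$normalizer, Fm)
  pred <- predict_one(object$fit, object$kind, Xn)
  tibble::tibble(.pred = pred$label, .score = pred$score)
}

#' Repeated stratified holdout evaluation
#'
#' The method's evaluation protocol: `repeats` random stratified
#' `train_frac`/(1 - `train_frac`) splits; on each split the normalizer and
#' hyperparameters are fitted on the training part only and accuracy is
#' measured on the held-out part. The one-class SVDD trains on the split's
#' disc candidates but is tested on both classes.
#'
#' @param features An `lfsa_features` tibble with both labels present.
#' @param spec A [classifier_spec()].
#' @param train_frac Training fraction of each split.
#' @param repeats Number of random splits.
#' @param seed Integer seed; split `r` uses `seed + r`.
#' @return A tibble of class `lfsa_eval` with one row per repeat
#'   (`repeat_id`, `accuracy`, plus the chosen hyperparameters); `glance()`
#'   gives mean and standard deviation.
#' @export
evaluate_split <- function(features, spec = classifier_spec(),
                           train_frac = 0.7, repeats = 10L, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, repeats >= 1L)
  y <- features$label
  if (min(table(y)) < 2L) stop("need at least two samples per class",
                               call. = FALSE)
  rows <- purrr::map(seq_len(repeats), function(r) {
    tr <- withr::with_seed(seed + r, {
      idx <- logical(nrow(features))
      for (lv in unique(y)) {
        pool <- which(y == lv)
        idx[sample(pool, round(train_frac * length(pool)))] <- TRUE
      }
      idx
    })
    sp <- spec; sp$seed <- spec$seed + r
    model <- train_classifier(features[tr, , drop = FALSE], sp)
    pred <- predict(model, features[!tr, , drop = FALSE])
    tibble::tibble(repeat_id = r,
                   accuracy = mean(pred$.pred == y[!tr]),
                   !!!model$hyperparams)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "spec_kind") <- spec$kind
  class(out) <- c("lfsa_eval", class(out))
  out
}

#' @rdname evaluate_split
#' @param x An `lfsa_eval` tibble.
#' @param ... Unused.
#' @export
glance.lfsa_eval <- function(x, ...) {
  tibble::tibble(classifier = attr(x, "spec_kind") %||% NA_character_,
                 repeats = nrow(x),
                 mean_accuracy = mean(x$accuracy),
                 sd_accuracy = stats::sd(x$accuracy))
}

#' Learning curve over training-set size
#'
#' Holds out one fixed stratified test set, then for each training size
#' draws that many disc candidates (plus equally many non-disc candidates
#' for binary classifiers; none for the SVDD) from the training pool,
#' trains, and evaluates on the fixed test set. Each size is repeated
#' `draws` times with fresh random draws.
#'
#' @param features An `lfsa_features` tibble with both labels.
#' @param sizes Integer vector of disc-sample counts.
#' @param kinds Character vector of classifier kinds to compare.
#' @param draws Random draws per size.
#' @param test_frac Fraction held out as the fixed test set.
#' @param seed Integer seed.
#' @param ... Passed on to [classifier_spec()] (grids, `cv_folds`).
#' @return A tibble of class `lfsa_learning_curve`: `classifier`, `size`,
#'   `draw`, `accuracy`.
#' @export
learning_curve <- function(features, sizes, kinds = c("svm", "svdd"),
                           draws = 10L, test_frac = 0.3, seed = 1L, ...) {
  y <- features$label
  test <- withr::with_seed(seed, {
    idx <- logical(nrow(features))
    for (lv in unique(y)) {
      pool <- which(y == lv)
      idx[sample(pool, round(test_frac * length(pool)))] <- TRUE
    }
    idx
  })
  pool_disc <- which(!test & y == "disc")
  pool_non <- which(!test & y == "non-disc")
  stopifnot(max(sizes) <= length(pool_disc), max(sizes) <= length(pool_non))
  test_feat <- features[test, , drop = FALSE]

  grid <- tidyr::expand_grid(classifier = kinds, size = as.integer(sizes),
                             draw = seq_len(draws))
  acc <- purrr::pmap_dbl(grid, function(classifier, size, draw) {
    pick <- withr::with_seed(seed + 1000L * size + draw, {
      d <- sample(pool_disc, size)
      n <- if (classifier == "svdd") integer(0) else sample(pool_non, size)
      c(d, n)
    })
    sp <- classifier_spec(kind = classifier,
                          seed = seed + 1000L * size + draw, ...)
    model <- train_classifier(features[pick, , drop = FALSE], sp)
    pred <- predict(model, test_feat)
    mean(pred$.pred == test_feat$label)
  })
  out <- dplyr::mutate(grid, accuracy = acc)
  class(out) <- c("lfsa_learning_curve", class(out))
  out
}

#' Raw-pixel baseline features
#'
#' The baseline representation the spectrum is compared against: each
#' candidate's grey (red-plane) intensities, mean-pooled to
#' `(300/pool) x (300/pool)` and vectorized. With the same classification
#' protocol, the spectrum features should beat this on data where the disc's
#' local structure matters more than its exact position.
#'
#' @param regions List of [candidate_region()] objects.
#' @param pool Pooling factor (must divide 300).
#' @return An `lfsa_features` tibble with `px_*` columns.
#' @export
pixel_features <- function(regions, pool = 10L) {
  stopifnot(300L %% pool == 0L)
  g <- 300L %/% pool
  rows <- purrr::imap(regions, function(reg, i) {
    px <- if (inherits(reg, "candidate_region")) reg$pixels else reg
    pooled <- colMeans(matrix(aperm(array(px, c(pool, g, pool, g)),
                                    c(1L, 3L, 2L, 4L)),
                              pool * pool, g * g))
    c(list(candidate_id = if (inherits(reg, "candidate_region")) reg$source_id
           else paste0("candidate-", i),
           label = if (inherits(reg, "candidate_region")) reg$label else "unknown"),
      stats::setNames(as.list(pooled), sprintf("px_%03d", seq_len(g * g))))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lfsa_features", class(out))
  out
}
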