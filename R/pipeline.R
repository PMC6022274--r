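#' Train an end-to-end optic-disc model
#'
#' Runs the full training pipeline on labelled candidate regions: pool
#' patches into a corpus (optionally from disc candidates only), subsample
#' the corpus to `corpus_cap` columns, build the dictionary with the chosen
#' method, compute every candidate's spectrum, and train the classifier.
#'
#' @param regions List of labelled [candidate_region()] objects.
#' @param M Patch side (must divide 300).
#' @param Dsize Number of dictionary atoms.
#' @param dict_method `"sparse"`, `"kmeans"` or `"random"`.
#' @param lambda Regularization weight for the sparse method (`"auto"` by
#'   default).
#' @param spec A [classifier_spec()].
#' @param corpus_cap Corpus subsampling cap (see [subsample_corpus()]).
#' @param dict_classes Build the dictionary from `"both"` classes or from
#'   `"disc"` candidates only.
#' @param seed Integer seed for subsampling and baseline dictionaries.
#' @param solver_max_iter,solver_tol Iteration budget and stopping tolerance
#'   for the sparse-selection solver.
#' @return An object of class `lfsa_model`: `dictionary`, `classifier`, `M`.
#' @export
train_lfsa <- function(regions, M = 10L, Dsize = 90L,
                       dict_method = c("sparse", "kmeans", "random"),
                       lambda = "auto", spec = classifier_spec(),
                       corpus_cap = 5000L,
                       dict_classes = c("both", "disc"), seed = 1L,
                       solver_max_iter = 500L, solver_tol = 1e-6) {
  dict_method <- match.arg(dict_method)
  dict_classes <- match.arg(dict_classes)
  pool <- if (dict_classes == "disc") {
    Filter(function(r) r$label == "disc", regions)
  } else regions
  corpus <- build_corpus(lapply(pool, partition_patches, M = M))
  corpus <- subsample_corpus(corpus, corpus_cap, seed = seed)
  dict <- switch(dict_method,
    sparse = sparse_dictionary(corpus, Dsize, lambda = lambda,
                               max_iter = solver_max_iter, tol = solver_tol),
    kmeans = kmeans_dictionary(corpus, Dsize, seed = seed),
    random = random_dictionary(corpus, Dsize, seed = seed)
  )
  dict$M <- M
  features <- spectrum_features(regions, dict, M)
  classifier <- train_classifier(features, spec)
  structure(list(dictionary = dict, classifier = classifier, M = M),
            class = "lfsa_model")
}

#' @export
print.lfsa_model <- function(x, ...) {
  cat(sprintf("<lfsa_model> M = %d, Dsize = %d (%s dictionary), %s classifier\n",
              x$M, x$dictionary$Dsize, x$dictionary$method,
              x$classifier$kind))
  invisible(x)
}

#' Detect the optic disc in a full fundus image
#'
#' Proposes `n_props` candidate windows on the red plane, scores each with
#' the trained model, and returns the centre of the highest-scoring
#' disc-classified candidate. If no candidate is classified as a disc, the
#' highest-scoring candidate is still returned with `disc_found = FALSE`.
#'
#' @param image A standardized [fundus_image()] or a red-plane matrix.
#' @param model An [train_lfsa()] model.
#' @param n_props Number of candidate windows to propose.
#' @param annotation Optional [disc_annotation()]; adds a `success` column
#'   via [detection_success()].
#' @param ... Passed to [propose_candidates()].
#' @return A one-row tibble: `source_id`, `center_row`, `center_col`,
#'   `score`, `disc_found`, and (when annotated) `success`.
#' @export
detect_disc <- function(image, model, n_props = 5L, annotation = NULL, ...) {
  stopifnot(inherits(model, "lfsa_model"))
  if (inherits(image, "fundus_image")) {
    red <- red_channel(image); sid <- image$source_id
  } else {
    red <- image; sid <- "image"
  }
  cands <- propose_candidates(red, n_props, source_id = sid, ...)
  feats <- spectrum_features(cands, model$dictionary, model$M)
  pred <- predict(model$classifier, feats)
  disc_idx <- which(pred$.pred == "disc")
  if (length(disc_idx) > 0L) {
    win <- disc_idx[which.max(pred$.score[disc_idx])]
    found <- TRUE
  } else {
    win <- which.max(pred$.score)
    found <- FALSE
  }
  ctr <- cands[[win]]$center
  out <- tibble::tibble(source_id = sid, center_row = ctr[1],
                        center_col = ctr[2], score = pred$.score[win],
                        disc_found = found)
  if (!is.null(annotation)) {
    out$success <- detection_success(ctr, annotation)
  }
  out
}

#' Run detection over a set of annotated images
#'
#' Applies [detect_disc()] to each image and reports per-image outcomes and
#' the overall success rate (the fraction of images whose detected centre
#' falls within the true disc).
#'
#' @param images A list where each element is either a [fundus_image()] or a
#'   list with elements `image` and (optionally) `annotation`, as returned by
#'   [synth_fundus_image()].
#' @param model An `lfsa_model`.
#' @param n_props Candidates proposed per image.
#' @param ... Passed to [detect_disc()].
#' @return A tibble of class `lfsa_detection`, one row per image; `glance()`
#'   gives the success rate over annotated images.
#' @export
run_detect <- function(images, model, n_props = 5L, ...) {
  rows <- purrr::map(images, function(el) {
    if (inherits(el, "fundus_image")) {
      detect_disc(el, model, n_props = n_props, ...)
    } else {
      detect_disc(el$image, model, n_props = n_props,
                  annotation = el$annotation, ...)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lfsa_detection", class(out))
  out
}

#' @rdname run_detect
#' @param x An `lfsa_detection` tibble.
#' @param ... Unused.
#' @export
glance.lfsa_detection <- function(x, ...) {
  ann <- "success" %in% names(x)
  tibble::tibble(
    images = nrow(x),
    annotated = if (ann) sum(!is.na(x$success)) else 0L,
    success_rate = if (ann) mean(x$success, na.rm = TRUE) else NA_real_,
    disc_found_rate = mean(x$disc_found)
  )
}

#' Parameter-grid evaluation
#'
#' Evaluates the method over a grid of patch sizes, dictionary sizes,
#' dictionary-selection methods and classifiers, reporting the repeated
#' holdout accuracy (mean and sd) and the reconstruction error of each cell
#' — the shape of the method's parameter-selection tables.
#'
#' For each `(M, dict_method)` the dictionary is fitted once on a stratified
#' `train_frac` "dictionary pool" of the candidates; for the sparse and
#' random methods the dictionaries are nested across `Dsize` (top-ranked
#' atoms, or a fixed random permutation truncated), so the reconstruction
#' error is exactly non-increasing in `Dsize`. Reconstruction error is
#' measured on the candidates outside the dictionary pool.
#'
#' @param regions List of labelled [candidate_region()] objects.
#' @param M_grid Patch sides to evaluate.
#' @param Dsize_grid Dictionary sizes; either a vector (used for every `M`)
#'   or a named list mapping `as.character(M)` to a vector.
#' @param dict_methods Subset of `c("sparse", "kmeans", "random")`.
#' @param classifiers Subset of `c("svm", "knn", "svdd")`.
#' @param lambda Sparse-method regularization (`"auto"` by default).
#' @param train_frac,repeats Repeated-holdout protocol passed to
#'   [evaluate_split()].
#' @param corpus_cap Corpus subsampling cap.
#' @param seed Integer seed.
#' @param solver_max_iter,solver_tol Iteration budget and stopping tolerance
#'   for the sparse-selection solver.
#' @param ... Passed to [classifier_spec()].
#' @return A tibble of class `lfsa_grid`: `M`, `Dsize`, `dict_method`,
#'   `classifier`, `mean_accuracy`, `sd_accuracy`, `r_error`. Infeasible
#'   cells (`Dsize` larger than the corpus) are `NA`.
#' @export
run_grid <- function(regions, M_grid = 10L, Dsize_grid = c(10L, 30L, 50L, 70L, 90L),
                     dict_methods = c("sparse", "kmeans", "random"),
                     classifiers = "svm", lambda = "auto",
                     train_frac = 0.7, repeats = 10L,
                     corpus_cap = 5000L, seed = 1L,
                     solver_max_iter = 500L, solver_tol = 1e-6, ...) {
  labels <- vapply(regions, `[[`, character(1), "label")
  dict_pool <- withr::with_seed(seed, {
    idx <- logical(length(regions))
    for (lv in unique(labels)) {
      pool <- which(labels == lv)
      idx[sample(pool, round(train_frac * length(pool)))] <- TRUE
    }
    idx
  })
  holdout <- regions[!dict_pool]

  out <- list()
  for (M in M_grid) {
    grids_pool <- lapply(regions[dict_pool], partition_patches, M = M)
    corpus <- subsample_corpus(build_corpus(grids_pool), corpus_cap,
                               seed = seed)
    dsizes <- if (is.list(Dsize_grid)) Dsize_grid[[as.character(M)]] else Dsize_grid
    sel <- if ("sparse" %in% dict_methods) {
      solve_selection_for(corpus, max(dsizes), lambda = lambda,
                          max_iter = solver_max_iter, tol = solver_tol)
    }
    rand_perm <- withr::with_seed(seed, sample.int(corpus$N))
    for (method in dict_methods) {
      for (Dsize in dsizes) {
        if (Dsize > corpus$N) {
          for (cls in classifiers) {
            out[[length(out) + 1L]] <- tibble::tibble(
              M = M, Dsize = Dsize, dict_method = method, classifier = cls,
              mean_accuracy = NA_real_, sd_accuracy = NA_real_,
              r_error = NA_real_)
          }
          next
        }
        dict <- switch(method,
          sparse = rank_and_select(sel, corpus, Dsize),
          kmeans = kmeans_dictionary(corpus, Dsize, seed = seed),
          random = new_dictionary(
            corpus$X[, rand_perm[seq_len(Dsize)], drop = FALSE],
            rand_perm[seq_len(Dsize)], "random", M = corpus$M)
        )
        dict$M <- M
        rerr <- reconstruction_error(holdout, dict, M)
        feats <- spectrum_features(regions, dict, M)
        for (cls in classifiers) {
          ev <- glance(evaluate_split(
            feats, classifier_spec(kind = cls, seed = seed, ...),
            train_frac = train_frac, repeats = repeats, seed = seed))
          out[[length(out) + 1L]] <- tibble::tibble(
            M = M, Dsize = Dsize, dict_method = method, classifier = cls,
            mean_accuracy = ev$mean_accuracy, sd_accuracy = ev$sd_accuracy,
            r_error = rerr)
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("lfsa_grid", class(res))
  res
}

#' Save / load a trained model
#'
#' Persists the dictionary, normalizer and classifier as one file.
#'
#' @param model An `lfsa_model`.
#' @param path File path.
#' @return `save_lfsa_model()` returns `path` invisibly; `load_lfsa_model()`
#'   returns the model.
#' @export
save_lfsa_model <- function(model, path) {
  stopifnot(inherits(model, "lfsa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lfsa_model
#' @export
load_lfsa_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lfsa_model"))
  model
}
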