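#' Stratified cross-validation fold assignment
#'
#' Strata are classes (qualitative response) or equal-frequency response bins
#' (quantitative, default deciles); within each stratum members are shuffled
#' and dealt to folds round-robin, so fold sizes and response distributions
#' stay balanced. Deterministic given the seed.
#'
#' @param response Response vector.
#' @param folds Number of folds.
#' @param n_bins Stratification bins for a continuous response.
#' @param seed Integer seed.
#' @return An integer vector of fold memberships in `1:folds`.
#' @export
make_folds <- function(response, folds = 5, n_bins = 10, seed = 1) {
  n <- length(response)
  stopifnot(folds >= 2, n >= folds)
  stratum <- if (response_task(response) == "classification") {
    as.integer(as_class_factor(response))
  } else {
    dplyr::ntile(response, min(n_bins, n))
  }
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in split(seq_len(n), stratum)) {
      idx <- if (length(s) > 1) s[sample.int(length(s))] else s
      # offset staggers strata so small strata do not pile into fold 1
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- (offset + length(idx)) %% folds
    }
  })
  fold
}

#' Cross-validate a weighted kNN specification
#'
#' Fivefold (by default) stratified cross-validation of the full modelling
#' recipe: inside each fold the autoscaling is refit on the fold-training
#' rows only, k is re-optimized there when not fixed, and the held-out fold
#' is predicted. Out-of-fold predictions are pooled and summarised once —
#' the CV \eqn{Q^2} references the pooled squared errors against the
#' variance of the full training response, mirroring the external-\eqn{Q^2}
#' definition.
#'
#' @inheritParams wknn_fit
#' @param k Fixed neighbourhood size, or `NULL` to re-optimize inside each
#'   fold (nested CV on the fold-training rows).
#' @return An object of class `wknn_cv`: a list with `predictions` (tibble
#'   of `id`, `fold`, `observed`, `predicted`), `metrics` (one-row tibble),
#'   `folds`, `seed`, `k` (per-fold tibble).
#' @export
kfold_cv <- function(data, descriptors = NULL, k = NULL, k_range = 3:7,
                     weighting = "inverse", folds = 5, seed = 1,
                     eps = 1e-12) {
  cols <- descriptor_names(data, {{ descriptors }})
  n <- nrow(data)
  y <- data$response
  task <- response_task(y)
  seeds <- derive_seeds(seed, folds + 1L)
  fold <- make_folds(y, folds = folds, seed = seeds[1])

  if (task == "classification") {
    yf <- as_class_factor(y)
    for (f in seq_len(folds)) {
      if (nlevels(droplevels(yf[fold != f])) < nlevels(yf)) {
        stop("class absent from the training part of fold ", f, call. = FALSE)
      }
    }
  }

  ids <- chem_ids(data)
  pred <- vector("list", folds)
  kused <- integer(folds)
  for (f in seq_len(folds)) {
    train <- data[fold != f, ]
    test <- data[fold == f, ]
    kf <- k %||% optimize_k(train, descriptors = cols, k_range = k_range,
                            weighting = weighting,
                            folds = min(folds, nrow(train)),
                            seed = seeds[f + 1L], eps = eps)
    fit <- wknn_fit(train, descriptors = cols, k = kf, weighting = weighting,
                    eps = eps)
    p <- predict(fit, test)
    kused[f] <- kf
    pred[[f]] <- tibble::tibble(id = chem_ids(test), fold = f,
                                observed = test$response, predicted = p$.pred)
  }
  pred <- dplyr::bind_rows(pred)
  pred <- pred[match(ids, pred$id), ]

  metrics <- if (task == "continuous") {
    tibble::tibble(
      Q2 = q_squared(pred$observed, pred$predicted, obs_train = y),
      RMSE = rmse(pred$observed, pred$predicted)
    )
  } else {
    cc <- confusion_counts(pred$observed, pred$predicted)
    classification_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
  }

  structure(list(predictions = pred, metrics = metrics, task = task,
                 folds = folds, seed = seed,
                 k = tibble::tibble(fold = seq_len(folds), k = kused)),
            class = "wknn_cv")
}

#' @export
print.wknn_cv <- function(x, ...) {
  cat(x$folds, "-fold cross-validation (", x$task, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.wknn_cv <- function(x, ...) x$predictions

#' @export
glance.wknn_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(folds = x$folds, seed = x$seed), x$metrics)
}

#' Performance table across CV, training and test sets
#'
#' Produces the standard three-block performance summary for a fitted model:
#' pooled fivefold-CV statistics (\eqn{Q^2}/RMSE or BA), training (fitting)
#' statistics from exclude-self predictions (\eqn{R^2}/RMSE or BA), and
#' external test statistics (\eqn{R^2}/RMSEP or BA), together with the
#' number of chemicals in each set and the descriptor count.
#'
#' @param model A [wknn_fit()] model.
#' @param train The training table the model was fitted on.
#' @param test Optional external test table.
#' @param folds,seed Cross-validation settings.
#' @return An object of class `wknn_eval`: a tibble with one row per set.
#' @export
model_performance <- function(model, train, test = NULL, folds = 5, seed = 1) {
  stopifnot(inherits(model, "wknn"))
  cv <- kfold_cv(train, descriptors = model$descriptors, k = model$k,
                 weighting = model$weighting, folds = folds, seed = seed,
                 eps = model$eps)
  loo <- loo_predict(model)

  if (model$task == "continuous") {
    rows <- list(
      tibble::tibble(set = "cv", n = nrow(train), n_descriptors = length(model$descriptors),
                     Q2 = cv$metrics$Q2, R2 = NA_real_, RMSE = cv$metrics$RMSE),
      tibble::tibble(set = "train", n = nrow(train), n_descriptors = length(model$descriptors),
                     Q2 = NA_real_,
                     R2 = r_squared(as.numeric(loo$observed), as.numeric(loo$predicted)),
                     RMSE = rmse(as.numeric(loo$observed), as.numeric(loo$predicted)))
    )
    if (!is.null(test)) {
      p <- predict(model, test)
      rows[[3]] <- tibble::tibble(
        set = "test", n = nrow(test), n_descriptors = length(model$descriptors),
        Q2 = q_squared(test$response, p$.pred, obs_train = as.numeric(model$y)),
        R2 = r_squared(test$response, p$.pred),
        RMSE = rmsep(test$response, p$.pred))
    }
  } else {
    mk <- function(set, obs, pred, n) {
      cc <- confusion_counts(obs, pred)
      m <- classification_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
      dplyr::bind_cols(tibble::tibble(set = set, n = n,
                                      n_descriptors = length(model$descriptors)), m)
    }
    rows <- list(
      mk("cv", cv$predictions$observed, cv$predictions$predicted, nrow(train)),
      mk("train", loo$observed, loo$predicted, nrow(train))
    )
    if (!is.null(test)) {
      p <- predict(model, test)
      rows[[3]] <- mk("test", test$response, p$.pred, nrow(test))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wknn_eval", class(out))
  out
}

#' Write a performance table to a delimited file
#'
#' @param x A [model_performance()] table.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_performance <- function(x, path) {
  write_delimited(tibble::as_tibble(x), path)
  invisible(path)
}
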