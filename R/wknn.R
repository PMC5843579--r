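#' Fit a distance-weighted k-nearest-neighbour model
#'
#' The workhorse learner: predictions for a query chemical are formed from
#' its `k` nearest training chemicals in the autoscaled descriptor space,
#' each neighbour weighted by its Euclidean distance so that closer
#' neighbours contribute more. Continuous endpoints use the weighted mean of
#' the neighbour responses; qualitative endpoints take the class with the
#' largest summed weight. A query that coincides exactly with training
#' chemicals (distance 0) receives the mean (or majority) of those exact
#' matches.
#'
#' The training descriptors are autoscaled to zero mean and unit sample
#' standard deviation and the parameters saved; every later query is scaled
#' with the same parameters. When `k = NULL` it is chosen by stratified
#' cross-validation over `k_range` (lowest CV error, ties to the smallest
#' k).
#'
#' @param data Training table with a `response` column and descriptor
#'   columns.
#' @param descriptors Descriptor selection (see [descriptor_names()]).
#' @param k Number of neighbours, or `NULL` to optimize over `k_range`.
#' @param k_range Candidate neighbourhood sizes (default 3 to 7).
#' @param weighting Neighbour weighting scheme: `"inverse"`
#'   (\eqn{w_i \propto 1/\max(d_i, \epsilon)}, the default), `"shepard"`
#'   (\eqn{1/(1+d)}), or `"exponential"` (\eqn{e^{-d}}).
#' @param folds,seed Cross-validation folds and seed used when optimizing k.
#' @param eps Floor applied to distances in the inverse weighting scheme.
#' @return An object of class `wknn` with components `X` (scaled training
#'   matrix), `y`, `task`, `k`, `weighting`, `scaler`, `descriptors`, `ids`,
#'   `structure_key`.
#' @export
#' @examples
#' sim <- simulate_qspr(n = 60, p = 4, informative = c(d01 = 1, d02 = 1), seed = 3)
#' fit <- wknn_fit(sim, k = 5)
#' predict(fit, sim[1:3, ])
wknn_fit <- function(data, descriptors = NULL, k = NULL, k_range = 3:7,
                     weighting = c("inverse", "shepard", "exponential"),
                     folds = 5, seed = 1, eps = 1e-12) {
  weighting <- match.arg(weighting)
  cols <- descriptor_names(data, {{ descriptors }})
  if (length(cols) == 0) stop("no descriptor columns", call. = FALSE)
  if (!"response" %in% names(data)) stop("data must have a response column",
                                         call. = FALSE)
  y <- data$response
  if (anyNA(y)) stop("missing responses", call. = FALSE)
  task <- response_task(y)
  if (task == "classification") {
    y <- as_class_factor(y)
    if (nlevels(y) < 2) stop("classification needs at least 2 classes",
                             call. = FALSE)
  }

  scaler <- fit_scaler(data, cols)
  X <- descriptor_matrix(apply_scaler(data, scaler), cols)

  if (is.null(k)) {
    k <- optimize_k(data, descriptors = cols, k_range = k_range,
                    weighting = weighting, folds = folds, seed = seed,
                    eps = eps)
  }
  if (k > nrow(X)) stop("k exceeds the number of training chemicals", call. = FALSE)

  structure(list(
    X = X, y = y, task = task, k = as.integer(k), weighting = weighting,
    eps = eps, scaler = scaler, descriptors = cols,
    ids = chem_ids(data),
    structure_key = if ("structure_key" %in% names(data))
      as.character(data$structure_key) else rep(NA_character_, nrow(data)),
    response_name = "response", seed = seed
  ), class = "wknn")
}

# Scale a query table into the model frame and return the descriptor matrix.
query_matrix <- function(object, new_data) {
  missing <- setdiff(object$descriptors, names(new_data))
  if (length(missing) > 0) {
    stop("descriptor column(s) missing from new data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  descriptor_matrix(apply_scaler(new_data, object$scaler), object$descriptors)
}

#' Predict with a weighted kNN model
#'
#' @param object A [wknn_fit()] model.
#' @param new_data A table with the model's descriptor columns (unscaled; the
#'   saved training scaling is applied internally).
#' @param neighbors Also return the neighbour evidence as a nested
#'   list-column of tibbles.
#' @param ... Unused.
#' @return A tibble with columns `id` and `.pred` (plus `neighbors` when
#'   requested).
#' @export
predict.wknn <- function(object, new_data, neighbors = FALSE, ...) {
  Xq <- query_matrix(object, new_data)
  scheme <- weighting_scheme_code(object$weighting)
  pred <- if (object$task == "continuous") {
    cpp_wknn_predict(object$X, as.numeric(object$y), Xq, object$k, scheme,
                     object$eps)
  } else {
    cls <- cpp_wknn_classify(object$X, as.integer(object$y),
                             nlevels(object$y), Xq, object$k, scheme,
                             object$eps)
    factor(levels(object$y)[cls], levels = levels(object$y))
  }
  out <- tibble::tibble(id = chem_ids(new_data), .pred = pred)
  if (neighbors) {
    nb <- find_neighbors(object, new_data)
    out$neighbors <- lapply(split(nb, factor(nb$query_id, levels = out$id)),
                            tibble::as_tibble)
  }
  out
}

#' Nearest training neighbours of query chemicals
#'
#' @param object A [wknn_fit()] model.
#' @param new_data Query table (unscaled descriptors).
#' @param k Number of neighbours; defaults to the model's `k`.
#' @return A tibble with one row per query-neighbour pair: `query_id`,
#'   `rank`, `neighbor_id`, `structure_key`, `response`, `distance`, and the
#'   normalized `weight` (weights within one query sum to 1). Distances are
#'   non-decreasing within a query; ties at the k-th distance keep
#'   training-set order.
#' @export
find_neighbors <- function(object, new_data, k = NULL) {
  k <- as.integer(k %||% object$k)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  k <- min(k, nrow(object$X))
  Xq <- query_matrix(object, new_data)
  nn <- cpp_knn_neighbors(object$X, Xq, k)
  qids <- chem_ids(new_data)
  out <- vector("list", nrow(Xq))
  for (q in seq_len(nrow(Xq))) {
    idx <- nn$index[q, ]
    d <- nn$distance[q, ]
    w <- scheme_weight(d, object$weighting, object$eps)
    out[[q]] <- tibble::tibble(
      query_id = qids[q], rank = seq_len(k),
      neighbor_id = object$ids[idx],
      structure_key = object$structure_key[idx],
      response = object$y[idx],
      distance = d, weight = w / sum(w)
    )
  }
  dplyr::bind_rows(out)
}

#' Leave-one-out predictions on the training set
#'
#' Each training chemical is predicted from the remaining n - 1 using the
#' model's k and weighting. These exclude-self predictions double as the
#' model's fitting statistics (in-sample kNN predictions are trivially
#' perfect) and feed the neighbour-accuracy part of the applicability-domain
#' assessment.
#'
#' @param object A [wknn_fit()] model.
#' @return A tibble with columns `id`, `observed`, `predicted`.
#' @export
loo_predict <- function(object) {
  stopifnot(inherits(object, "wknn"))
  if (nrow(object$X) <= object$k) {
    stop("leave-one-out needs more training chemicals than k", call. = FALSE)
  }
  scheme <- weighting_scheme_code(object$weighting)
  pred <- if (object$task == "continuous") {
    cpp_loo_predict(object$X, as.numeric(object$y), object$k, scheme, object$eps)
  } else {
    cls <- cpp_loo_classify(object$X, as.integer(object$y), nlevels(object$y),
                            object$k, scheme, object$eps)
    factor(levels(object$y)[cls], levels = levels(object$y))
  }
  tibble::tibble(id = object$ids, observed = object$y, predicted = pred)
}

#' Choose k by cross-validated error
#'
#' Runs stratified `folds`-fold cross-validation on the autoscaled training
#' table for every k in `k_range` (a single neighbour sort per fold serves
#' all k values) and returns the k with the lowest pooled CV error —
#' misclassification rate for qualitative endpoints, RMSE for quantitative
#' ones. Ties go to the smallest k.
#'
#' @inheritParams wknn_fit
#' @return The selected integer k.
#' @export
optimize_k <- function(data, descriptors = NULL, k_range = 3:7,
                       weighting = "inverse", folds = 5, seed = 1,
                       eps = 1e-12) {
  cols <- descriptor_names(data, {{ descriptors }})
  n <- nrow(data)
  if (n < folds) stop("fewer training chemicals than folds", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > n - 1) {
    stop("k_range must lie within [1, n_train - 1]", call. = FALSE)
  }
  scaler <- fit_scaler(data, cols)
  X <- descriptor_matrix(apply_scaler(data, scaler), cols)
  y <- data$response
  fold <- make_folds(y, folds = folds, seed = seed)
  scheme <- weighting_scheme_code(weighting)

  if (response_task(y) == "continuous") {
    P <- cpp_cv_predict(X, as.numeric(y), fold, k_range, scheme, eps)
    err <- apply(P, 2, function(p) rmse(as.numeric(y), p))
  } else {
    yf <- as_class_factor(y)
    P <- cpp_cv_classify(X, as.integer(yf), nlevels(yf), fold, k_range,
                         scheme, eps)
    err <- apply(P, 2, function(p) mean(p != as.integer(yf)))
  }
  # ties (up to float noise) go to the smallest k
  k_range[which(err <= min(err) + 1e-10)[1]]
}

#' @export
print.wknn <- function(x, ...) {
  cat("Weighted kNN model (", x$task, ")\n", sep = "")
  cat("  training chemicals:", nrow(x$X), "\n")
  cat("  descriptors:", length(x$descriptors), "\n")
  cat("  k:", x$k, "  weighting:", x$weighting, "\n")
  invisible(x)
}

#' Tidy a weighted kNN model
#'
#' @param x A [wknn_fit()] model.
#' @param ... Unused.
#' @return Per-training-chemical leave-one-out predictions and residuals.
#' @export
tidy.wknn <- function(x, ...) {
  loo <- loo_predict(x)
  if (x$task == "continuous") {
    loo$residual <- loo$observed - loo$predicted
  } else {
    loo$correct <- loo$observed == loo$predicted
  }
  loo
}

#' One-row summary of a weighted kNN model
#'
#' Fitting statistics are computed from exclude-self (leave-one-out)
#' predictions.
#'
#' @param x A [wknn_fit()] model.
#' @param ... Unused.
#' @return A one-row tibble: n, p, k, weighting, and `R2`/`RMSE` or `BA`.
#' @export
glance.wknn <- function(x, ...) {
  loo <- loo_predict(x)
  base <- tibble::tibble(n = nrow(x$X), p = length(x$descriptors), k = x$k,
                         task = x$task, weighting = x$weighting)
  if (x$task == "continuous") {
    dplyr::mutate(base,
                  R2 = r_squared(as.numeric(loo$observed), as.numeric(loo$predicted)),
                  RMSE = rmse(as.numeric(loo$observed), as.numeric(loo$predicted)))
  } else {
    dplyr::mutate(base, BA = balanced_accuracy(loo$observed, loo$predicted))
  }
}
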