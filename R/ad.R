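#' Fit the two-tier applicability-domain assessor
#'
#' Combines a global and a local view of whether a query chemical sits
#' inside the chemical space the model was trained on:
#'
#' * **Global leverage.** The leverage of a query is
#'   \eqn{h = x^T (X^T X)^{-1} x} on the scaled training matrix restricted to
#'   the model descriptors — the diagonal of the hat matrix
#'   \eqn{H = X (X^T X)^{-1} X^T} for training rows, proportional to the
#'   Mahalanobis distance from the training centroid. Queries with
#'   \eqn{h > 3p/n} fall outside the global domain. A rank-deficient
#'   \eqn{X^T X} is inverted with the Moore–Penrose pseudo-inverse.
#' * **Local 5-NN index.** A continuous `[0, 1]` similarity of the query to
#'   its five nearest training neighbours:
#'   \eqn{\exp(-\bar d_w / c)} where \eqn{\bar d_w} is the weighted mean
#'   5-NN distance (same weighting as the model) and \eqn{c} is calibrated on
#'   the training set so that the 95th percentile of the training chemicals'
#'   own leave-one-out \eqn{\bar d_w} values maps to 0.4 — anchoring the
#'   0.4/0.6 interpretation bands to the data's own distance scale. A query
#'   identical to a training chemical scores exactly 1.
#' * **Confidence level.** The distance-weighted leave-one-out accuracy of
#'   the five nearest neighbours:
#'   \eqn{\sum_j w_j a_j / \sum_j w_j} with
#'   \eqn{a_j = 1 / (1 + |y_j - \hat y_j^{LOO}| / s)} for continuous
#'   responses (s = leave-one-out RMSE of the training set) and
#'   \eqn{a_j = 1} if neighbour j is classified correctly in leave-one-out,
#'   0 otherwise, for classes.
#'
#' @param model A [wknn_fit()] model.
#' @param n_neighbors Neighbours used by the local index and confidence
#'   (default 5; fewer training chemicals triggers a warning and uses all).
#' @param calibration_q Quantile of training leave-one-out weighted 5-NN
#'   distances pinned to a local index of 0.4.
#' @param tol Relative tolerance of the pseudo-inverse.
#' @return An object of class `wknn_ad` storing the generalized inverse, the
#'   `3p/n` threshold, the training leverages, the local-index scale `c`,
#'   and the training leave-one-out predictions.
#' @export
fit_ad <- function(model, n_neighbors = 5, calibration_q = 0.95,
                   tol = .Machine$double.eps^0.5) {
  stopifnot(inherits(model, "wknn"))
  X <- model$X
  n <- nrow(X); p <- ncol(X)
  if (n == 0) stop("empty training matrix", call. = FALSE)
  if (n_neighbors > n - 1) {
    warning("fewer than ", n_neighbors + 1,
            " training chemicals; local index uses all ", n - 1)
    n_neighbors <- n - 1L
  }

  G <- MASS::ginv(crossprod(X), tol = tol)
  train_leverage <- unname(rowSums((X %*% G) * X))
  threshold <- 3 * p / n

  loo <- loo_predict(model)
  s <- if (model$task == "continuous") {
    max(rmse(as.numeric(loo$observed), as.numeric(loo$predicted)), 1e-12)
  } else {
    1
  }

  # training chemicals' own weighted-mean 5-NN distance, self excluded
  nn <- cpp_knn_neighbors(X, X, min(n_neighbors + 1L, n))
  dbar <- vapply(seq_len(n), function(i) {
    d <- nn$distance[i, ]
    idx <- nn$index[i, ]
    keep <- which(idx != i)
    if (length(keep) > n_neighbors) keep <- keep[seq_len(n_neighbors)]
    d <- d[keep]
    w <- scheme_weight(d, model$weighting, model$eps)
    sum(w * d) / sum(w)
  }, numeric(1))
  q <- quantile(dbar, calibration_q, names = FALSE, type = 7)
  c_scale <- max(q, 1e-12) / log(1 / 0.4)

  structure(list(model = model, G = G, threshold = threshold,
                 train_leverage = train_leverage, c_scale = c_scale,
                 n_neighbors = as.integer(n_neighbors), loo = loo, s = s,
                 train_dbar = dbar),
            class = "wknn_ad")
}

#' @export
print.wknn_ad <- function(x, ...) {
  cat("Applicability domain: leverage threshold 3p/n =",
      format(x$threshold, digits = 4), "\n")
  cat("  local index scale c =", format(x$c_scale, digits = 4),
      "(", x$n_neighbors, "nearest neighbours )\n")
  invisible(x)
}

#' Tidy an applicability-domain model
#'
#' @param x A [fit_ad()] object.
#' @param ... Unused.
#' @return Training-set leverages and weighted 5-NN distances per chemical.
#' @export
tidy.wknn_ad <- function(x, ...) {
  tibble::tibble(id = x$model$ids, leverage = x$train_leverage,
                 inside = x$train_leverage <= x$threshold,
                 dbar = x$train_dbar)
}

#' Leverage of query chemicals
#'
#' @param ad A [fit_ad()] object.
#' @param new_data Query table (unscaled descriptors).
#' @return A tibble with `id`, `leverage` and `inside`
#'   (`leverage <= 3p/n`).
#' @export
query_leverage <- function(ad, new_data) {
  stopifnot(inherits(ad, "wknn_ad"))
  Xq <- query_matrix(ad$model, new_data)
  h <- unname(rowSums((Xq %*% ad$G) * Xq))
  tibble::tibble(id = chem_ids(new_data), leverage = h,
                 inside = h <= ad$threshold)
}

# weighted-mean distance to the nearest training neighbours, one per query
query_dbar <- function(ad, Xq) {
  nn <- cpp_knn_neighbors(ad$model$X, Xq, ad$n_neighbors)
  vapply(seq_len(nrow(Xq)), function(q) {
    d <- nn$distance[q, ]
    w <- scheme_weight(d, ad$model$weighting, ad$model$eps)
    sum(w * d) / sum(w)
  }, numeric(1))
}

#' Local applicability-domain index
#'
#' @inheritParams query_leverage
#' @return A numeric vector in `[0, 1]`, one value per query; exactly 1 for
#'   a query identical to a training chemical, decreasing with the weighted
#'   mean distance to the five nearest training neighbours.
#' @export
local_ad_index <- function(ad, new_data) {
  stopifnot(inherits(ad, "wknn_ad"))
  Xq <- query_matrix(ad$model, new_data)
  nn <- cpp_knn_neighbors(ad$model$X, Xq, ad$n_neighbors)
  dbar <- query_dbar(ad, Xq)
  idx <- exp(-dbar / ad$c_scale)
  idx[nn$distance[, 1] == 0] <- 1  # exact training match
  pmin(pmax(idx, 0), 1)
}

#' Confidence level of query predictions
#'
#' @inheritParams query_leverage
#' @return A numeric vector in `[0, 1]`: the distance-weighted leave-one-out
#'   accuracy of the query's five nearest training neighbours.
#' @export
confidence_level <- function(ad, new_data) {
  stopifnot(inherits(ad, "wknn_ad"))
  Xq <- query_matrix(ad$model, new_data)
  nn <- cpp_knn_neighbors(ad$model$X, Xq, ad$n_neighbors)
  loo <- ad$loo
  acc <- if (ad$model$task == "continuous") {
    err <- abs(as.numeric(loo$observed) - as.numeric(loo$predicted))
    1 / (1 + err / ad$s)
  } else {
    as.numeric(loo$observed == loo$predicted)
  }
  vapply(seq_len(nrow(Xq)), function(q) {
    d <- nn$distance[q, ]
    w <- scheme_weight(d, ad$model$weighting, ad$model$eps)
    sum(w * acc[nn$index[q, ]]) / sum(w)
  }, numeric(1))
}

#' Interpret the two applicability-domain tiers
#'
#' Deterministic mapping from (global leverage verdict, local index) to a
#' reliability category; the `[0.4, 0.6]` band is closed at both ends:
#'
#' * outside global AD, index < 0.4 — `unreliable`
#' * outside, 0.4–0.6 — `boundary_average` (on the boundary of the training
#'   set, but with quite similar neighbours)
#' * outside, > 0.6 — `boundary_trusted`
#' * inside, 0.4–0.6 — `gap_caution` (the query falls in a gap of the
#'   model's chemical space but within the training-set boundary)
#' * inside, > 0.6 — `reliable`
#'
#' The combination inside/low index (< 0.4) is not one of the four
#' documented cases; it is mapped to `gap_caution` and flagged.
#'
#' @param global_inside Logical vector: leverage within the `3p/n` threshold.
#' @param local_index Numeric vector in `[0, 1]`.
#' @return A factor with levels `unreliable`, `boundary_average`,
#'   `boundary_trusted`, `gap_caution`, `reliable`.
#' @export
interpret_ad <- function(global_inside, local_index) {
  stopifnot(length(global_inside) == length(local_index),
            all(local_index >= 0 & local_index <= 1))
  band <- ifelse(local_index < 0.4, "low",
                 ifelse(local_index <= 0.6, "mid", "high"))
  out <- ifelse(!global_inside,
                ifelse(band == "low", "unreliable",
                       ifelse(band == "mid", "boundary_average",
                              "boundary_trusted")),
                ifelse(band == "high", "reliable", "gap_caution"))
  factor(out, levels = c("unreliable", "boundary_average", "boundary_trusted",
                         "gap_caution", "reliable"))
}

#' Assess the applicability domain of query chemicals
#'
#' @inheritParams query_leverage
#' @return A tibble with one row per query: `id`, `leverage`,
#'   `global_inside`, `local_ad_index`, `confidence`, `interpretation` and
#'   `flagged` (`TRUE` for the undocumented inside/low-index combination).
#' @export
assess_ad <- function(ad, new_data) {
  lev <- query_leverage(ad, new_data)
  idx <- local_ad_index(ad, new_data)
  conf <- confidence_level(ad, new_data)
  interp <- interpret_ad(lev$inside, idx)
  tibble::tibble(
    id = lev$id, leverage = lev$leverage, global_inside = lev$inside,
    local_ad_index = idx, confidence = conf, interpretation = interp,
    flagged = lev$inside & idx < 0.4
  )
}
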