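# Independent brute-force reference implementations used as oracles.
# Deliberately written with plain loops and base R, sharing no code with the
# package internals.

# stable neighbour order: ties broken by training index
brute_order <- function(d) order(d, seq_along(d))

brute_wknn_predict <- function(Xtr, y, q, k, eps = 1e-12) {
  d <- sqrt(colSums((t(Xtr) - q)^2))
  ord <- brute_order(d)[seq_len(k)]
  dd <- d[ord]
  if (any(dd == 0)) return(mean(y[ord][dd == 0]))
  w <- 1 / pmax(dd, eps)
  sum(w * y[ord]) / sum(w)
}

brute_wknn_classify <- function(Xtr, y, q, k, eps = 1e-12) {
  # y: factor; returns character label
  d <- sqrt(colSums((t(Xtr) - q)^2))
  ord <- brute_order(d)[seq_len(k)]
  dd <- d[ord]
  lv <- levels(y)
  score <- numeric(length(lv))
  if (any(dd == 0)) {
    for (j in which(dd == 0)) {
      score[match(y[ord[j]], lv)] <- score[match(y[ord[j]], lv)] + 1
    }
  } else {
    w <- 1 / pmax(dd, eps)
    for (j in seq_along(ord)) {
      score[match(y[ord[j]], lv)] <- score[match(y[ord[j]], lv)] + w[j]
    }
  }
  lv[which.max(score)]
}

brute_loo_predict <- function(X, y, k, eps = 1e-12) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- brute_wknn_predict(X[-i, , drop = FALSE], y[-i], X[i, ], k, eps)
  }
  out
}

# leave-one-out CV with per-fold autoscaling (the refit-without-i oracle)
brute_loo_refit <- function(data_x, y, k, eps = 1e-12) {
  n <- nrow(data_x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tr <- as.matrix(data_x[-i, , drop = FALSE])
    mu <- colMeans(tr)
    sdev <- apply(tr, 2, sd)
    trs <- scale(tr, center = mu, scale = sdev)
    qs <- (as.numeric(data_x[i, ]) - mu) / sdev
    out[i] <- brute_wknn_predict(trs, y[-i], qs, k, eps)
  }
  out
}

brute_hat_diag <- function(X) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  diag(H)
}

# exhaustive greedy correlation-filter oracle: repeatedly find the pair with
# the largest |r| above the threshold and drop the member with the largest
# mean |r| to all other surviving columns (ties: later input column).
brute_correlation_filter <- function(M, threshold) {
  alive <- seq_len(ncol(M))
  repeat {
    if (length(alive) < 2) break
    cm <- abs(cor(M[, alive, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    hit <- which(cm == max(cm), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    a <- alive[hit[1, 1]]; b <- alive[hit[1, 2]]
    mean_abs <- sapply(c(a, b), function(j) {
      others <- setdiff(alive, j)
      mean(abs(cor(M[, j], M[, others, drop = FALSE])))
    })
    drop_j <- if (mean_abs[1] > mean_abs[2]) a
              else if (mean_abs[2] > mean_abs[1]) b else max(a, b)
    alive <- setdiff(alive, drop_j)
  }
  alive
}

# build a wknn model object directly in scaled space (identity scaler),
# bypassing wknn_fit, for tests that reason about exact distances
make_scaled_model <- function(X, y, k, weighting = "inverse") {
  cols <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  colnames(X) <- cols
  scaler <- structure(
    tibble::tibble(descriptor = cols, mean = rep(0, length(cols)),
                   sd = rep(1, length(cols))),
    class = c("qspr_scaler", "tbl_df", "tbl", "data.frame"))
  ids <- sprintf("T%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  structure(list(
    X = X, y = y,
    task = if (is.numeric(y)) "continuous" else "classification",
    k = as.integer(k), weighting = weighting, eps = 1e-12, scaler = scaler,
    descriptors = cols, ids = ids,
    structure_key = rep(NA_character_, nrow(X)),
    response_name = "response", seed = 1L
  ), class = "wknn")
}

scaled_query_tbl <- function(X) {
  out <- tibble::as_tibble(as.data.frame(X))
  out$id <- sprintf("Q%03d", seq_len(nrow(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
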