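test_that("training leverages follow x^2 / sum(x^2) in one dimension", {
  # two 1-D chemicals scale to +-1/sqrt(2): h_i = x_i^2 / sum(x^2) = 0.5
  train <- tibble::tibble(id = c("t1", "t2"), response = c(0, 1),
                          x = c(0, 2))
  fit <- wknn_fit(train, k = 1)
  ad <- fit_ad(fit, n_neighbors = 1)
  expect_equal(ad$train_leverage, c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(ad$threshold, 3 * 1 / 2)
})

test_that("hat-matrix diagonal matches the dense oracle with trace p", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; p <- 4
    d <- tibble::tibble(id = as.character(1:n), response = rnorm(n))
    for (j in 1:p) d[[paste0("v", j)]] <- rnorm(n)
    fit <- wknn_fit(d, k = 3)
    ad <- fit_ad(fit)
    want <- brute_hat_diag(fit$X)
    expect_equal(ad$train_leverage, want, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(ad$train_leverage), p, tolerance = 1e-10)
    expect_true(all(ad$train_leverage >= -1e-12 & ad$train_leverage <= 1 + 1e-12))
  }
})

test_that("query leverage: centroid is 0, training rows match, far points exceed 3p/n", {
  sim <- simulate_qspr(n = 100, p = 5, informative = c(d01 = 1), seed = 2)
  fit <- wknn_fit(sim, k = 5)
  ad <- fit_ad(fit)

  centroid <- sim[1, ]
  for (col in descriptor_names(sim)) centroid[[col]] <- mean(sim[[col]])
  ql <- query_leverage(ad, centroid)
  expect_equal(ql$leverage, 0, tolerance = 1e-10)
  expect_true(ql$inside)

  ql_tr <- query_leverage(ad, sim[7, ])
  expect_equal(ql_tr$leverage, ad$train_leverage[7], tolerance = 1e-10)

  far <- sim[1, ]
  for (col in descriptor_names(sim)) far[[col]] <- 10
  qf <- query_leverage(ad, far)
  expect_gt(qf$leverage, ad$threshold)
  expect_false(qf$inside)
})

test_that("local AD index is 1 on training chemicals and low far away", {
  sim <- simulate_qspr(n = 100, p = 4, informative = c(d01 = 1), seed = 3)
  fit <- wknn_fit(sim, k = 5)
  ad <- fit_ad(fit)

  expect_equal(local_ad_index(ad, sim[3, ]), 1)

  far <- sim[1, ]
  for (col in descriptor_names(sim)) far[[col]] <- 10  # ~10 sigma out
  expect_lt(local_ad_index(ad, far), 0.4)
})

test_that("the local index never increases along a ray from the centroid", {
  sim <- simulate_qspr(n = 80, p = 3, seed = 4)
  fit <- wknn_fit(sim, k = 5)
  ad <- fit_ad(fit)
  direction <- c(1, -0.5, 2)
  idx <- vapply(seq(0, 8, by = 0.5), function(t) {
    q <- sim[1, ]
    cols <- descriptor_names(sim)
    for (j in seq_along(cols)) q[[cols[j]]] <- mean(sim[[cols[j]]]) +
        t * direction[j] * sd(sim[[cols[j]]])
    local_ad_index(ad, q)
  }, numeric(1))
  expect_true(all(diff(idx) <= 1e-9))
})

test_that("confidence is the distance-weighted LOO accuracy of the neighbours", {
  # duplicated training points with equal responses: all LOO errors are 0
  base <- simulate_qspr(n = 20, p = 2, informative = c(d01 = 1),
                        noise_sd = 0, seed = 5)
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, id = paste0(id, "b")))
  fit <- wknn_fit(dup, k = 3)
  ad <- fit_ad(fit)
  expect_equal(max(abs(ad$loo$observed - ad$loo$predicted)), 0)
  expect_equal(confidence_level(ad, base[2, ]), 1)

  # hand-built set: verify the formula sum(w a) / sum(w) independently
  sim <- simulate_qspr(n = 30, p = 3, informative = c(d01 = 1),
                       noise_sd = 0.5, seed = 6)
  fit2 <- wknn_fit(sim, k = 4)
  ad2 <- fit_ad(fit2)
  q <- simulate_qspr(n = 2, p = 3, seed = 7)[1, ]
  got <- confidence_level(ad2, q)
  nb <- find_neighbors(fit2, q, k = 5)
  loo <- ad2$loo
  err <- abs(as.numeric(loo$observed) - as.numeric(loo$predicted))
  s <- rmse(as.numeric(loo$observed), as.numeric(loo$predicted))
  a_j <- 1 / (1 + err[match(nb$neighbor_id, loo$id)] / s)
  w <- 1 / pmax(nb$distance, 1e-12)
  expect_equal(got, sum(w * a_j) / sum(w), tolerance = 1e-12)

  # in the limit of enormous neighbour LOO errors (accuracy scale s fixed)
  # confidence goes to 0
  ad_bad <- ad2
  ad_bad$loo$predicted <- ad_bad$loo$predicted + 1e9
  expect_lt(confidence_level(ad_bad, q), 1e-6)
})

test_that("the interpretation table covers all five cases with closed 0.4/0.6 bands", {
  expect_equal(as.character(interpret_ad(FALSE, 0.3)), "unreliable")
  expect_equal(as.character(interpret_ad(FALSE, 0.5)), "boundary_average")
  expect_equal(as.character(interpret_ad(FALSE, 0.65)), "boundary_trusted")
  expect_equal(as.character(interpret_ad(TRUE, 0.5)), "gap_caution")
  expect_equal(as.character(interpret_ad(TRUE, 0.7)), "reliable")
  # the undocumented inside/low combination also maps to gap_caution
  expect_equal(as.character(interpret_ad(TRUE, 0.3)), "gap_caution")
  # band endpoints are inside the "average" band
  expect_equal(as.character(interpret_ad(FALSE, 0.4)), "boundary_average")
  expect_equal(as.character(interpret_ad(FALSE, 0.6)), "boundary_average")
  expect_equal(as.character(interpret_ad(TRUE, 0.4)), "gap_caution")
  expect_equal(as.character(interpret_ad(TRUE, 0.6)), "gap_caution")
  # exactly one category for any input
  g <- expand.grid(inside = c(TRUE, FALSE), idx = seq(0, 1, by = 0.05))
  out <- interpret_ad(g$inside, g$idx)
  expect_false(anyNA(out))
})

test_that("assess_ad flags the inside/low-index combination", {
  sim <- simulate_qspr(n = 60, p = 6, seed = 8)
  fit <- wknn_fit(sim, k = 5)
  ad <- fit_ad(fit)
  adx <- assess_ad(ad, sim[1:10, ])
  expect_equal(adx$flagged, adx$global_inside & adx$local_ad_index < 0.4)
  expect_equal(as.character(adx$interpretation),
               as.character(interpret_ad(adx$global_inside,
                                         adx$local_ad_index)))
  expect_true(all(adx$local_ad_index >= 0 & adx$local_ad_index <= 1))
  expect_true(all(adx$confidence >= 0 & adx$confidence <= 1))
})

test_that("local index and confidence depend only on scaled distances", {
  # build two models in scaled space differing by a rigid rotation
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("v1", "v2")))
  y <- X[, 1] + rnorm(n, sd = 0.1)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  XR <- X %*% R
  colnames(XR) <- c("v1", "v2")

  m1 <- make_scaled_model(X, y, k = 4)
  m2 <- make_scaled_model(XR, y, k = 4)
  ad1 <- fit_ad(m1)
  ad2 <- fit_ad(m2)

  Q <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("v1", "v2")))
  QR <- Q %*% R
  colnames(QR) <- c("v1", "v2")
  expect_equal(local_ad_index(ad1, scaled_query_tbl(Q)),
               local_ad_index(ad2, scaled_query_tbl(QR)), tolerance = 1e-9)
  expect_equal(confidence_level(ad1, scaled_query_tbl(Q)),
               confidence_level(ad2, scaled_query_tbl(QR)), tolerance = 1e-9)
})

test_that("rank-deficient training matrices are handled by the pseudo-inverse", {
  d <- tibble::tibble(id = as.character(1:10), response = rnorm(10),
                      a = rnorm(10))
  d$b <- 2 * d$a  # collinear pair: X^T X is singular
  fit <- wknn_fit(d, k = 3)
  ad <- fit_ad(fit)
  expect_true(all(is.finite(ad$train_leverage)))
  ql <- query_leverage(ad, d[1, ])
  expect_true(is.finite(ql$leverage))
})
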