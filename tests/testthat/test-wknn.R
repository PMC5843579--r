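test_that("a query coinciding with a training chemical returns its value", {
  sim <- simulate_qspr(n = 20, p = 3, informative = c(d01 = 1), seed = 2)
  sim$response[5] <- 7.3
  fit <- wknn_fit(sim, k = 4)
  p <- predict(fit, sim[5, ])
  expect_equal(p$.pred, 7.3)
  nb <- find_neighbors(fit, sim[5, ])
  expect_equal(nb$neighbor_id[1], sim$id[5])
  expect_equal(nb$distance[1], 0)
})

test_that("neighbours come back sorted with normalized positive weights", {
  sim <- simulate_qspr(n = 30, p = 4, seed = 3)
  fit <- wknn_fit(sim, k = 5)
  nb <- find_neighbors(fit, sim[c(1, 9), ], k = 5)
  for (q in unique(nb$query_id)) {
    s <- nb[nb$query_id == q, ]
    expect_true(all(diff(s$distance) >= 0))
    expect_true(all(s$weight > 0))
    expect_equal(sum(s$weight), 1)
  }
})

test_that("neighbour search matches the exhaustive distance sort", {
  set.seed(10)
  sim <- simulate_qspr(n = 50, p = 6, informative = c(d01 = 1), seed = 10)
  fit <- wknn_fit(sim, k = 5)
  queries <- simulate_qspr(n = 8, p = 6, seed = 11)
  nb <- find_neighbors(fit, queries, k = 5)
  Xq <- as.matrix(apply_scaler(queries, fit$scaler)[fit$descriptors])
  for (q in seq_len(nrow(queries))) {
    d <- sqrt(colSums((t(fit$X) - Xq[q, ])^2))
    ord <- brute_order(d)[1:5]
    s <- nb[nb$query_id == queries$id[q], ]
    expect_equal(s$neighbor_id, fit$ids[ord])
    expect_equal(s$distance, unname(d[ord]), tolerance = 1e-12)
  }
})

test_that("inverse-distance weighting follows w_i = (1/d_i) / sum(1/d_j)", {
  # two 1-D training chemicals whose scaled coordinates are +-1/sqrt(2);
  # the query sits so the scaled distances have ratio 1:3, giving weights
  # 0.75 / 0.25 and prediction 0.75*0 + 0.25*4 = 1
  train <- tibble::tibble(id = c("t1", "t2"), response = c(0, 4),
                          x = c(0, sqrt(2)))
  fit <- wknn_fit(train, k = 2)
  query <- tibble::tibble(id = "q", x = -sqrt(2) / 2)
  nb <- find_neighbors(fit, query)
  expect_equal(nb$distance, c(sqrt(2) / 2, 3 * sqrt(2) / 2))
  expect_equal(nb$weight, c(0.75, 0.25))
  expect_equal(predict(fit, query)$.pred, 1.0)
})

test_that("equidistant neighbours average and exact matches dominate", {
  # 1-D symmetric training pair; query at the centre is equidistant
  train <- tibble::tibble(id = c("t1", "t2"), response = c(0, 2),
                          x = c(-1, 1))
  fit <- wknn_fit(train, k = 2)
  expect_equal(predict(fit, tibble::tibble(id = "q", x = 0))$.pred, 1.0)
  # sitting exactly on t1 short-circuits to its response
  expect_equal(predict(fit, tibble::tibble(id = "q", x = -1))$.pred, 0)
})

test_that("weighted kNN predictions equal the brute-force oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(10:50, 1); p <- sample(1:10, 1); k <- sample(1:min(7, n - 1), 1)
    sim <- simulate_qspr(n = n, p = p, informative = c(d01 = 1),
                         noise_sd = 0.5, seed = seed)
    fit <- wknn_fit(sim, k = k)
    m <- 5
    queries <- simulate_qspr(n = m, p = p, seed = seed + 1000)
    got <- predict(fit, queries)$.pred
    Xq <- as.matrix(apply_scaler(queries, fit$scaler)[fit$descriptors])
    want <- vapply(seq_len(m), function(q) {
      brute_wknn_predict(fit$X, as.numeric(fit$y), Xq[q, ], k)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("classification matches the brute-force weighted vote", {
  for (seed in 1:10) {
    sim <- simulate_qspr(n = 40, p = 4, informative = c(d01 = 2),
                         task = "classification", seed = seed)
    fit <- wknn_fit(sim, k = 5)
    queries <- simulate_qspr(n = 6, p = 4, seed = seed + 500)
    got <- as.character(predict(fit, queries)$.pred)
    Xq <- as.matrix(apply_scaler(queries, fit$scaler)[fit$descriptors])
    want <- vapply(seq_len(6), function(q) {
      brute_wknn_classify(fit$X, fit$y, Xq[q, ], 5)
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("leave-one-out predictions refit without the held-out chemical", {
  sim <- simulate_qspr(n = 30, p = 3, informative = c(d01 = 1, d02 = 1),
                       noise_sd = 0.3, seed = 4)
  fit <- wknn_fit(sim, k = 4)
  loo <- loo_predict(fit)
  want <- brute_loo_predict(fit$X, as.numeric(fit$y), 4)
  expect_equal(loo$predicted, want, tolerance = 1e-10)

  # duplicated training rows with equal responses predict themselves exactly
  dup <- dplyr::bind_rows(sim, dplyr::mutate(sim[1:3, ], id = paste0(id, "b")))
  fit2 <- wknn_fit(dup, k = 3)
  loo2 <- loo_predict(fit2)
  at_dup <- loo2$id %in% c(dup$id[1:3], paste0(dup$id[1:3], "b"))
  expect_equal(loo2$predicted[at_dup], loo2$observed[at_dup])
})

test_that("with n = k + 1 every leave-one-out prediction uses all others", {
  train <- tibble::tibble(id = as.character(1:4), response = c(1, 2, 3, 10),
                          x = c(0, 1, 2, 5))
  fit <- wknn_fit(train, k = 3)
  loo <- loo_predict(fit)
  want <- brute_loo_predict(fit$X, train$response, 3)
  expect_equal(loo$predicted, want, tolerance = 1e-12)
})

test_that("predictions stay within the convex hull of neighbour responses", {
  sim <- simulate_qspr(n = 60, p = 4, informative = c(d01 = 1), seed = 5)
  fit <- wknn_fit(sim, k = 5)
  queries <- simulate_qspr(n = 20, p = 4, seed = 6)
  p <- predict(fit, queries, neighbors = TRUE)
  for (i in seq_len(nrow(p))) {
    resp <- as.numeric(p$neighbors[[i]]$response)
    expect_gte(p$.pred[i], min(resp) - 1e-12)
    expect_lte(p$.pred[i], max(resp) + 1e-12)
  }
})

test_that("prediction is invariant to training-set permutation off ties", {
  sim <- simulate_qspr(n = 40, p = 3, informative = c(d01 = 1), seed = 7)
  fit1 <- wknn_fit(sim, k = 5)
  perm <- sim[rev(seq_len(nrow(sim))), ]
  fit2 <- wknn_fit(perm, k = 5)
  queries <- simulate_qspr(n = 10, p = 3, seed = 8)
  expect_equal(predict(fit1, queries)$.pred, predict(fit2, queries)$.pred,
               tolerance = 1e-12)
})

test_that("k optimization minimizes CV error with deterministic ties", {
  # well-separated clusters: responses reproducible by any small k
  set.seed(30)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 8), ] + matrix(rnorm(64, sd = 0.05), ncol = 2)
  d <- tibble::tibble(id = as.character(1:32),
                      response = rep(c(1, 2, 3, 4), each = 8),
                      a = X[, 1], b = X[, 2])
  k <- optimize_k(d, k_range = 3:7, seed = 1)
  expect_equal(k, 3)  # all of 3..7 are perfect; ties go to the smallest

  expect_equal(optimize_k(d, k_range = c(3, 3), seed = 1), 3)

  noise <- simulate_qspr(n = 40, p = 3, informative = NULL, noise_sd = 1,
                         seed = 9)
  expect_equal(optimize_k(noise, seed = 2), optimize_k(noise, seed = 2))
})

test_that("descriptor selection accepts NULL variables, names and tidyselect", {
  sim <- simulate_qspr(n = 10, p = 3, seed = 1)
  all_cols <- c("d01", "d02", "d03")
  expect_equal(descriptor_names(sim), all_cols)
  nothing <- NULL
  expect_equal(descriptor_names(sim, nothing), all_cols)  # NULL via variable
  some <- c("d02", "d03")
  expect_equal(descriptor_names(sim, some), some)
  expect_equal(descriptor_names(sim, dplyr::starts_with("d0")), all_cols)
  expect_error(descriptor_names(sim, c("d01", "zz")), "zz")
  fit <- wknn_fit(sim, descriptors = nothing, k = 3)
  expect_equal(fit$descriptors, all_cols)
})

test_that("model inputs are validated", {
  sim <- simulate_qspr(n = 10, p = 2, seed = 1)
  expect_error(wknn_fit(sim, k = 11), "exceeds")
  fit <- wknn_fit(sim, k = 3)
  expect_error(predict(fit, sim[, c("id", "response", "d01")]), "d02")
  expect_error(optimize_k(sim, k_range = 3:20), "k_range")
})

test_that("glance and tidy summarise the fit", {
  sim <- simulate_qspr(n = 50, p = 3, informative = c(d01 = 1.5),
                       noise_sd = 0.2, seed = 12)
  fit <- wknn_fit(sim, k = 5)
  g <- glance(fit)
  expect_equal(g$n, 50)
  expect_equal(g$k, 5)
  expect_gt(g$R2, 0.5)
  td <- tidy(fit)
  expect_equal(nrow(td), 50)
  expect_equal(td$residual, td$observed - td$predicted)
})
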