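test_that("regression metrics satisfy their defining identities", {
  set.seed(1)
  obs <- rnorm(40); pred <- obs + rnorm(40, sd = 0.3)

  expect_equal(rmse(obs, obs), 0)
  expect_equal(rmse(c(3, -4) + c(0, 0), c(0, 0)), sqrt(12.5))
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 40)), 0)
  expect_equal(q_squared(obs, obs, obs), 1)
  expect_equal(q_squared(obs, rep(mean(obs), 40), obs), 0)

  # two-line recomputations
  expect_equal(rmse(obs, pred), sqrt(mean((obs - pred)^2)))
  expect_equal(rmsep(obs, pred), sqrt(sum((obs - pred)^2) / length(obs)))
  expect_equal(r_squared(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))

  expect_error(rmse(obs, pred[-1]), "length")
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_error(q_squared(obs, pred, rep(2, 10)), "constant")
})

test_that("R2 is invariant under a joint affine rescaling of the response", {
  set.seed(2)
  obs <- rnorm(30); pred <- 0.8 * obs + rnorm(30, sd = 0.2)
  r2 <- r_squared(obs, pred)
  expect_equal(r_squared(5 * obs - 3, 5 * pred - 3), r2)
  # RMSE, by contrast, carries the scale
  expect_equal(rmse(5 * obs - 3, 5 * pred - 3), 5 * rmse(obs, pred))
})

test_that("Q2 is pooled, split-invariant, and pinned to RMSEP", {
  set.seed(3)
  tr <- rnorm(50); te <- rnorm(40); pe <- te + rnorm(40, sd = 0.5)
  q_full <- q_squared(te, pe, tr)

  # equal halves pooled per the defining formula reproduce the full-set Q2
  h1 <- 1:20; h2 <- 21:40
  pooled_mse <- (sum((te[h1] - pe[h1])^2) + sum((te[h2] - pe[h2])^2)) / 40
  denom <- sum((tr - mean(tr))^2) / 50
  expect_equal(q_full, 1 - pooled_mse / denom)

  # fixed RMSEP implies fixed Q2 given the training variance
  expect_equal(q_full, 1 - rmsep(te, pe)^2 / denom)
})

test_that("classification metrics follow the confusion-matrix definitions", {
  m <- classification_metrics(tp = 8, tn = 6, fp = 4, fn = 2)
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, 0.6)
  expect_equal(m$BA, 0.7)

  perfect <- classification_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_equal(unlist(perfect), c(Sn = 1, Sp = 1, BA = 1))

  expect_error(classification_metrics(0, 5, 0, 0), "empty class")
  expect_error(classification_metrics(-1, 5, 2, 1), "non-negative")
})

test_that("Sn of one class is Sp of the other; BA survives label swap", {
  for (i in 1:100) {
    set.seed(i)
    cts <- sample(0:20, 4, replace = TRUE) + 1L
    m <- classification_metrics(cts[1], cts[2], cts[3], cts[4])
    # transpose the matrix = swap the positive class
    t_m <- classification_metrics(cts[2], cts[1], cts[4], cts[3])
    expect_equal(m$Sn, t_m$Sp)
    expect_equal(m$Sp, t_m$Sn)
    expect_equal(m$BA, t_m$BA)
    expect_equal(m$BA, (m$Sn + m$Sp) / 2, tolerance = 1e-12)
  }
})

test_that("balanced_accuracy agrees with the count route and extends to 3 classes", {
  set.seed(5)
  obs <- factor(sample(c("pos", "neg"), 60, replace = TRUE))
  pred <- factor(sample(c("pos", "neg"), 60, replace = TRUE))
  cc <- confusion_counts(obs, pred, positive = "neg")
  m <- classification_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
  expect_equal(balanced_accuracy(obs, pred), m$BA)

  obs3 <- factor(c("a", "a", "b", "b", "c", "c"))
  pred3 <- c("a", "a", "b", "a", "c", "b")
  expect_equal(balanced_accuracy(obs3, pred3), mean(c(1, 0.5, 0.5)))
})

test_that("fold maker is stratified, balanced and reproducible", {
  sim <- simulate_qspr(n = 100, p = 2, informative = c(d01 = 1),
                       task = "classification", class_balance = 0.4, seed = 1)
  f <- make_folds(sim$response, folds = 5, seed = 3)
  expect_identical(f, make_folds(sim$response, folds = 5, seed = 3))
  tab <- table(sim$response, f)
  expect_true(all(tab["active", ] == 8))
  expect_true(all(tab["inactive", ] == 12))

  y <- rnorm(63)
  f2 <- make_folds(y, folds = 5, seed = 1)
  expect_true(max(table(f2)) - min(table(f2)) <= 2)
})

test_that("n-fold CV equals the refit-without-one oracle", {
  sim <- simulate_qspr(n = 16, p = 3, informative = c(d01 = 1, d02 = -1),
                       noise_sd = 0.2, seed = 6)
  cv <- kfold_cv(sim, k = 3, folds = 16, seed = 1)
  want <- brute_loo_refit(sim[descriptor_names(sim)], sim$response, 3)
  expect_equal(cv$predictions$predicted, want, tolerance = 1e-10)
})

test_that("cross-validation is deterministic and reports pooled metrics", {
  sim <- simulate_qspr(n = 80, p = 4, informative = c(d01 = 1, d02 = 1),
                       noise_sd = 0.2, seed = 7)
  a <- kfold_cv(sim, k = 5, folds = 5, seed = 9)
  b <- kfold_cv(sim, k = 5, folds = 5, seed = 9)
  expect_equal(a$predictions, b$predictions)
  # pooled Q2 recomputed from the out-of-fold predictions
  pr <- a$predictions
  expect_equal(a$metrics$Q2, q_squared(pr$observed, pr$predicted, sim$response))
  expect_equal(a$metrics$RMSE, rmse(pr$observed, pr$predicted))
})

test_that("classification CV refuses folds missing a class", {
  d <- tibble::tibble(id = as.character(1:10),
                      response = factor(c(rep("a", 9), "b")),
                      x = rnorm(10))
  expect_error(kfold_cv(d, k = 3, folds = 5, seed = 1), "class absent")
})

test_that("the performance table has the CV / training / test blocks", {
  sim <- simulate_qspr(n = 120, p = 5, informative = c(d01 = 1, d02 = 1),
                       noise_sd = 0.2, seed = 8)
  sp <- split_train_test(sim, 0.75, seed = 1)
  train <- sp[sp$set == "train", ]; test <- sp[sp$set == "test", ]
  fit <- wknn_fit(train, descriptors = c("d01", "d02"), k = 4)
  perf <- model_performance(fit, train, test, seed = 2)
  expect_equal(perf$set, c("cv", "train", "test"))
  expect_equal(perf$n, c(90, 90, 30))
  expect_equal(unique(perf$n_descriptors), 2)
  expect_true(all(perf$RMSE > 0))
  expect_gt(perf$Q2[1], 0.8)
  expect_gt(perf$R2[2], 0.8)
})
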