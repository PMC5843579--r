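#' Simulate a QSPR modelling table with planted structure
#'
#' Generates a deterministic synthetic dataset shaped like a curated
#' descriptor table: one row per chemical with an `id`, a `structure_key`, a
#' `response` (continuous or two-class) and `p` numeric descriptor columns.
#' Background descriptors are independent standard normals; structure is
#' planted on request:
#'
#' * **informative columns** drive the response through a linear latent signal
#'   plus Gaussian noise,
#' * **collinear pairs** are generated with a target Pearson correlation so
#'   the correlation filter has something to remove,
#' * **near-constant columns** are given a small standard deviation so the
#'   degeneracy filter fires,
#' * **missing cells** are set to `NA`.
#'
#' For a classification task the latent signal is thresholded at the rank
#' quantile implied by `class_balance`, giving an exact class split and a
#' controllable Bayes error via `noise_sd`.
#'
#' @param n Number of chemicals.
#' @param p Number of descriptor columns (named `d01`, `d02`, ...).
#' @param informative Named numeric vector of generating coefficients, names
#'   being descriptor columns (e.g. `c(d01 = 1, d02 = 1)`), or `NULL` for a
#'   pure-noise response.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   latent signal.
#' @param collinear Optional data frame with columns `col_a`, `col_b`, `r`:
#'   `col_b` is regenerated as an `r`-correlated copy of `col_a`.
#' @param near_constant Character vector of columns regenerated with standard
#'   deviation `near_constant_sd`.
#' @param near_constant_sd Standard deviation used for near-constant columns
#'   (default 0.05, well under the usual 0.25 filtering threshold).
#' @param missing Optional data frame with columns `row`, `col` (column name
#'   or index) marking cells to blank out.
#' @param task `"continuous"` or `"classification"`.
#' @param class_balance Fraction of chemicals in the positive class
#'   (`"active"`) for classification tasks.
#' @param seed Integer seed; the full output is a pure function of the
#'   arguments and this seed.
#' @return A tibble with columns `id`, `structure_key`, `response`, and the
#'   `p` descriptors. Attribute `"ground_truth"` (also via
#'   [ground_truth()]) records the informative columns, their coefficients,
#'   the noiseless latent signal and the simulation arguments.
#' @export
#' @examples
#' sim <- simulate_qspr(n = 50, p = 5, informative = c(d01 = 1, d02 = -0.5), seed = 1)
#' ground_truth(sim)$informative
simulate_qspr <- function(n = 100, p = 10,
                          informative = NULL,
                          noise_sd = 0.1,
                          collinear = NULL,
                          near_constant = NULL,
                          near_constant_sd = 0.05,
                          missing = NULL,
                          task = c("continuous", "classification"),
                          class_balance = 0.5,
                          seed = 1) {
  task <- match.arg(task)
  stopifnot(n >= 2, p >= 1, noise_sd >= 0, class_balance > 0, class_balance < 1)
  cols <- sprintf("d%02d", seq_len(p))

  if (!is.null(informative)) {
    if (is.null(names(informative)) || any(!nzchar(names(informative)))) {
      stop("`informative` must be a named numeric vector", call. = FALSE)
    }
    bad <- setdiff(names(informative), cols)
    if (length(bad) > 0) {
      stop("informative column(s) outside the matrix: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(intersect(names(informative), near_constant)) > 0) {
      stop("informative columns cannot also be near-constant", call. = FALSE)
    }
  }
  if (!is.null(collinear)) {
    collinear <- tibble::as_tibble(collinear)
    stopifnot(all(c("col_a", "col_b", "r") %in% names(collinear)))
    if (any(abs(collinear$r) >= 1)) stop("target correlations must lie in (-1, 1)",
                                         call. = FALSE)
  }

  with_seed(seed, {
    X <- matrix(rnorm(n * p), nrow = n, ncol = p, dimnames = list(NULL, cols))
    if (!is.null(collinear)) {
      for (i in seq_len(nrow(collinear))) {
        a <- collinear$col_a[[i]]; b <- collinear$col_b[[i]]; r <- collinear$r[[i]]
        X[, b] <- r * X[, a] + sqrt(1 - r^2) * rnorm(n)
      }
    }
    if (!is.null(near_constant)) {
      bad <- setdiff(near_constant, cols)
      if (length(bad) > 0) stop("near-constant column(s) outside the matrix: ",
                                paste(bad, collapse = ", "), call. = FALSE)
      for (b in near_constant) X[, b] <- 3 + rnorm(n, sd = near_constant_sd)
    }

    latent <- if (is.null(informative)) rep(0, n) else
      drop(X[, names(informative), drop = FALSE] %*% informative)
    noise <- rnorm(n, sd = noise_sd)

    response <- if (task == "continuous") {
      latent + noise
    } else {
      noisy <- latent + noise
      n_active <- round(n * class_balance)
      factor(ifelse(rank(-noisy, ties.method = "first") <= n_active,
                    "active", "inactive"),
             levels = c("active", "inactive"))
    }

    out <- tibble::tibble(
      id = sprintf("C%05d", seq_len(n)),
      structure_key = sprintf("STRUCT-%05d", seq_len(n)),
      response = response
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(X))

    if (!is.null(missing)) {
      missing <- tibble::as_tibble(missing)
      stopifnot(all(c("row", "col") %in% names(missing)))
      for (i in seq_len(nrow(missing))) {
        col <- missing$col[[i]]
        if (is.numeric(col)) col <- cols[[col]]
        out[[col]][missing$row[[i]]] <- NA_real_
      }
    }

    attr(out, "ground_truth") <- list(
      informative = informative,
      latent = latent,
      task = task,
      noise_sd = noise_sd,
      collinear = collinear,
      near_constant = near_constant,
      class_balance = if (task == "classification") class_balance else NULL,
      seed = seed
    )
    out
  })
}

#' Ground truth of a simulated dataset
#'
#' @param data A tibble produced by [simulate_qspr()] or [inject_duplicates()].
#' @return The `"ground_truth"` (or `"duplicate_truth"`) attribute.
#' @export
ground_truth <- function(data) {
  attr(data, "duplicate_truth") %||% attr(data, "ground_truth")
}

#' Inject duplicate structure keys into a dataset
#'
#' Appends duplicated records so the duplicate-merging rule of
#' [merge_duplicates()] can be exercised with known ground truth. The first
#' half of the injected pairs repeat the source record's response exactly
#' (they must merge); the second half offset it by
#' `disagreement_sd * sd(response)` (with `disagreement_sd` comfortably above
#' the merge multiplier they must be dropped). The expected outcome per
#' duplicated structure key, evaluated with the same range rule on the
#' injected table, is stored in attribute `"duplicate_truth"`.
#'
#' @param data A modelling table with `id`, `structure_key` and numeric
#'   `response` columns.
#' @param n_pairs Number of records to duplicate (at most `nrow(data) / 2`).
#' @param disagreement_sd Offset of disagreeing duplicates, in units of the
#'   response standard deviation. `0` makes every pair merge.
#' @param sigma Merge multiplier the truth table is evaluated against
#'   (see [merge_duplicates()]).
#' @param seed Integer seed choosing which records are duplicated.
#' @return The table with `n_pairs` appended rows, plus attribute
#'   `"duplicate_truth"`: a tibble of `structure_key` and `expected`
#'   (`"merge"` or `"drop"`).
#' @export
inject_duplicates <- function(data, n_pairs, disagreement_sd = 3, sigma = 1,
                              seed = 1) {
  stopifnot(is.numeric(data$response), n_pairs >= 1)
  if (n_pairs > nrow(data) / 2) stop("n_pairs must be at most n/2", call. = FALSE)
  base_sd <- sd(data$response)
  with_seed(seed, {
    picks <- sort(sample.int(nrow(data), n_pairs))
    n_agree <- ceiling(n_pairs / 2)
    offset <- c(rep(0, n_agree),
                rep(disagreement_sd * base_sd, n_pairs - n_agree))
    dup <- data[picks, ]
    dup$id <- paste0(dup$id, "-dup")
    dup$response <- dup$response + offset
    out <- dplyr::bind_rows(data, dup)

    full_sd <- sd(out$response)
    truth <- tibble::tibble(
      structure_key = dup$structure_key,
      expected = ifelse(abs(offset) <= sigma * full_sd, "merge", "drop")
    )
    attr(out, "duplicate_truth") <- truth
    out
  })
}
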