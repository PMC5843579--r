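#' Merge duplicated structures and remove discordant duplicates
#'
#' Chemicals sharing a `structure_key` are experimental replicates of the same
#' (QSAR-ready) structure. For a continuous endpoint, a group whose response
#' range does not exceed `sigma` times the standard deviation of the whole
#' dataset is replaced by a single record carrying the arithmetic mean of the
#' replicate values; groups spreading wider than that are treated as mutually
#' inconsistent outliers and removed entirely. For a classification endpoint,
#' concordant groups collapse to one record and discordant groups are either
#' dropped (default, the analogue of the outlier rule) or resolved by strict
#' majority vote (`conflict = "majority"`; tied votes still drop the group).
#'
#' @param data A modelling table with `id`, `structure_key` and `response`
#'   columns; additional columns are carried over from the first record of
#'   each group.
#' @param sigma Multiplier on the whole-dataset response standard deviation
#'   defining how far replicates may spread and still be averaged.
#' @param conflict How to resolve discordant classification duplicates.
#' @return A tibble with one record per `structure_key`. Attribute
#'   `"dropped"` (see [dropped_records()]) lists the removed records and the
#'   reason; attribute `"response_sd"` stores the dataset standard deviation
#'   the rule used.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   structure_key = c("K1", "K1", "K2"),
#'   response = c(1.0, 1.2, 5.0)
#' )
#' merged <- merge_duplicates(d, sigma = 1)
#' merged$response
merge_duplicates <- function(data, sigma = 1, conflict = c("drop", "majority")) {
  conflict <- match.arg(conflict)
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  stopifnot(sigma > 0, all(c("id", "structure_key", "response") %in% names(data)))
  if (anyNA(data$response)) stop("missing responses are not allowed", call. = FALSE)

  task <- response_task(data$response)
  data <- tibble::as_tibble(data)

  keep <- list(); dropped <- list()
  if (task == "continuous") {
    if (!is.numeric(data$response)) stop("non-numeric response", call. = FALSE)
    dataset_sd <- sd(data$response)
    groups <- split(seq_len(nrow(data)), data$structure_key)
    groups <- groups[order(vapply(groups, min, integer(1)))]  # keep input order
    for (idx in groups) {
      if (length(idx) == 1) { keep[[length(keep) + 1L]] <- data[idx, ]; next }
      vals <- data$response[idx]
      if (diff(range(vals)) <= sigma * dataset_sd) {
        rec <- data[idx[1], ]
        rec$response <- mean(vals)
        keep[[length(keep) + 1L]] <- rec
      } else {
        bad <- data[idx, c("id", "structure_key", "response")]
        bad$reason <- "duplicate_outlier"
        dropped[[length(dropped) + 1L]] <- bad
      }
    }
  } else {
    dataset_sd <- NA_real_
    y <- as_class_factor(data$response)
    groups <- split(seq_len(nrow(data)), data$structure_key)
    groups <- groups[order(vapply(groups, min, integer(1)))]
    for (idx in groups) {
      labels <- y[idx]
      tab <- table(labels)
      winners <- names(tab)[tab == max(tab)]
      concordant <- length(unique(as.character(labels))) == 1
      if (concordant || (conflict == "majority" && length(winners) == 1)) {
        rec <- data[idx[1], ]
        rec$response <- labels[match(winners[1], as.character(labels))][1]
        keep[[length(keep) + 1L]] <- rec
      } else {
        bad <- data[idx, c("id", "structure_key")]
        bad$response <- as.character(labels)
        bad$reason <- "class_conflict"
        dropped[[length(dropped) + 1L]] <- bad
      }
    }
  }

  out <- dplyr::bind_rows(keep)
  if (nrow(out) == 0) stop("all records dropped as duplicate outliers", call. = FALSE)
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(id = character(), structure_key = character(),
                   response = if (task == "continuous") numeric() else character(),
                   reason = character())
  attr(out, "response_sd") <- dataset_sd
  out
}

#' Records removed by a curation or filtering step
#'
#' @param data The tibble returned by [merge_duplicates()].
#' @return A tibble of dropped records with a `reason` column.
#' @export
dropped_records <- function(data) {
  attr(data, "dropped")
}

#' Stratified train/test split
#'
#' Splits a dataset into training and test portions while preserving the
#' response distribution: per class for a qualitative endpoint, per
#' equal-frequency response bin (default deciles) for a quantitative one. The
#' number of test chemicals drawn from each stratum is proportional to the
#' stratum size (largest-remainder rounding, so the overall test count equals
#' `round(n * (1 - fraction))` and every stratum is within one chemical of
#' exact proportionality). Classes with fewer than two members are placed in
#' the training set with a warning. The split is a pure function of the seed.
#'
#' @param data A modelling table with a `response` column.
#' @param fraction Training fraction in `(0, 1]` (default 0.75, i.e. a 75/25
#'   split).
#' @param n_bins Number of equal-frequency bins used to stratify a continuous
#'   response.
#' @param seed Integer seed.
#' @return The input tibble with an added `set` column (`"train"`/`"test"`),
#'   with attributes `fraction` and `seed`.
#' @export
#' @examples
#' sim <- simulate_qspr(n = 40, p = 3, seed = 7)
#' table(split_train_test(sim, fraction = 0.75, seed = 1)$set)
split_train_test <- function(data, fraction = 0.75, n_bins = 10, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1, n_bins >= 1)
  n <- nrow(data)
  if (n < 2) stop("need at least two records to split", call. = FALSE)

  y <- data$response
  if (response_task(y) == "classification") {
    stratum <- as.integer(as_class_factor(y))
    small <- which(table(stratum)[as.character(stratum)] < 2)
    if (length(small) > 0) {
      warning("class(es) with fewer than 2 members placed in the training set")
    }
  } else {
    stratum <- dplyr::ntile(y, min(n_bins, n))
    small <- integer(0)
  }

  n_test_total <- round(n * (1 - fraction))
  set <- rep("train", n)

  if (n_test_total > 0) {
    eligible <- setdiff(seq_len(n), small)
    strata <- split(eligible, stratum[eligible])
    sizes <- lengths(strata)
    quota_exact <- sizes * (1 - fraction)
    quota <- floor(quota_exact)
    short <- n_test_total - sum(quota)
    if (short > 0) {
      extra <- order(quota_exact - quota, decreasing = TRUE)[seq_len(min(short, length(strata)))]
      quota[extra] <- quota[extra] + 1L
    } else if (short < 0) {
      trim <- order(quota_exact - quota)[seq_len(min(-short, sum(quota > 0)))]
      quota[trim] <- pmax(quota[trim] - 1L, 0L)
    }
    quota <- pmin(quota, sizes)
    with_seed(seed, {
      for (s in seq_along(strata)) {
        if (quota[s] > 0) {
          take <- strata[[s]][sample.int(sizes[s], quota[s])]
          set[take] <- "test"
        }
      }
    })
  }

  out <- tibble::as_tibble(data)
  out$set <- set
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  out
}

#' Append a descriptor column
#'
#' Widens a modelling table by one named descriptor column — used, for
#' example, to add a binary salt-form flag as an extra descriptor for
#' endpoints where the counterion matters (melting and boiling point). The
#' appended column takes part in scaling and distances like any other
#' descriptor.
#'
#' @param data A modelling table.
#' @param name Name of the new column; must not already exist.
#' @param values Numeric vector, one value per chemical, in row order.
#' @return The widened tibble; chemical order unchanged, new column last.
#' @export
append_descriptor <- function(data, name, values) {
  stopifnot(is.character(name), length(name) == 1)
  if (name %in% names(data)) {
    stop("descriptor '", name, "' already present", call. = FALSE)
  }
  if (length(values) != nrow(data)) {
    stop("length mismatch: ", length(values), " values for ", nrow(data),
         " chemicals", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out[[name]] <- as.numeric(values)
  out
}
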