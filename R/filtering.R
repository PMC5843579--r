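#' Remove constant, near-constant and incomplete descriptors
#'
#' Drops every descriptor column that is constant, near-constant (sample
#' standard deviation at or below `near_constant_sd`, default 0.25) or has at
#' least one missing value. Column order of the survivors is preserved.
#'
#' @param data A modelling table.
#' @param near_constant_sd Standard-deviation threshold below which a column
#'   counts as near-constant.
#' @param descriptors Descriptor selection (see [descriptor_names()]).
#' @return The table without the offending columns. Attribute `"removed"`
#'   (see [removed_descriptors()]) records each removed column, the reason
#'   (`"missing"`, `"constant"` or `"near_constant"`) and its standard
#'   deviation.
#' @export
remove_degenerate <- function(data, near_constant_sd = 0.25, descriptors = NULL) {
  stopifnot(near_constant_sd >= 0)
  cols <- descriptor_names(data, {{ descriptors }})
  if (nrow(data) == 0 || length(cols) == 0) stop("empty descriptor matrix", call. = FALSE)

  removed <- tibble::tibble(descriptor = character(), reason = character(),
                            sd = numeric())
  for (col in cols) {
    v <- data[[col]]
    if (anyNA(v)) {
      removed <- dplyr::add_row(removed, descriptor = col, reason = "missing",
                                sd = NA_real_)
    } else {
      s <- sd(v)
      if (is.na(s) || s == 0) {  # single row: no variability to speak of
        removed <- dplyr::add_row(removed, descriptor = col, reason = "constant",
                                  sd = s)
      } else if (s <= near_constant_sd) {
        removed <- dplyr::add_row(removed, descriptor = col,
                                  reason = "near_constant", sd = s)
      }
    }
  }
  if (nrow(removed) == length(cols)) {
    stop("all descriptor columns removed as degenerate", call. = FALSE)
  }
  out <- data[setdiff(names(data), removed$descriptor)]
  attr(out, "removed") <- removed
  out
}

#' Remove strongly intercorrelated descriptors
#'
#' Greedy pairwise correlation filter: while any pair of surviving descriptors
#' has `|r|` above `threshold`, take the worst-correlated pair and remove the
#' member with the largest mean absolute correlation to all other surviving
#' descriptors (ties remove the later column in input order). Correlations
#' are re-evaluated after every removal, so no surviving pair exceeds the
#' threshold on exit.
#'
#' @param data A modelling table with no missing descriptor values (run
#'   [remove_degenerate()] first).
#' @param threshold Absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.96).
#' @param use_abs Compare `|r|` (default) or signed `r` against the threshold.
#' @param descriptors Descriptor selection (see [descriptor_names()]).
#' @return The table without the removed columns; attribute `"removed"` lists
#'   them with the partner that triggered the removal.
#' @export
filter_correlation <- function(data, threshold = 0.96, use_abs = TRUE,
                               descriptors = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  cols <- descriptor_names(data, {{ descriptors }})
  if (length(cols) < 2) stop("need at least two descriptor columns", call. = FALSE)
  m <- descriptor_matrix(data, cols)
  if (anyNA(m)) stop("missing values present; run remove_degenerate() first",
                     call. = FALSE)
  if (any(apply(m, 2, sd) == 0)) {
    stop("zero-variance column present; run remove_degenerate() first",
         call. = FALSE)
  }

  cm <- cor(m)
  if (!use_abs) cm[] <- pmax(cm, 0)  # signed mode: negative r never offends
  acm <- abs(cor(m))
  alive <- seq_along(cols)
  removed <- tibble::tibble(descriptor = character(), reason = character(),
                            partner = character(), r = numeric())

  repeat {
    if (length(alive) < 2) break
    sub <- if (use_abs) abs(cm[alive, alive, drop = FALSE]) else cm[alive, alive, drop = FALSE]
    diag(sub) <- 0
    worst <- max(sub)
    if (worst <= threshold) break
    hit <- which(sub == worst, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    pair <- alive[hit[1, ]]  # first offending pair in input order

    # mean |r| of each pair member against every other surviving column
    mean_abs <- vapply(pair, function(j) {
      others <- setdiff(alive, j)
      mean(acm[j, others])
    }, numeric(1))
    drop_j <- if (mean_abs[1] > mean_abs[2]) pair[1]
              else if (mean_abs[2] > mean_abs[1]) pair[2]
              else max(pair)  # tie: later column in input order
    keep_j <- setdiff(pair, drop_j)
    removed <- dplyr::add_row(removed, descriptor = cols[drop_j],
                              reason = "correlated", partner = cols[keep_j],
                              r = cm[pair[1], pair[2]])
    alive <- setdiff(alive, drop_j)
  }

  out <- data[setdiff(names(data), removed$descriptor)]
  attr(out, "removed") <- removed
  out
}

#' Descriptors removed by a filtering step
#'
#' @param data The tibble returned by [remove_degenerate()] or
#'   [filter_correlation()].
#' @return A tibble of removed descriptor names and reasons.
#' @export
removed_descriptors <- function(data) {
  attr(data, "removed")
}

#' Write a plain-text filtering report
#'
#' @param data A tibble carrying a `"removed"` attribute.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(data, path) {
  removed <- removed_descriptors(data)
  lines <- c(sprintf("descriptors removed: %d", nrow(removed)),
             sprintf("- %s (%s%s)", removed$descriptor, removed$reason,
                     ifelse(is.na(removed$sd %||% NA), "",
                            sprintf(", sd=%.4g", removed$sd %||% NA))))
  if ("partner" %in% names(removed)) {
    lines <- c(sprintf("descriptors removed: %d", nrow(removed)),
               sprintf("- %s (correlated with %s, r=%.4f)",
                       removed$descriptor, removed$partner, removed$r))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Fit autoscaling parameters on training rows
#'
#' Computes the per-descriptor mean and sample standard deviation (n - 1
#' denominator) on the training rows only. These parameters are saved and
#' applied unchanged to any later data, so test chemicals are scaled into the
#' training set's coordinate frame.
#'
#' @param data A modelling table (training rows only, or use `train_ids`).
#' @param descriptors Descriptor selection (see [descriptor_names()]).
#' @param train_ids Optional character vector restricting the fit to a subset
#'   of `data$id`.
#' @return An object of class `qspr_scaler`: a tibble with columns
#'   `descriptor`, `mean`, `sd`.
#' @export
fit_scaler <- function(data, descriptors = NULL, train_ids = NULL) {
  cols <- descriptor_names(data, {{ descriptors }})
  if (!is.null(train_ids)) {
    keep <- chem_ids(data) %in% train_ids
    if (!any(keep)) stop("no rows match train_ids", call. = FALSE)
    data <- data[keep, ]
  }
  m <- descriptor_matrix(data, cols)
  mu <- unname(colMeans(m))
  s <- unname(apply(m, 2, sd))
  zero <- cols[is.na(s) | s == 0]
  if (length(zero) > 0) {
    stop("zero training standard deviation for descriptor(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  structure(tibble::tibble(descriptor = cols, mean = mu, sd = s),
            class = c("qspr_scaler", "tbl_df", "tbl", "data.frame"))
}

#' Apply (or invert) saved autoscaling parameters
#'
#' @param data A modelling table containing every descriptor the scaler knows.
#' @param scaler A [fit_scaler()] object.
#' @param inverse Undo the scaling instead of applying it.
#' @return The table with descriptor columns replaced by
#'   `(x - mean) / sd` (or its inverse).
#' @export
apply_scaler <- function(data, scaler, inverse = FALSE) {
  stopifnot(inherits(scaler, "qspr_scaler"))
  missing <- setdiff(scaler$descriptor, names(data))
  if (length(missing) > 0) {
    stop("descriptor column(s) missing from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(scaler))) {
    col <- scaler$descriptor[i]
    out[[col]] <- if (inverse) out[[col]] * scaler$sd[i] + scaler$mean[i]
                  else (out[[col]] - scaler$mean[i]) / scaler$sd[i]
  }
  out
}
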