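#' Genetic-algorithm configuration
#'
#' Defaults follow the published selection protocol: 100 consecutive
#' independent runs of 100 generations each on 30 chromosomes, with a 0.01
#' per-gene mutation probability and a 0.5 crossover probability, fitness
#' evaluated by fivefold cross-validation with the neighbourhood size
#' optimized in 3–7. Reduced budgets (fewer runs/generations) are plain
#' argument changes, not code changes.
#'
#' @param population Chromosomes per generation.
#' @param generations Generations per run.
#' @param runs Independent GA runs whose best chromosomes are tallied into
#'   selection frequencies.
#' @param p_mutation Per-gene mutation probability.
#' @param p_crossover Probability that a mating pair undergoes uniform
#'   crossover.
#' @param k_range Neighbourhood sizes searched inside the fitness function.
#' @param folds Cross-validation folds of the fitness function.
#' @param elitism Number of best chromosomes copied unchanged to the next
#'   generation.
#' @param init_prob Probability a gene starts switched on; default
#'   `min(0.5, 10/p)` so initial models stay small when many descriptors are
#'   offered.
#' @param lambda Parsimony pressure: fitness is penalised by
#'   `lambda * subset_size / p`.
#' @param delta Forward-selection tolerance: the final subset is the
#'   smallest prefix whose CV fitness is within `delta` of the best prefix.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 30, generations = 100, runs = 100,
                      p_mutation = 0.01, p_crossover = 0.5, k_range = 3:7,
                      folds = 5, elitism = 1, init_prob = NULL, lambda = 0,
                      delta = 0.01) {
  stopifnot(population >= 2, runs >= 1, generations >= 1,
            p_mutation >= 0, p_mutation <= 1,
            p_crossover >= 0, p_crossover <= 1, lambda >= 0, delta >= 0)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 runs = as.integer(runs), p_mutation = p_mutation,
                 p_crossover = p_crossover, k_range = as.integer(k_range),
                 folds = as.integer(folds), elitism = as.integer(elitism),
                 init_prob = init_prob, lambda = lambda, delta = delta),
            class = "ga_config")
}

# CV fitness of a descriptor subset: Q2-style pooled CV score for continuous
# responses, balanced accuracy for classes, at the best k in k_range (ties to
# the smallest k). Returns c(fitness, k).
subset_cv_fitness <- function(X, y, fold, sel, config, scheme, eps = 1e-12) {
  if (!any(sel)) return(c(-Inf, NA_real_))
  Xs <- X[, sel, drop = FALSE]
  ks <- config$k_range
  ks <- ks[ks <= nrow(Xs) - 1]
  if (length(ks) == 0) ks <- nrow(Xs) - 1L
  if (is.numeric(y)) {
    P <- cpp_cv_predict(Xs, y, fold, ks, scheme, eps)
    denom <- sum((y - mean(y))^2) / length(y)
    score <- 1 - colMeans((y - P)^2) / denom
  } else {
    P <- cpp_cv_classify(Xs, as.integer(y), nlevels(y), fold, ks, scheme, eps)
    score <- apply(P, 2, function(p) {
      balanced_accuracy(y, levels(y)[p])
    })
  }
  # ties (up to float noise) go to the smallest k
  best <- which(score >= max(score) - 1e-10)[1]
  fitness <- score[best] - config$lambda * sum(sel) / ncol(X)
  c(fitness, ks[best])
}

# the forward-selection parsimony rule: smallest prefix whose CV fitness is
# within delta of the best prefix
forward_choose <- function(cv_fitness, delta) {
  which(cv_fitness >= max(cv_fitness) - delta)[1]
}

# One GA run: evolve a population of binary descriptor-inclusion vectors and
# return the best chromosome ever seen (elitism makes it the final elite).
ga_run <- function(fitness_fn, p, config, seed) {
  with_seed(seed, {
    init_prob <- config$init_prob %||% min(0.5, 10 / p)
    pop <- matrix(runif(config$population * p) < init_prob,
                  nrow = config$population)
    fit <- apply(pop, 1, fitness_fn)

    best_chrom <- pop[which.max(fit), ]
    best_fit <- max(fit)

    tournament <- function() {
      i <- sample.int(config$population, 2, replace = TRUE)
      if (fit[i[2]] > fit[i[1]]) i[2] else i[1]
    }

    for (gen in seq_len(config$generations)) {
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
      offspring <- list()
      while (length(offspring) < config$population - config$elitism) {
        a <- pop[tournament(), ]
        b <- pop[tournament(), ]
        if (runif(1) < config$p_crossover) {
          mask <- runif(p) < 0.5
          tmp <- a[mask]; a[mask] <- b[mask]; b[mask] <- tmp
        }
        a <- xor(a, runif(p) < config$p_mutation)
        b <- xor(b, runif(p) < config$p_mutation)
        offspring[[length(offspring) + 1L]] <- a
        if (length(offspring) < config$population - config$elitism) {
          offspring[[length(offspring) + 1L]] <- b
        }
      }
      pop <- rbind(pop[elite_idx, , drop = FALSE],
                   do.call(rbind, offspring))
      fit <- apply(pop, 1, fitness_fn)
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_chrom <- pop[gen_best, ]
      }
    }
    list(best = best_chrom, fitness = best_fit)
  })
}

#' One round of GA descriptor selection
#'
#' Runs `config$runs` independent genetic-algorithm searches over binary
#' descriptor-inclusion chromosomes, each evolved for `config$generations`
#' generations with tournament selection (size 2, elitism), uniform
#' crossover and per-gene mutation. Fitness is the cross-validated model
#' quality of the encoded subset (Q2-style score for continuous responses,
#' balanced accuracy for classes) at the best k in `config$k_range`; the
#' all-zero chromosome scores `-Inf`. The selection frequency of a
#' descriptor is the fraction of runs whose best chromosome contains it.
#'
#' @param data Training table with `response` and descriptor columns.
#' @param descriptors Descriptor selection (see [descriptor_names()]).
#' @param config A [ga_config()].
#' @param seed Integer seed; expanded into per-run sub-seeds, so the whole
#'   trace is reproducible.
#' @return An object of class `selection_trace` with `frequency` (tibble of
#'   `descriptor`, `frequency`, `rank`) and `runs` (per-run best fitness and
#'   chromosome).
#' @export
ga_select <- function(data, descriptors = NULL, config = ga_config(),
                      seed = 1) {
  cols <- descriptor_names(data, {{ descriptors }})
  if (length(cols) < 1) stop("no candidate descriptors", call. = FALSE)
  y <- data$response
  if (response_task(y) == "classification") y <- as_class_factor(y)
  scaler <- fit_scaler(data, cols)
  X <- descriptor_matrix(apply_scaler(data, scaler), cols)
  p <- length(cols)

  seeds <- derive_seeds(seed, config$runs + 1L)
  fold <- make_folds(data$response, folds = config$folds, seed = seeds[1])
  scheme <- weighting_scheme_code("inverse")

  cache <- new.env(parent = emptyenv())
  fitness_fn <- function(sel) {
    key <- paste0("k", paste(which(sel), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- subset_cv_fitness(X, y, fold, sel, config, scheme)[1]
    cache[[key]] <- val
    val
  }

  if (p == 1) {
    runs_tbl <- tibble::tibble(run = seq_len(config$runs),
                               fitness = fitness_fn(TRUE),
                               chromosome = replicate(config$runs, TRUE,
                                                      simplify = FALSE))
  } else {
    results <- lapply(seq_len(config$runs), function(r) {
      ga_run(fitness_fn, p, config, seeds[r + 1L])
    })
    runs_tbl <- tibble::tibble(
      run = seq_len(config$runs),
      fitness = vapply(results, `[[`, numeric(1), "fitness"),
      chromosome = lapply(results, `[[`, "best")
    )
  }

  freq <- colMeans(do.call(rbind, runs_tbl$chromosome))
  frequency <- tibble::tibble(descriptor = cols, frequency = freq)
  frequency$rank <- rank(-frequency$frequency, ties.method = "first")
  frequency <- dplyr::arrange(frequency, .data$rank)

  structure(list(frequency = frequency, runs = runs_tbl, config = config,
                 seed = seed, descriptors = cols),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("GA selection trace:", length(x$descriptors), "descriptors,",
      nrow(x$runs), "runs\n")
  print(head(x$frequency, 10))
  invisible(x)
}

#' @export
tidy.selection_trace <- function(x, ...) x$frequency

#' Two-round GA descriptor selection
#'
#' Round one searches the full candidate list; round two repeats the search
#' on the top-scoring half (by round-one selection frequency), concentrating
#' the runs on descriptors that already proved useful and driving the
#' selection towards a consistent final subset. The final ranking comes from
#' round-two frequencies.
#'
#' @inheritParams ga_select
#' @return A `selection_trace` whose `frequency` table carries `frequency_r1`,
#'   `frequency_r2` (NA for descriptors eliminated after round one) and the
#'   final `rank`; `rounds` holds the two underlying traces.
#' @export
two_round_select <- function(data, descriptors = NULL, config = ga_config(),
                             seed = 1) {
  cols <- descriptor_names(data, {{ descriptors }})
  if (length(cols) < 4) stop("need at least 4 candidate descriptors", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)

  r1 <- ga_select(data, descriptors = cols, config = config, seed = seeds[1])
  top_half <- r1$frequency$descriptor[seq_len(ceiling(length(cols) / 2))]
  top_half <- cols[cols %in% top_half]  # restore input order
  r2 <- ga_select(data, descriptors = top_half, config = config,
                  seed = seeds[2])

  frequency <- tibble::tibble(descriptor = cols)
  frequency$frequency_r1 <-
    r1$frequency$frequency[match(cols, r1$frequency$descriptor)]
  frequency$frequency_r2 <-
    r2$frequency$frequency[match(cols, r2$frequency$descriptor)]
  in_r2 <- !is.na(frequency$frequency_r2)
  frequency$rank <- NA_integer_
  frequency$rank[in_r2] <- rank(-frequency$frequency_r2[in_r2],
                                ties.method = "first")
  frequency <- frequency[order(!in_r2, frequency$rank), ]

  structure(list(frequency = frequency, rounds = list(r1, r2),
                 config = config, seed = seed, descriptors = cols),
            class = "selection_trace")
}

#' Forward selection along the frequency ranking
#'
#' Descriptors are added in decreasing selection-frequency order; after each
#' addition the cross-validated fitness (k re-optimized) and the
#' exclude-self fitting statistic are recorded. The final subset is the
#' smallest prefix whose CV fitness is within `config$delta` of the best
#' prefix — the parsimony rule that keeps models small while conceding
#' essentially nothing in CV performance.
#'
#' @inheritParams ga_select
#' @param ranked_descriptors Candidate descriptors in decreasing frequency
#'   order (e.g. `tidy(trace)$descriptor`).
#' @return A list with `selected` (character vector), `k` (optimized for the
#'   selected subset), and `curve`: a tibble of `size`, `descriptor`,
#'   `cv_fitness`, `fit_fitness` and `balance` (`|fit - cv|`).
#' @export
forward_select <- function(data, ranked_descriptors, config = ga_config(),
                           seed = 1) {
  stopifnot(length(ranked_descriptors) >= 1)
  y <- data$response
  if (response_task(y) == "classification") y <- as_class_factor(y)
  scaler <- fit_scaler(data, ranked_descriptors)
  X <- descriptor_matrix(apply_scaler(data, scaler), ranked_descriptors)
  fold <- make_folds(data$response, folds = config$folds,
                     seed = derive_seeds(seed, 1L))
  scheme <- weighting_scheme_code("inverse")
  eps <- 1e-12

  sizes <- seq_along(ranked_descriptors)
  cv_fit <- numeric(length(sizes))
  fit_fit <- numeric(length(sizes))
  k_at <- integer(length(sizes))
  for (s in sizes) {
    sel <- seq_along(ranked_descriptors) <= s
    res <- subset_cv_fitness(X, y, fold, sel, config, scheme)
    cv_fit[s] <- res[1]
    k_at[s] <- as.integer(res[2])
    Xs <- X[, sel, drop = FALSE]
    if (is.numeric(y)) {
      loo <- cpp_loo_predict(Xs, y, k_at[s], scheme, eps)
      fit_fit[s] <- 1 - mean((y - loo)^2) / (sum((y - mean(y))^2) / length(y))
    } else {
      loo <- cpp_loo_classify(Xs, as.integer(y), nlevels(y), k_at[s], scheme,
                              eps)
      fit_fit[s] <- balanced_accuracy(y, levels(y)[loo])
    }
  }
  chosen <- forward_choose(cv_fit, config$delta)

  list(
    selected = ranked_descriptors[seq_len(chosen)],
    k = k_at[chosen],
    curve = tibble::tibble(size = sizes, descriptor = ranked_descriptors,
                           cv_fitness = cv_fit, fit_fitness = fit_fit,
                           balance = abs(fit_fit - cv_fit), k = k_at)
  )
}

#' Full descriptor-selection pipeline
#'
#' Two rounds of GA frequency ranking followed by forward selection, then a
#' final weighted kNN fit on the selected subset.
#'
#' @inheritParams ga_select
#' @param rounds `2` (default) for the two-round protocol, `1` to skip the
#'   halving round.
#' @return An object of class `qspr_selection` with `selected`, `k`,
#'   `trace` (the `selection_trace`), `curve` (forward-selection path) and
#'   `model` (the fitted [wknn_fit()] on the selected subset).
#' @export
select_descriptors <- function(data, descriptors = NULL, config = ga_config(),
                               rounds = 2, seed = 1) {
  cols <- descriptor_names(data, {{ descriptors }})
  seeds <- derive_seeds(seed, 3L)
  trace <- if (rounds >= 2 && length(cols) >= 4) {
    two_round_select(data, descriptors = cols, config = config,
                     seed = seeds[1])
  } else {
    ga_select(data, descriptors = cols, config = config, seed = seeds[1])
  }
  ranked <- trace$frequency$descriptor[!is.na(trace$frequency$rank)]
  fw <- forward_select(data, ranked, config = config, seed = seeds[2])
  model <- wknn_fit(data, descriptors = fw$selected, k = fw$k)

  structure(list(selected = fw$selected, k = fw$k, trace = trace,
                 curve = fw$curve, model = model, config = config,
                 seed = seed),
            class = "qspr_selection")
}

#' @export
print.qspr_selection <- function(x, ...) {
  cat("Selected", length(x$selected), "descriptor(s), k =", x$k, "\n")
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.qspr_selection <- function(x, ...) x$trace$frequency

#' @export
glance.qspr_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), k = x$k,
                 cv_fitness = x$curve$cv_fitness[length(x$selected)],
                 seed = x$seed)
}

#' Write a selection trace and forward-selection curve to delimited files
#'
#' @param x A `qspr_selection` or `selection_trace`.
#' @param path Output path for the frequency table; the forward-selection
#'   curve (if present) goes to `<path>` with suffix `_forward` before the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  freq <- if (inherits(x, "qspr_selection")) x$trace$frequency else x$frequency
  write_delimited(freq, path)
  if (inherits(x, "qspr_selection")) {
    curve_path <- sub("(\\.[^.]+)$", "_forward\\1", path)
    write_delimited(x$curve, curve_path)
  }
  invisible(path)
}
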