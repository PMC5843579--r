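# Delimiter by extension: .csv is comma, everything else (.txt, .tsv) tab.
path_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_delim(path, delim = path_delim(path), show_col_types = FALSE,
                    progress = FALSE)
}

write_delimited <- function(x, path) {
  readr::write_delim(x, path, delim = path_delim(path))
  invisible(path)
}

#' Read and write modelling datasets
#'
#' Delimited text (comma for `.csv`, tab otherwise) with columns `id`,
#' `structure_key` and `response` (a non-numeric response is treated as a
#' class label), plus any number of numeric descriptor columns.
#'
#' @param path File path.
#' @return `read_dataset()`: a tibble. `write_dataset()`: `path`, invisibly.
#' @export
read_dataset <- function(path) {
  out <- read_delimited(path)
  need <- c("id", "response")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$id <- as.character(out$id)
  if (!is.numeric(out$response)) out$response <- factor(out$response)
  out
}

#' @rdname read_dataset
#' @param data The table to write.
#' @export
write_dataset <- function(data, path) write_delimited(data, path)

#' Read and write descriptor matrices
#'
#' Delimited text whose first column is the chemical id and whose remaining
#' columns are numeric descriptors — the layout common descriptor engines
#' export.
#'
#' @param path File path.
#' @return `read_descriptors()`: a tibble with an `id` column first.
#' @export
read_descriptors <- function(path) {
  out <- read_delimited(path)
  names(out)[1] <- "id"
  out$id <- as.character(out$id)
  out
}

#' @rdname read_descriptors
#' @param data The table to write (`id` column first).
#' @export
write_descriptors <- function(data, path) {
  stopifnot("id" %in% names(data))
  write_delimited(dplyr::relocate(data, "id"), path)
}

#' Read chemical structures for a pluggable descriptor engine
#'
#' Supports SMILES files (one structure per line, optionally followed by a
#' whitespace-separated id) and SDF/MOL files (standard V2000 molblocks,
#' parsed with ChemmineR when available). Records that fail to parse are
#' reported in the `"failures"` attribute rather than aborting the read.
#' The structures themselves are kept as opaque strings/ids: descriptor
#' computation is delegated to an external engine, and precomputed
#' descriptor tables remain the first-class input.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"smiles"`, `"sdf"` or `"mol"`.
#' @return A tibble with columns `id` and `structure`; attribute
#'   `"failures"` lists records that could not be parsed.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf", "mol")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = , smiles = , txt = "smiles",
                     sdf = "sdf", mol = "mol",
                     stop("cannot infer structure format from extension '",
                          ext, "'", call. = FALSE))
  }

  if (format == "smiles") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty structure file: ", path, call. = FALSE)
    parts <- strsplit(trimws(lines), "[ \t]+")
    tibble::tibble(
      id = vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("S%04d", i)
      }, character(1)),
      structure = vapply(parts, `[[`, character(1), 1)
    )
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE)) {
      stop("reading SDF/MOL requires the ChemmineR package", call. = FALSE)
    }
    src <- path
    if (format == "mol") {
      # a MOL file is a single unterminated molblock; close it as SDF
      src <- tempfile(fileext = ".sdf")
      writeLines(c(readr::read_lines(path, progress = FALSE), "$$$$"), src)
      on.exit(unlink(src))
    }
    sdf <- ChemmineR::read.SDFset(src)
    if (length(sdf) == 0) stop("empty structure file: ", path, call. = FALSE)
    ok <- ChemmineR::validSDF(sdf)
    titles <- vapply(seq_along(sdf), function(i) {
      h <- ChemmineR::header(sdf[[i]])
      t <- trimws(h[1])
      if (nzchar(t)) t else sprintf("S%04d", i)
    }, character(1))
    blocks <- vapply(which(ok), function(i) {
      paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
    }, character(1))
    out <- tibble::tibble(id = titles[ok], structure = blocks)
    attr(out, "failures") <- tibble::tibble(
      record = unname(which(!ok)),
      id = titles[!ok],
      reason = "invalid molblock"
    )
    out
  }
}

#' Compute descriptors through a pluggable engine
#'
#' The package does not bundle a descriptor calculator. An engine is any R
#' function taking a structure tibble (`id`, `structure`) and returning a
#' descriptor table (`id` first, numeric columns after); register one via
#' `options(knnqspr.descriptor_engine = <function>)` or pass it directly.
#' Without an engine, precomputed descriptor tables must be used.
#'
#' @param structures A tibble from [read_structures()].
#' @param engine A function, or `NULL` to use the registered option.
#' @return The engine's descriptor tibble.
#' @export
compute_descriptors <- function(structures, engine = NULL) {
  engine <- engine %||% getOption("knnqspr.descriptor_engine")
  if (is.null(engine)) {
    stop("no descriptor engine registered; supply a precomputed descriptor ",
         "table instead (see read_descriptors())", call. = FALSE)
  }
  out <- engine(structures)
  stopifnot(is.data.frame(out), "id" %in% names(out))
  tibble::as_tibble(out)
}

MODEL_FORMAT <- "knnqspr_wknn"
MODEL_VERSION <- 1L

#' Save and load fitted models
#'
#' Models are persisted as a single JSON text file holding the task, k,
#' weighting, descriptor names, scaling parameters and the scaled training
#' data at full double precision, so a reloaded model reproduces predictions
#' bit for bit. The applicability-domain assessor is rebuilt
#' deterministically from the stored training data on load.
#'
#' @param model A [wknn_fit()] model.
#' @param path Output file (conventionally `.json`).
#' @return `save_model()`: `path` invisibly; `load_model()`: the `wknn`
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wknn"))
  payload <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    task = model$task, k = model$k, weighting = model$weighting,
    eps = model$eps, descriptors = model$descriptors,
    scaler_mean = model$scaler$mean, scaler_sd = model$scaler$sd,
    ids = model$ids, structure_key = model$structure_key,
    response = if (model$task == "continuous") as.numeric(model$y)
               else as.character(model$y),
    classes = if (model$task == "classification") levels(model$y) else NULL,
    n = nrow(model$X), p = ncol(model$X),
    X = as.numeric(model$X)  # column-major
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("corrupt or truncated model file: ", path,
                             call. = FALSE)
                      })
  if (!identical(payload$format, MODEL_FORMAT)) {
    stop("not a knnqspr model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(payload$version), MODEL_VERSION)) {
    stop("model file version ", payload$version,
         " not supported (expected ", MODEL_VERSION, ")", call. = FALSE)
  }
  X <- matrix(as.numeric(payload$X), nrow = payload$n, ncol = payload$p,
              dimnames = list(payload$ids, payload$descriptors))
  y <- if (payload$task == "continuous") as.numeric(payload$response)
       else factor(payload$response, levels = payload$classes)
  scaler <- structure(
    tibble::tibble(descriptor = payload$descriptors,
                   mean = payload$scaler_mean, sd = payload$scaler_sd),
    class = c("qspr_scaler", "tbl_df", "tbl", "data.frame"))
  structure(list(
    X = X, y = y, task = payload$task, k = as.integer(payload$k),
    weighting = payload$weighting, eps = payload$eps,
    scaler = scaler, descriptors = payload$descriptors,
    ids = payload$ids, structure_key = payload$structure_key,
    response_name = "response", seed = NA_integer_
  ), class = "wknn")
}

#' Batch prediction with a full per-query report
#'
#' Predicts every query with one or more fitted models and writes one report
#' row per query per model: the prediction, the two-tier
#' applicability-domain assessment (leverage and threshold, global verdict,
#' local index, confidence, interpretation), and — unless `neighbors =
#' FALSE` — the up-to-five nearest training neighbours, each with its id,
#' structure key, experimental response, leave-one-out predicted response
#' and distance. Output rows follow input order; the delimiter follows the
#' output extension (comma for `.csv`, tab otherwise).
#'
#' @param models A named list of [wknn_fit()] models, or a character vector
#'   of model-file paths (names default to the file stem).
#' @param input A query table with an `id` column and descriptor columns, or
#'   the path of a delimited descriptor table.
#' @param output Optional report path; when `NULL` the report tibble is only
#'   returned.
#' @param neighbors Include the neighbour block.
#' @return The report tibble, invisibly when `output` is given.
#' @export
predict_batch <- function(models, input, output = NULL, neighbors = TRUE) {
  if (is.character(models)) {
    paths <- models
    models <- lapply(paths, load_model)
    names(models) <- tools::file_path_sans_ext(basename(paths))
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("model", seq_along(models))
  }
  data <- if (is.character(input)) read_descriptors(input) else
    tibble::as_tibble(input)

  reports <- lapply(names(models), function(nm) {
    model <- models[[nm]]
    missing <- setdiff(model$descriptors, names(data))
    if (length(missing) > 0) {
      stop("model '", nm, "' requires descriptor column(s) absent from the ",
           "input: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    ad <- fit_ad(model)
    pred <- predict(model, data)
    adx <- assess_ad(ad, data)
    pred_out <- if (model$task == "continuous") pred$.pred
                else as.character(pred$.pred)
    rep <- tibble::tibble(
      model = nm, id = pred$id,
      prediction = pred_out,
      leverage = adx$leverage, leverage_threshold = ad$threshold,
      global_ad = ifelse(adx$global_inside, "inside", "outside"),
      local_ad_index = adx$local_ad_index, confidence = adx$confidence,
      interpretation = as.character(adx$interpretation),
      flagged = adx$flagged
    )
    if (neighbors) {
      nmax <- min(5L, nrow(model$X))
      nb <- find_neighbors(model, data, k = nmax)
      loo <- ad$loo
      nb$loo_pred <- loo$predicted[match(nb$neighbor_id, loo$id)]
      for (r in seq_len(nmax)) {
        slice <- nb[nb$rank == r, ]
        slice <- slice[match(rep$id, slice$query_id), ]
        rep[[sprintf("n%d_id", r)]] <- slice$neighbor_id
        rep[[sprintf("n%d_key", r)]] <- slice$structure_key
        rep[[sprintf("n%d_exp", r)]] <-
          if (model$task == "continuous") as.numeric(slice$response)
          else as.character(slice$response)
        rep[[sprintf("n%d_pred", r)]] <-
          if (model$task == "continuous") as.numeric(slice$loo_pred)
          else as.character(slice$loo_pred)
        rep[[sprintf("n%d_dist", r)]] <- slice$distance
      }
    }
    rep
  })
  report <- dplyr::bind_rows(reports)
  if (!is.null(output)) {
    write_delimited(report, output)
    return(invisible(report))
  }
  report
}
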