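# Columns with a fixed meaning in modelling tables; everything else that is
# numeric is treated as a descriptor unless the user selects explicitly.
RESERVED_COLS <- c("id", "structure_key", "response", "source", "set")

#' Resolve the descriptor columns of a modelling table
#'
#' Most functions in knnqspr take a data frame whose rows are chemicals and
#' whose columns mix bookkeeping (`id`, `structure_key`, `response`, `source`,
#' `set`) with numeric molecular descriptors. This helper resolves which
#' columns are descriptors: by default every numeric, non-reserved column;
#' otherwise whatever a tidyselect expression or character vector picks.
#'
#' @param data A data frame of chemicals.
#' @param descriptors `NULL` (default: all numeric non-reserved columns), a
#'   tidyselect expression, or a character vector of column names.
#' @return A character vector of descriptor column names, in `data`'s order.
#' @export
#' @examples
#' d <- tibble::tibble(id = c("a", "b"), response = c(1, 2), x1 = c(0, 1), x2 = c(2, 3))
#' descriptor_names(d)
#' descriptor_names(d, x2)
descriptor_names <- function(data, descriptors = NULL) {
  q <- rlang::enquo(descriptors)
  default <- function() {
    cand <- setdiff(names(data), RESERVED_COLS)
    cand[vapply(data[cand], is.numeric, logical(1))]
  }
  if (rlang::quo_is_null(q)) return(default())
  # a plain value (NULL variable or character vector) short-circuits;
  # anything else is a tidyselect expression
  sentinel <- new.env()
  val <- tryCatch(rlang::eval_tidy(q), error = function(e) sentinel)
  if (is.null(val)) return(default())
  if (is.character(val)) {
    missing <- setdiff(val, names(data))
    if (length(missing) > 0) {
      stop("descriptor column(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(val)
  }
  names(tidyselect::eval_select(q, data))
}

# Run code with a temporary RNG state so seeded helpers do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Expand one user-facing seed into a reproducible vector of sub-seeds, so each
# component (fold maker, GA run, ...) gets an independent stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

chem_ids <- function(data) {
  if ("id" %in% names(data)) as.character(data$id) else as.character(seq_len(nrow(data)))
}

response_task <- function(response) {
  if (is.numeric(response)) "continuous" else "classification"
}

as_class_factor <- function(response) {
  if (is.factor(response)) response else factor(response)
}

# Descriptor sub-matrix as a plain numeric matrix with chemical ids as rownames.
descriptor_matrix <- function(data, descriptors) {
  m <- as.matrix(data[descriptors])
  if (!is.numeric(m)) stop("descriptor columns must be numeric", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- chem_ids(data)
  m
}

weighting_scheme_code <- function(weighting) {
  switch(weighting,
    inverse = 1L, shepard = 2L, exponential = 3L,
    stop("unknown weighting scheme: ", weighting, call. = FALSE)
  )
}

scheme_weight <- function(d, weighting, eps = 1e-12) {
  switch(weighting,
    inverse = 1 / pmax(d, eps),
    shepard = 1 / (1 + d),
    exponential = exp(-d),
    stop("unknown weighting scheme: ", weighting, call. = FALSE)
  )
}
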