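# Model serialization (JSON) and delimited-text I/O for raw signals,
# feature tables, and training logs.

.config_to_list <- function(config) {
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out$m) && is.infinite(out$m)) out$m <- "Inf"
  out
}

.config_from_list <- function(lst) {
  if (!is.null(lst$m) && identical(lst$m, "Inf")) lst$m <- Inf
  do.call(train_config, lst)
}

#' Save a trained network (and optionally its label map) as JSON
#'
#' Floats are written with 17 significant digits so the document round-trips
#' bit-exactly through [load_model()].
#'
#' @param state a `pgsom_network`.
#' @param file path of the JSON file to write.
#' @param labels optional [calibrate()] result to embed.
#' @return `file`, invisibly.
#' @export
save_model <- function(state, file, labels = NULL) {
  s <- seq_len(state$n)
  neurons <- lapply(s, function(k)
    list(id = state$id[k], row = state$pos[1L, k], col = state$pos[2L, k],
         age = state$age[k], ceq = state$ceq[k], w = state$W[, k]))
  obj <- list(mode = state$mode, dim = state$dim, eta = state$eta,
              presentations = state$presentations,
              scale = state$scale, neurons = neurons)
  if (!is.null(state$config)) obj$config <- .config_to_list(state$config)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "pgsom_labelmap"))
    obj$labels <- list(ids = labels$ids, labels = labels$labels,
                       direct = labels$direct, coverage = labels$coverage)
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), file)
  invisible(file)
}

#' Load a model saved by [save_model()]
#'
#' @param file path of the JSON model file.
#' @return A list with `network` (a `pgsom_network`) and `labels` (a
#'   `pgsom_labelmap`, or `NULL` if none was embedded).
#' @export
load_model <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  st <- .new_state(obj$dim, obj$mode, obj$eta,
                   capacity = max(64L, length(obj$neurons)))
  st$scale <- as.numeric(obj$scale)
  for (nr in obj$neurons)
    add_neuron(st, nr$row, nr$col, as.numeric(nr$w), ceq = nr$ceq, age = nr$age)
  ids <- vapply(obj$neurons, function(nr) as.integer(nr$id), integer(1))
  if (length(ids) > 0L) {
    st$id[seq_along(ids)] <- ids
    st$next_id <- max(ids) + 1L
  }
  st$presentations <- as.integer(obj$presentations)
  if (!is.null(obj$config)) st$config <- .config_from_list(obj$config)
  labels <- NULL
  if (!is.null(obj$labels))
    labels <- structure(list(ids = as.integer(obj$labels$ids),
                             labels = obj$labels$labels,
                             direct = as.logical(obj$labels$direct),
                             coverage = obj$labels$coverage),
                        class = "pgsom_labelmap")
  list(network = st, labels = labels)
}

#' Write the per-iteration training log
#'
#' One record per iteration (iteration, neuron_count, mean_qe, eta), as
#' tab-delimited text.
#'
#' @param state a trained `pgsom_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_training_log <- function(state, file) {
  utils::write.table(state$log, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a raw 7-channel sensor log from CSV
#'
#' Expects a header with columns `wrist_x, wrist_y, wrist_z, hip_x, hip_y,
#' hip_z, piezo` and optionally `label`.
#'
#' @param file CSV path.
#' @return A list with `data` (numeric matrix, the 7 channels in canonical
#'   order) and `labels` (per-row labels, or `NULL`).
#' @export
read_raw_csv <- function(file) {
  df <- utils::read.csv(file)
  missing <- setdiff(raw_channel_names(), names(df))
  if (length(missing) > 0L)
    stop("raw CSV is missing channel column(s): ", paste(missing, collapse = ", "))
  labels <- if ("label" %in% names(df)) df$label else NULL
  list(data = as.matrix(df[raw_channel_names()]), labels = labels)
}

#' Write a feature matrix (plus optional labels) as CSV
#'
#' @param x feature matrix with one window per row.
#' @param file CSV path.
#' @param y optional labels, one per row.
#' @return `file`, invisibly.
#' @export
write_features_csv <- function(x, file, y = NULL) {
  df <- as.data.frame(x)
  if (is.null(colnames(x)) && ncol(x) == length(feature_names()))
    names(df) <- feature_names()
  if (!is.null(y)) df$label <- y
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a feature CSV written by [write_features_csv()]
#'
#' @param file CSV path.
#' @return A list with `x` (numeric feature matrix) and `y` (labels or `NULL`).
#' @export
read_features_csv <- function(file) {
  df <- utils::read.csv(file)
  y <- NULL
  if ("label" %in% names(df)) {
    y <- df$label
    df$label <- NULL
  }
  list(x = as.matrix(df), y = y)
}
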