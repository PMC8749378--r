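# Evaluation machinery: confusion matrices, accuracy / Cohen's kappa / macro
# recall / macro F-measure, stratified k-fold cross-validation with the
# batch-training + calibration protocol, and the SF x RF grid search.

#' Confusion matrix (rows = truth, columns = prediction)
#'
#' @param truth true class labels.
#' @param pred predicted class labels.
#' @param classes class universe; defaults to the sorted union of both.
#' @return A K x K integer matrix with dimnames `truth` / `predicted`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  stopifnot(length(truth) == length(pred))
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = as.character(classes),
                               predicted = as.character(classes)))
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is trace over total. Cohen's kappa is `(p_o - p_e) / (1 - p_e)`
#' with the expected agreement `p_e` from the row/column marginals (1 when
#' observed and chance agreement are both perfect, 0 when chance agreement is
#' perfect but observed is not). Macro recall and macro F-measure average
#' over classes that have at least one true sample; per-class precision and
#' F1 are 0 when their denominators vanish.
#'
#' @param cm a confusion matrix as from [confusion_matrix()].
#' @return A list with `accuracy`, `kappa`, `macro_recall`, `macro_f1`,
#'   `per_class_recall` (named) and `n` (total samples).
#' @export
metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("metrics(): empty confusion matrix")
  stopifnot(nrow(cm) == ncol(cm))
  diag_ <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  po <- sum(diag_) / n
  pe <- sum(rows * cols) / n^2
  kappa <- if (1 - pe < .Machine$double.eps) {
    if (po >= 1) 1 else 0
  } else (po - pe) / (1 - pe)
  present <- rows > 0
  recall <- ifelse(rows > 0, diag_ / rows, NA_real_)
  precision <- ifelse(cols > 0, diag_ / cols, 0)
  f1 <- ifelse(precision + recall > 0 & !is.na(recall),
               2 * precision * recall / (precision + recall), 0)
  names(recall) <- rownames(cm)
  list(accuracy = po, kappa = kappa,
       macro_recall = mean(recall[present]),
       macro_f1 = mean(f1[present]),
       per_class_recall = recall, n = n)
}

#' Evaluate a calibrated network on labeled data
#'
#' @param state a trained `pgsom_network`.
#' @param labelmap a [calibrate()] result.
#' @param x labeled evaluation samples (rows).
#' @param y true class labels.
#' @param classes class universe for the confusion matrix.
#' @return A list with the [metrics()] fields plus `confusion`,
#'   `neuron_count` and `inference_ms` (mean per-sample prediction time,
#'   informational only).
#' @export
evaluate_model <- function(state, labelmap, x, y, classes = NULL) {
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_labels(state, labelmap, x)
  dt <- proc.time()[["elapsed"]] - t0
  cm <- confusion_matrix(y, pred, classes)
  out <- metrics(cm)
  out$confusion <- cm
  out$neuron_count <- neuron_count(state)
  out$inference_ms <- 1000 * dt / max(1L, nrow(as.matrix(x)))
  out
}

# stratified fold assignment: classes are shuffled internally and fold labels
# dealt cyclically with a running offset, so fold sizes differ by at most one
# both overall and within each class
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validation of the train / calibrate / predict loop
#'
#' Folds are seeded and stratified by class. Per fold the network is trained
#' on the fold-train portion (per-iteration batches of `config$batch_size`),
#' calibrated with a fixed seeded subset of `calib_size` fold-train samples,
#' and evaluated on the held-out fold. A warning is emitted when a class is
#' absent from a held-out fold; macro metrics then cover the present classes.
#'
#' @param x feature matrix (rows = samples).
#' @param y class labels.
#' @param config a [train_config()] object.
#' @param k number of folds.
#' @param calib_size labeled samples used for calibration per fold.
#' @return An object of class `pgsom_cv`: list with `folds` (per-fold data
#'   frame of accuracy, kappa, macro_recall, macro_f1, neuron_count), `mean`
#'   and `sd` (named numeric summaries).
#' @export
cross_validate <- function(x, y, config, k = 10L,
                           calib_size = config$calib_size) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= k, k >= 2L)
  classes <- sort(unique(y))
  set.seed(config$seed)
  fold <- .stratified_folds(y, k)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (!all(classes %in% y[te]))
      warning("fold ", f, ": class(es) ",
              paste(setdiff(classes, y[te]), collapse = ", "),
              " absent from the held-out fold")
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    net <- train_network(x[tr, , drop = FALSE], cfg_f)
    set.seed(cfg_f$seed + 10000L)
    ci <- tr[sample.int(length(tr), min(calib_size, length(tr)))]
    lm <- calibrate(net, x[ci, , drop = FALSE], y[ci])
    ev <- evaluate_model(net, lm, x[te, , drop = FALSE], y[te], classes)
    res[[f]] <- data.frame(fold = f, accuracy = ev$accuracy, kappa = ev$kappa,
                           macro_recall = ev$macro_recall,
                           macro_f1 = ev$macro_f1,
                           neuron_count = ev$neuron_count)
  }
  folds <- do.call(rbind, res)
  num <- folds[, -1L]
  structure(list(folds = folds,
                 mean = colMeans(num),
                 sd = vapply(num, stats::sd, numeric(1))),
            class = "pgsom_cv")
}

#' @export
print.pgsom_cv <- function(x, ...) {
  cat("<pgsom_cv> ", nrow(x$folds), " folds: accuracy ",
      sprintf("%.3f +- %.3f", x$mean[["accuracy"]], x$sd[["accuracy"]]),
      ", kappa ", sprintf("%.3f", x$mean[["kappa"]]),
      ", mean neurons ", sprintf("%.1f", x$mean[["neuron_count"]]),
      "\n", sep = "")
  invisible(x)
}

#' Spread-factor / ratio-factor grid search
#'
#' Runs [cross_validate()] for every (SF, RF) cell with shared seeds and
#' collects mean accuracy and mean neuron count per cell.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param sf_values spread factors to try.
#' @param rf_values ratio factors to try.
#' @param config base [train_config()]; `sf`/`rf` are overridden per cell.
#' @param k folds per cell.
#' @return A data frame with one row per cell: `sf`, `rf`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_neurons`.
#' @export
grid_search <- function(x, y, sf_values, rf_values, config, k = 10L) {
  stopifnot(length(sf_values) > 0, length(rf_values) > 0)
  cells <- expand.grid(sf = sf_values, rf = rf_values,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$sf <- cells$sf[i]
    cfg$rf <- cells$rf[i]
    cfg$m <- NULL
    cv <- cross_validate(x, y, cfg, k = k)
    out[[i]] <- data.frame(sf = cells$sf[i], rf = cells$rf[i],
                           mean_accuracy = cv$mean[["accuracy"]],
                           sd_accuracy = cv$sd[["accuracy"]],
                           mean_neurons = cv$mean[["neuron_count"]])
  }
  do.call(rbind, out)
}

#' Percent reduction between two network sizes
#'
#' `100 * (1 - n_to / n_from)`: e.g. shrinking from 1254 to 856.1 neurons is
#' a 31.7 percent reduction.
#'
#' @param n_from reference size.
#' @param n_to reduced size.
#' @return Percentage reduction.
#' @export
percent_reduction <- function(n_from, n_to) {
  stopifnot(n_from > 0)
  100 * (1 - n_to / n_from)
}

#' Seeded train / validation split
#'
#' Splits `n` samples at the given ratio: `floor(ratio * n)` go to the
#' training pool, the rest to validation (8586 samples at 9:1 give 7727 and
#' 859).
#'
#' @param n number of samples.
#' @param ratio training fraction.
#' @param seed integer seed for the shuffle.
#' @return A list with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, ratio = 0.9, seed = 1L) {
  stopifnot(n >= 2L, ratio > 0, ratio < 1)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(ratio * n)
  list(train = sort(ord[seq_len(n_train)]),
       validation = sort(ord[(n_train + 1L):n]))
}
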