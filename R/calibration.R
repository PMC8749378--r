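# Neuron calibration: after unsupervised training, a small labeled subset is
# presented once; each activated neuron takes the majority class among the
# samples that activated it, and never-activated neurons inherit the label of
# the nearest directly-labeled neuron in weight space. Prediction then maps a
# sample to its winner's label.

# batched winner search (argmin only): for a block of samples the additive
# ||x||^2 term is constant per sample and cannot change the argmin, so only
# ||w||^2 - 2 x.w is compared. Ties go to the lowest slot (= lowest id).
.winner_slots_batch <- function(state, X, chunk = 1024L) {
  n <- state$n
  Wl <- state$W[, seq_len(n), drop = FALSE]
  wsql <- state$wsq[seq_len(n)]
  m <- nrow(X)
  out <- integer(m)
  at <- 1L
  while (at <= m) {
    hi <- min(at + chunk - 1L, m)
    blk <- t(X[at:hi, , drop = FALSE])                  # D x b
    D2 <- wsql - 2 * crossprod(Wl, blk)                 # n x b
    out[at:hi] <- max.col(-t(D2), ties.method = "first")
    at <- hi + 1L
  }
  out
}

.majority <- function(v) {
  u <- sort(unique(v))
  counts <- vapply(u, function(z) sum(v == z), integer(1))
  u[which.max(counts)]     # first maximum -> smallest label on ties
}

#' Label trained neurons from a small labeled subset
#'
#' Each labeled sample activates its winner neuron; every activated neuron is
#' assigned the majority class among its activating samples (ties break to
#' the smallest class label). Neurons never activated during calibration are
#' assigned the label of the nearest directly-labeled neuron in weight space
#' (Euclidean distance, ties to the smallest neuron id), so every live neuron
#' ends up with exactly one label.
#'
#' @param state a trained `pgsom_network`.
#' @param x_lab matrix of labeled samples (rows).
#' @param y_lab class labels, one per row of `x_lab`.
#' @return An object of class `pgsom_labelmap`: list with `ids` (live neuron
#'   ids), `labels` (one label per id), `direct` (logical, labeled by
#'   activation rather than propagation) and `coverage` (fraction labeled
#'   directly).
#' @export
calibrate <- function(state, x_lab, y_lab) {
  x_lab <- as.matrix(x_lab)
  if (nrow(x_lab) != length(y_lab))
    stop("calibrate(): ", nrow(x_lab), " samples but ", length(y_lab), " labels")
  if (nrow(x_lab) < 1L) stop("calibrate(): no labeled samples")
  if (ncol(x_lab) != state$dim)
    stop("calibrate(): sample dimension ", ncol(x_lab), " != network dimension ",
         state$dim)
  if (is.factor(y_lab)) y_lab <- as.character(y_lab)
  n <- state$n
  slots <- .winner_slots_batch(state, x_lab)
  labels <- rep(y_lab[1L][NA], n)
  direct <- logical(n)
  for (s in unique(slots)) {
    labels[s] <- .majority(y_lab[slots == s])
    direct[s] <- TRUE
  }
  if (!all(direct)) {
    lab_slots <- which(direct)
    Wl <- state$W[, seq_len(n), drop = FALSE]
    for (u in which(!direct)) {
      d <- colSums((Wl[, lab_slots, drop = FALSE] - Wl[, u])^2)
      labels[u] <- labels[lab_slots[which.min(d)]]   # lowest id on ties
    }
  }
  structure(list(ids = state$id[seq_len(n)], labels = labels,
                 direct = direct, coverage = mean(direct)),
            class = "pgsom_labelmap")
}

#' Classify samples by their winner neuron's label
#'
#' @param state a trained `pgsom_network`.
#' @param labelmap a [calibrate()] result covering all live neurons.
#' @param newdata matrix of samples to classify (rows).
#' @return Vector of predicted class labels, one per row.
#' @export
predict_labels <- function(state, labelmap, newdata) {
  stopifnot(inherits(labelmap, "pgsom_labelmap"))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != state$dim)
    stop("predict_labels(): sample dimension ", ncol(newdata),
         " != network dimension ", state$dim)
  live <- state$id[seq_len(state$n)]
  at <- match(live, labelmap$ids)
  if (anyNA(at))
    stop("predict_labels(): label map does not cover all live neurons")
  slots <- .winner_slots_batch(state, newdata)
  labelmap$labels[at][slots]
}

#' @export
print.pgsom_labelmap <- function(x, ...) {
  cat("<pgsom_labelmap> ", length(x$ids), " neurons, ",
      length(unique(x$labels)), " classes, coverage ",
      sprintf("%.1f%%", 100 * x$coverage), " direct\n", sep = "")
  invisible(x)
}
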