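# Feature pipeline: 30 Hz raw logs with 7 channels (wrist x/y/z, hip x/y/z,
# abdominal piezo) are cut into 500-sample windows; two synthetic
# acceleration magnitudes (wrist, hip) extend them to 9 signals; 11 summary
# statistics per signal plus 2 correlations with the piezo channel give the
# 101-dimensional feature vector (11 * 9 + 2).

#' Canonical raw channel order
#' @return Character vector of the 7 raw channel names.
#' @export
raw_channel_names <- function() {
  c("wrist_x", "wrist_y", "wrist_z", "hip_x", "hip_y", "hip_z", "piezo")
}

.signal_names <- function() {
  c("wrist_x", "wrist_y", "wrist_z", "hip_x", "hip_y", "hip_z", "piezo",
    "wrist_syn", "hip_syn")
}

.stat_names <- function() {
  c("mean", "variance", "rms", "kurtosis", "skewness", "energy",
    "p10", "p25", "p50", "p75", "p90")
}

#' Names of the 101 feature columns
#'
#' For each of the 9 signals (wrist x/y/z, hip x/y/z, piezo, wrist synthetic,
#' hip synthetic) the 11 statistics in order mean, variance, RMS, kurtosis,
#' skewness, energy, p10, p25, p50, p75, p90; then the correlation of the hip
#' synthetic signal with the piezo signal and of the wrist synthetic signal
#' with the piezo signal.
#'
#' @return Character vector of length 101.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(.signal_names(), .stat_names(), paste, sep = "_"))),
    "corr_hip_syn_piezo", "corr_wrist_syn_piezo")
}

#' Synthetic acceleration magnitude
#'
#' Elementwise Euclidean norm of a tri-axial accelerometer triple:
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param x,y,z equal-length numeric series.
#' @return Numeric series of the same length.
#' @examples
#' synthetic_acceleration(3, 4, 0)  # 5
#' @export
synthetic_acceleration <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    stop("synthetic_acceleration(): series lengths differ")
  sqrt(x^2 + y^2 + z^2)
}

#' Cut a raw log into fixed-length signal windows
#'
#' Consecutive windows of `width` rows are taken every `step` rows (default
#' non-overlapping); a trailing remainder shorter than `width` is dropped. A
#' window's label is the majority of its row labels (ties to the smallest).
#'
#' @param raw N x 7 numeric matrix or data frame; if it carries the canonical
#'   column names they are used to order the channels.
#' @param labels optional per-row labels of length N.
#' @param width window length in samples.
#' @param step stride between window starts.
#' @param fs sampling rate in Hz (carried on the windows, informational).
#' @return A list of windows, each a list with `samples` (width x 7 matrix),
#'   `label` (or `NA`) and `fs`. Empty (with a warning) when N < width.
#' @export
slide_windows <- function(raw, labels = NULL, width = 500L, step = width,
                          fs = 30) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.null(colnames(raw)) && all(raw_channel_names() %in% colnames(raw)))
    raw <- raw[, raw_channel_names(), drop = FALSE]
  if (ncol(raw) != 7L)
    stop("slide_windows(): expected 7 channels, got ", ncol(raw))
  n <- nrow(raw)
  if (!is.null(labels) && length(labels) != n)
    stop("slide_windows(): ", length(labels), " labels for ", n, " rows")
  if (n < width) {
    warning("fewer rows (", n, ") than the window width (", width,
            "); no windows produced")
    return(list())
  }
  starts <- seq.int(1L, n - width + 1L, by = step)
  lapply(starts, function(s) {
    rows <- s:(s + width - 1L)
    list(samples = raw[rows, , drop = FALSE],
         label = if (is.null(labels)) NA else .majority(labels[rows]),
         fs = fs)
  })
}

# one signal's 11 statistics. Conventions are pinned deliberately:
# population variance (divide by n), Fisher excess kurtosis (normal -> 0),
# Fisher-Pearson g1 skewness, energy = mean of squares (or plain sum),
# percentiles by linear interpolation between order statistics. A constant
# signal has zero central moments, so kurtosis and skewness are defined as 0.
.signal_stats <- function(v, energy = "mean") {
  n <- length(v)
  m <- mean(v)
  cv <- v - m
  m2 <- mean(cv^2)
  msq <- mean(v^2)
  if (m2 > 0) {
    kurt <- mean(cv^4) / m2^2 - 3
    skew <- mean(cv^3) / m2^1.5
  } else {
    kurt <- 0
    skew <- 0
  }
  c(m, m2, sqrt(msq), kurt, skew,
    if (energy == "sum") n * msq else msq,
    stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7))
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Extract the 101-dimensional feature vector of one window
#'
#' Builds the wrist and hip synthetic acceleration magnitudes, computes the
#' 11 statistics for each of the 9 signals, and appends the Pearson
#' correlations of the two synthetic signals with the piezo signal (0 when
#' either series is constant). See [feature_names()] for the ordering
#' contract and `.signal_stats` conventions in the source.
#'
#' @param win a window from [slide_windows()], or a bare numeric matrix with
#'   the 7 raw channels.
#' @param energy `"mean"` (mean of squares, scale-free in the window length)
#'   or `"sum"` (plain sum of squares).
#' @return Named numeric vector of length 101.
#' @export
extract_features <- function(win, energy = c("mean", "sum")) {
  energy <- match.arg(energy)
  samples <- if (is.list(win)) win$samples else win
  if (ncol(samples) != 7L)
    stop("extract_features(): expected 7 channels, got ", ncol(samples))
  for (k in seq_len(7L))
    if (anyNA(samples[, k]))
      stop("extract_features(): channel ", raw_channel_names()[k],
           " contains NaN/NA values")
  wrist_syn <- synthetic_acceleration(samples[, 1L], samples[, 2L], samples[, 3L])
  hip_syn <- synthetic_acceleration(samples[, 4L], samples[, 5L], samples[, 6L])
  signals <- cbind(samples, wrist_syn, hip_syn)
  stats9 <- as.vector(apply(signals, 2L, .signal_stats, energy = energy))
  out <- c(stats9,
           .safe_cor(hip_syn, samples[, 7L]),
           .safe_cor(wrist_syn, samples[, 7L]))
  names(out) <- feature_names()
  out
}

#' Raw log to feature matrix
#'
#' Convenience wrapper: [slide_windows()] then [extract_features()] per
#' window.
#'
#' @inheritParams slide_windows
#' @inheritParams extract_features
#' @return A list with `x` (windows x 101 feature matrix) and `y` (window
#'   labels, or `NULL` when no labels were given).
#' @export
extract_feature_matrix <- function(raw, labels = NULL, width = 500L,
                                   step = width, fs = 30,
                                   energy = c("mean", "sum")) {
  energy <- match.arg(energy)
  wins <- slide_windows(raw, labels, width = width, step = step, fs = fs)
  if (length(wins) == 0L)
    return(list(x = matrix(numeric(), 0L, 101L,
                           dimnames = list(NULL, feature_names())),
                y = NULL))
  x <- t(vapply(wins, extract_features, numeric(101L), energy = energy))
  y <- if (is.null(labels)) NULL else vapply(wins, `[[`, labels[1L][NA], "label")
  list(x = x, y = y)
}

#' Z-score features by training-set statistics
#'
#' Columns are centered and scaled by the training mean and standard
#' deviation; constant columns pass through unchanged. The returned scaler
#' can be reused on further data and inverted with [unstandardize()].
#'
#' @param train training feature matrix (statistics are estimated here).
#' @param other optional further matrix scaled with the training statistics.
#' @return A list with `train`, `other` (or `NULL`) and `scaler` (list with
#'   `center`, `scale`).
#' @export
standardize <- function(train, other = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) > 0L)
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  constant <- !is.finite(scale) | scale == 0
  center[constant] <- 0
  scale[constant] <- 1
  apply_scaler <- function(x) sweep(sweep(x, 2L, center), 2L, scale, "/")
  list(train = apply_scaler(train),
       other = if (is.null(other)) NULL else apply_scaler(as.matrix(other)),
       scaler = list(center = center, scale = scale))
}

#' Invert [standardize()]
#'
#' @param x a scaled matrix.
#' @param scaler the `scaler` element of a [standardize()] result.
#' @return The matrix on the original scale.
#' @export
unstandardize <- function(x, scaler) {
  sweep(sweep(as.matrix(x), 2L, scaler$scale, "*"), 2L, scaler$center, "+")
}
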