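# Synthetic data with the statistical structure the method assumes: nine
# imbalanced activity classes (the reference study's per-class sample counts
# are the default proportions), isotropic Gaussian clusters in feature space
# with unit within-class standard deviation, and one deliberately overlapping
# class pair emulating the walking / low-speed-running confusion. A raw-signal
# generator (class-specific sinusoids at 30 Hz plus noise) exercises the
# feature pipeline end to end.

.default_class_counts <- function() {
  c(1635, 807, 794, 840, 1549, 1646, 494, 359, 462)
}

#' Synthetic dataset configuration
#'
#' @param n_classes number of activity classes.
#' @param class_proportions class proportions summing to 1. Default: the nine
#'   imbalanced activity counts (1635, 807, 794, 840, 1549, 1646, 494, 359,
#'   462), normalized.
#' @param dim feature dimensionality.
#' @param separation distance of class centroids from the origin, in units of
#'   the within-class standard deviation (centroids are drawn on a sphere of
#'   this radius).
#' @param overlap_pairs list of class index pairs whose centroids are pulled
#'   to `separation / 4` apart, creating deliberate confusion. Default:
#'   classes 4 and 6 (walking vs low-speed running).
#' @param n_samples total number of samples.
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 9L, class_proportions = NULL, dim = 101L,
                         separation = 8, overlap_pairs = list(c(4L, 6L)),
                         n_samples = 8586L, seed = 1L) {
  if (is.null(class_proportions)) {
    counts <- .default_class_counts()
    if (n_classes != 9L) counts <- rep(1, n_classes)
    class_proportions <- counts / sum(counts)
  }
  stopifnot(length(class_proportions) == n_classes,
            abs(sum(class_proportions) - 1) <= 1e-9,
            separation >= 0, dim >= 1, n_samples >= n_classes)
  for (p in overlap_pairs)
    stopifnot(length(p) == 2L, all(p >= 1), all(p <= n_classes))
  structure(list(n_classes = as.integer(n_classes),
                 class_proportions = class_proportions,
                 dim = as.integer(dim), separation = separation,
                 overlap_pairs = overlap_pairs,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "synth_config")
}

# deterministic largest-remainder rounding of n * proportions
.round_counts <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic feature dataset
#'
#' Isotropic Gaussian clusters with unit within-class standard deviation.
#' Class centroids are drawn (seeded) uniformly on a sphere of radius
#' `separation`; each overlap pair then has its two centroids moved to
#' `separation / 4` apart around their midpoint. Class sizes follow the
#' configured proportions by largest-remainder rounding (each within one of
#' `n_samples * proportion`). Rows are shuffled; everything is deterministic
#' under the seed.
#'
#' @param cfg a [synth_config()] object.
#' @return A list with `x` (n x dim matrix), `y` (integer class labels
#'   1..n_classes) and `centroids` (n_classes x dim).
#' @export
make_feature_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  K <- cfg$n_classes
  D <- cfg$dim
  centroids <- matrix(0, K, D)
  for (k in seq_len(K)) {
    z <- stats::rnorm(D)
    nz <- sqrt(sum(z^2))
    if (nz > 0) centroids[k, ] <- z / nz * cfg$separation
  }
  for (p in cfg$overlap_pairs) {
    a <- p[[1]]; b <- p[[2]]
    mid <- (centroids[a, ] + centroids[b, ]) / 2
    u <- centroids[b, ] - centroids[a, ]
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(1, rep(0, D - 1L))
    centroids[a, ] <- mid - u * cfg$separation / 8
    centroids[b, ] <- mid + u * cfg$separation / 8
  }
  counts <- .round_counts(cfg$class_proportions, cfg$n_samples)
  n <- sum(counts)
  x <- matrix(0, n, D)
  y <- integer(n)
  at <- 0L
  for (k in seq_len(K)) {
    if (counts[k] == 0L) next
    rows <- at + seq_len(counts[k])
    x[rows, ] <- matrix(stats::rnorm(counts[k] * D), counts[k], D) +
      matrix(centroids[k, ], counts[k], D, byrow = TRUE)
    y[rows] <- k
    at <- at + counts[k]
  }
  ord <- sample.int(n)
  colnames(x) <- if (D == 101L) feature_names() else paste0("f", seq_len(D))
  list(x = x[ord, , drop = FALSE], y = y[ord], centroids = centroids)
}

#' Generate a raw 7-channel sensor log
#'
#' Each class is a bout of class-specific sinusoids: one frequency per class
#' (equally spaced over 0.5-4 Hz), seeded per-channel amplitudes and phases,
#' Gaussian noise, sampled at `fs` Hz. Bouts are at least one window long so
#' [slide_windows()] always produces windows.
#'
#' @param cfg a [synth_config()] object (`n_classes` and `seed` are used).
#' @param rows_per_class bout length per class in samples (>= 500).
#' @param noise_sd standard deviation of the additive Gaussian noise; 0 gives
#'   the clean deterministic waveform.
#' @param fs sampling rate in Hz.
#' @return A list with `data` (rows x 7 matrix, canonical channel names) and
#'   `labels` (per-row class labels).
#' @export
make_raw_dataset <- function(cfg, rows_per_class = 1500L, noise_sd = 0.2,
                             fs = 30) {
  stopifnot(inherits(cfg, "synth_config"), rows_per_class >= 500L,
            noise_sd >= 0)
  set.seed(cfg$seed)
  K <- cfg$n_classes
  freqs <- seq(0.5, 4, length.out = K)
  t <- (seq_len(rows_per_class) - 1L) / fs
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    amp <- stats::runif(7L, 0.5, 2)
    phase <- stats::runif(7L, 0, 2 * pi)
    clean <- vapply(seq_len(7L),
                    function(ch) amp[ch] * sin(2 * pi * freqs[k] * t + phase[ch]),
                    numeric(rows_per_class))
    blocks[[k]] <- clean + matrix(stats::rnorm(rows_per_class * 7L, 0, noise_sd),
                                  rows_per_class, 7L)
  }
  data <- do.call(rbind, blocks)
  colnames(data) <- raw_channel_names()
  list(data = data, labels = rep(seq_len(K), each = rows_per_class))
}
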