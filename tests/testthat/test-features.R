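test_that("synthetic acceleration is the elementwise Euclidean norm", {
  expect_equal(synthetic_acceleration(3, 4, 0), 5)
  expect_equal(synthetic_acceleration(0, 0, 0), 0)
  expect_equal(synthetic_acceleration(c(-2, 7), c(0, 0), c(0, 0)), c(2, 7))
  expect_error(synthetic_acceleration(1:3, 1:2, 1:3), "lengths differ")
})

test_that("window slicing honors width, step and the remainder rule", {
  raw <- matrix(rnorm(1499 * 7), ncol = 7)
  expect_length(slide_windows(raw[1:1000, ]), 2L)
  expect_length(slide_windows(raw), 2L)                 # remainder dropped
  expect_length(slide_windows(raw[1:1000, ], step = 250), 3L)
  expect_warning(w <- slide_windows(raw[1:100, ]), "window width")
  expect_length(w, 0L)
  # window labels: majority with smallest-label tie-break
  labels <- c(rep(1L, 200), rep(2L, 300), rep(2L, 250), rep(3L, 250))
  wins <- slide_windows(raw[1:1000, ], labels)
  expect_identical(wins[[1]]$label, 2L)
  expect_identical(wins[[2]]$label, 2L)   # tie 250/250 -> smallest label
})

test_that("a valid window yields exactly 101 named features", {
  fv <- extract_features(random_window(1))
  expect_length(fv, 101L)
  expect_identical(names(fv), feature_names())
  expect_identical(length(feature_names()), 11L * 9L + 2L)
})

test_that("constant windows produce the degenerate statistics exactly", {
  m <- matrix(2, nrow = 500, ncol = 7)
  fv <- extract_features(m)
  expect_equal(unname(fv["piezo_mean"]), 2)
  expect_equal(unname(fv["piezo_variance"]), 0)
  expect_equal(unname(fv["piezo_rms"]), 2)
  expect_equal(unname(fv["piezo_energy"]), 4)
  expect_equal(unname(fv[paste0("piezo_p", c(10, 25, 50, 75, 90))]), rep(2, 5))
  expect_equal(unname(fv["piezo_kurtosis"]), 0)
  expect_equal(unname(fv["piezo_skewness"]), 0)
  # synthetic channels: sqrt(3 * 2^2)
  expect_equal(unname(fv["wrist_syn_mean"]), 2 * sqrt(3))
  expect_equal(unname(fv[c("corr_hip_syn_piezo", "corr_wrist_syn_piezo")]),
               c(0, 0))
})

test_that("every statistic matches an independent reimplementation", {
  m <- random_window(33)
  fv <- extract_features(m)
  wrist_syn <- sqrt(rowSums(m[, 1:3]^2))
  hip_syn <- sqrt(rowSums(m[, 4:6]^2))
  signals <- cbind(m, wrist_syn, hip_syn)
  for (k in 1:9) {
    v <- signals[, k]
    sig <- pgsom:::.signal_names()[k]
    expect_equal(unname(fv[paste0(sig, "_mean")]), mean(v))
    expect_equal(unname(fv[paste0(sig, "_variance")]),
                 sum((v - mean(v))^2) / length(v))
    expect_equal(unname(fv[paste0(sig, "_rms")]), sqrt(mean(v^2)))
    expect_equal(unname(fv[paste0(sig, "_energy")]), sum(v^2) / length(v))
    # e1071's type-1 estimators are the population-moment conventions used here
    expect_equal(unname(fv[paste0(sig, "_kurtosis")]),
                 e1071::kurtosis(v, type = 1))
    expect_equal(unname(fv[paste0(sig, "_skewness")]),
                 e1071::skewness(v, type = 1))
    expect_equal(unname(fv[paste0(sig, "_p", c(10, 25, 50, 75, 90))]),
                 unname(quantile(v, c(.1, .25, .5, .75, .9))))
  }
  expect_equal(unname(fv["corr_hip_syn_piezo"]), cor(hip_syn, m[, 7]))
  expect_equal(unname(fv["corr_wrist_syn_piezo"]), cor(wrist_syn, m[, 7]))
  # energy convention switch: plain sum of squares
  fv_sum <- extract_features(m, energy = "sum")
  expect_equal(unname(fv_sum["piezo_energy"]), sum(m[, 7]^2))
})

test_that("NaN input is rejected with the offending channel named", {
  m <- random_window(2)
  m[40, 4] <- NaN
  expect_error(extract_features(m), "hip_x")
})

test_that("feature extraction has no cross-window state", {
  raw <- matrix(rnorm(1500 * 7), ncol = 7)
  fm <- extract_feature_matrix(raw, labels = rep(1:3, each = 500))
  expect_equal(dim(fm$x), c(3L, 101L))
  expect_identical(fm$y, 1:3)
  # each row equals the window extracted in isolation
  for (i in 1:3)
    expect_equal(fm$x[i, ],
                 extract_features(raw[(i - 1) * 500 + 1:500, ]))
})

test_that("standardization is invertible and keeps constant columns", {
  set.seed(4)
  x <- cbind(matrix(rnorm(60, 5, 2), ncol = 3), const = 7)
  out <- standardize(x, x[1:5, ])
  expect_equal(unname(colMeans(out$train)[1:3]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(out$train, 2, sd)[1:3]), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(out$train[, 4]), rep(7, 20))
  expect_equal(unstandardize(out$other, out$scaler), unname(x[1:5, ]),
               ignore_attr = TRUE, tolerance = 1e-9)
})
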