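test_that("find_winner picks the nearest neuron with exact distances", {
  st <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(3, 4)))
  # exact match gives distance 0
  fw <- find_winner(st, c(3, 4))
  expect_identical(fw$id, 2L)
  expect_identical(fw$d, 0)
  # squared distances: 1 vs 18
  fw <- find_winner(st, c(0, 1))
  expect_identical(fw$id, 1L)
  expect_equal(fw$d, 1)
  expect_error(find_winner(st, c(1, 2, 3)), "dimension")
})

test_that("find_winner matches an exhaustive linear scan on random networks", {
  set.seed(7)
  st <- build_network(cbind(0L, seq_len(50L)),
                      matrix(rnorm(50 * 6), ncol = 6))
  w <- neuron_weights(st)
  for (rep in 1:20) {
    x <- rnorm(6)
    d_all <- colSums((t(w) - x)^2)
    fw <- find_winner(st, x)
    expect_identical(fw$id, unname(which.min(d_all)))
    expect_equal(fw$d, min(d_all), tolerance = 1e-12)
  }
})

test_that("learning-rate decay follows (1 - R/n) with floor and warning", {
  expect_equal(decay_eta(0.1, 1, 100), 0.099)
  expect_equal(decay_eta(0.5, 0, 10), 0.5)
  # repeated application is monotone non-increasing
  eta <- 0.3
  for (i in 1:50) {
    eta2 <- decay_eta(eta, 1, 7)
    expect_lte(eta2, eta)
    eta <- eta2
  }
  expect_gte(eta, 1e-4)
  # degenerate configuration: R >= n
  expect_warning(out <- decay_eta(0.2, 5, 4), "clamped")
  expect_equal(out, 1e-4)
})

test_that("error accumulation touches only the winner", {
  st <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(5, 5)))
  accumulate_error(st, 1L, d = 4, eta = 0.1)
  expect_equal(st$ceq[1:2], c(0.4, 0))
  accumulate_error(st, 1L, d = 0, eta = 0.1)
  expect_equal(st$ceq[1:2], c(0.4, 0))
  total_before <- sum(st$ceq)
  accumulate_error(st, 2L, d = 2, eta = 0.5)
  expect_equal(sum(st$ceq) - total_before, 1)
})

test_that("weight update moves the winner to the input and damps neighbors", {
  # x equal to all weights: nothing moves
  st <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(1, 2), c(1, 2)))
  update_weights(st, 1L, c(1, 2), eta = 0.5)
  expect_equal(neuron_weights(st), rbind(`1` = c(1, 2), `2` = c(1, 2)))

  # full-step update on an isolated winner lands exactly on the input
  st <- build_network(rbind(c(0, 0)), rbind(c(5, -3)))
  update_weights(st, 1L, c(1, 1), eta = 1)
  expect_equal(unname(neuron_weights(st)[1, ]), c(1, 1))

  # a neighbor already at the winner's pre-update weight does not move
  st <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(2, 2), c(2, 2)))
  update_weights(st, 1L, c(0, 0), eta = 0.25)
  expect_equal(unname(neuron_weights(st)[1, ]), c(1.5, 1.5))
  expect_equal(unname(neuron_weights(st)[2, ]), c(2, 2))

  # neighbor pulled toward the winner's old weight, damped by exp(-d_i/tau)
  st <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(2, 0), c(0, 0)))
  update_weights(st, 1L, c(4, 0), eta = 0.5, tau = 1)
  expect_equal(unname(neuron_weights(st)[2, ]),
               c(0, 0) + 0.5 * (c(2, 0) - c(0, 0)) * exp(-16))
})

test_that("growth threshold is -D log(SF), positive and decreasing in SF", {
  expect_equal(growth_threshold(101, 0.8), 22.53749868273518, tolerance = 1e-13)
  expect_equal(growth_threshold(1, exp(-1)), 1)
  sf <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  gt <- vapply(sf, function(s) growth_threshold(20, s), numeric(1))
  expect_true(all(diff(gt) < 0))
  expect_true(all(gt > 0))
  expect_error(growth_threshold(10, 1), "between 0 and 1")
  expect_error(growth_threshold(10, 0), "between 0 and 1")
})

test_that("age threshold rounds RF x batch half-up", {
  expect_identical(age_threshold(1.25, 4000), 5000L)
  expect_identical(age_threshold(1, 100), 100L)
  expect_identical(age_threshold(1.5, 4000), 6000L)
  # half-up, not banker's rounding
  expect_identical(age_threshold(0.0005, 1000), 1L)
  expect_identical(age_threshold(1.0005, 1000), 1001L)
})

test_that("boundary winners grow into every free slot, resetting their error", {
  gt <- growth_threshold(2, 0.5)

  # below threshold: nothing happens
  st <- build_network(rbind(c(0, 0)), rbind(c(0, 0)))
  st$ceq[1] <- gt - 1e-9
  expect_identical(grow_or_redistribute(st, 1L, gt), integer(0))
  expect_identical(neuron_count(st), 1L)

  # isolated winner over threshold: 4 new neurons, winner error cleared
  st <- build_network(rbind(c(0, 0)), rbind(c(1, 1)))
  st$ceq[1] <- gt + 1
  new_ids <- grow_or_redistribute(st, 1L, gt)
  expect_identical(new_ids, 2:5)
  expect_identical(neuron_count(st), 5L)
  expect_equal(st$ceq[1], 0)
  df <- neurons(st)
  expect_setequal(paste(df$row, df$col)[-1], c("-1 0", "1 0", "0 -1", "0 1"))
  expect_true(all(df$age == 0L), TRUE)
})

test_that("interior winners redistribute half their error equally, conserving totals", {
  st <- plus_network()
  st$ceq[1] <- 10
  expect_identical(grow_or_redistribute(st, 1L, gt = 8), integer(0))
  expect_equal(st$ceq[1:5], c(5, 1.25, 1.25, 1.25, 1.25))
  expect_identical(neuron_count(st), 5L)
})

test_that("weight interpolation follows the opposite/midpoint/perturbation ladder", {
  # (a) opposite neighbor occupied: linear extrapolation
  st <- build_network(rbind(c(0, 0), c(0, -1)), rbind(c(1, 1), c(0, 0)))
  expect_equal(interpolate_weight(st, 1L, c(0, 1)), c(2, 2))

  # (b) no opposite, another neighbor occupied: midpoint with lowest id
  st <- build_network(rbind(c(0, 0), c(1, 0)), rbind(c(2, 0), c(0, 0)))
  expect_equal(interpolate_weight(st, 1L, c(0, 1)), c(1, 0))

  # (c) lone neuron: bounded seeded perturbation
  st <- build_network(rbind(c(0, 0)), rbind(c(3, 3)))
  st$scale <- c(2, 2)
  set.seed(11)
  w1 <- interpolate_weight(st, 1L, c(0, 1))
  set.seed(11)
  w2 <- interpolate_weight(st, 1L, c(0, 1))
  expect_identical(w1, w2)
  expect_true(all(abs(w1 - c(3, 3)) <= 0.01 * st$scale))

  st2 <- build_network(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0), c(1, 1)))
  expect_error(interpolate_weight(st2, 1L, c(0, 1)), "occupied")
})

test_that("age update zeroes winner and newborns and ages the rest", {
  st <- build_network(rbind(c(0, 0), c(0, 1), c(0, 2)),
                      matrix(rnorm(6), ncol = 2))
  st$age[1:3] <- c(5L, 2L, 0L)
  update_ages(st, 1L)
  expect_identical(st$age[1:3], c(0L, 3L, 1L))
  # single-neuron network: always the winner, age pinned at 0
  st1 <- build_network(rbind(c(0, 0)), rbind(c(0, 0)))
  for (i in 1:5) update_ages(st1, 1L)
  expect_identical(st1$age[1], 0L)
})

test_that("pruning removes exactly the neurons whose age exceeds M", {
  st <- build_network(rbind(c(0, 0), c(0, 1), c(0, 2)),
                      matrix(rnorm(6), ncol = 2), mode = "pgsom")
  m <- 4L
  st$age[1:3] <- c(0L, m, m + 1L)
  removed <- prune(st, m)
  expect_identical(removed, 3L)
  expect_identical(neurons(st)$id, c(1L, 2L))
  # all ages within threshold: no removal
  expect_identical(prune(st, m), integer(0))
  # infinite threshold is the identity
  st$age[1:2] <- c(1000L, 2000L)
  expect_identical(prune(st, Inf), integer(0))
  expect_identical(neuron_count(st), 2L)
  # never prune to an empty network: youngest survivor retained
  st$age[1:2] <- c(7L, 9L)
  expect_warning(removed <- prune(st, 5), "youngest")
  expect_identical(removed, 2L)
  expect_identical(neurons(st)$id, 1L)
})
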