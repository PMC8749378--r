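test_that("training is deterministic and initialization matches the mode", {
  d <- two_cluster_data(n = 120, dim = 3, seed = 5)

  # GSOM/PGSOM start from the canonical 2x2 square
  cfg0 <- train_config("gsom", sf = 0.5, batch_size = 20, max_iter = 0, seed = 1)
  net0 <- train_network(d$x, cfg0)
  expect_identical(neuron_count(net0), 4L)
  expect_setequal(paste(neurons(net0)$row, neurons(net0)$col),
                  c("0 0", "0 1", "1 0", "1 1"))
  expect_equal(net0$eta, cfg0$eta0)

  # SOM mode starts (and stays) on its fixed grid
  cfgs <- train_config("som", som_rows = 3, som_cols = 4, batch_size = 30,
                       max_iter = 3, seed = 2)
  nets <- train_network(d$x, cfgs)
  expect_identical(neuron_count(nets), 12L)
  expect_true(all(nets$log$neuron_count == 12L))

  # bit-identical repeat runs under the same seed
  cfg <- train_config("pgsom", sf = 0.6, batch_size = 40, max_iter = 4, seed = 9)
  n1 <- train_network(d$x, cfg)
  n2 <- train_network(d$x, cfg)
  expect_identical(neuron_weights(n1), neuron_weights(n2))
  expect_identical(neurons(n1), neurons(n2))
  expect_identical(n1$eta, n2$eta)
})

test_that("GSOM grows beyond its four seeds and never shrinks", {
  d <- two_cluster_data(n = 200, dim = 2, seed = 3)
  cfg <- train_config("gsom", sf = 0.9, batch_size = 100, max_iter = 1, seed = 4)
  net <- train_network(d$x, cfg)
  expect_gt(neuron_count(net), 4L)
  cfg5 <- train_config("gsom", sf = 0.9, batch_size = 50, max_iter = 5, seed = 4)
  net5 <- train_network(d$x, cfg5)
  expect_true(all(diff(net5$log$neuron_count) >= 0))
})

test_that("eta is monotone non-increasing over training", {
  d <- two_cluster_data(n = 200, dim = 4, seed = 6)
  cfg <- train_config("pgsom", sf = 0.7, batch_size = 50, max_iter = 8, seed = 2)
  net <- train_network(d$x, cfg)
  expect_true(all(diff(net$log$eta) <= 0))
  expect_lte(net$log$eta[1], cfg$eta0)
  expect_gte(net$eta, cfg$eta_min)
})

test_that("PGSOM keeps every age within the threshold and the index bijective", {
  d <- two_cluster_data(n = 300, dim = 3, seed = 8)
  cfg <- train_config("pgsom", sf = 0.8, rf = 1, batch_size = 60, max_iter = 6,
                      seed = 3)
  net <- train_network(d$x, cfg)
  m <- resolve_age_threshold(cfg)
  df <- neurons(net)
  expect_true(all(df$age <= m))
  expect_true(all(df$ceq >= 0))
  # position-index bijection after growth and pruning
  expect_equal(length(ls(net$index)), nrow(df))
  for (i in seq_len(nrow(df))) {
    slot <- pgsom:::.slot_at(net, df$row[i], df$col[i])
    expect_identical(net$id[slot], df$id[i])
  }
  # ids are unique and slot order is id order
  expect_identical(df$id, sort(unique(df$id)))
})

test_that("the batch kernel and stepwise presentation are the same algorithm", {
  d <- two_cluster_data(n = 150, dim = 3, seed = 10)
  for (mode in c("som", "gsom", "pgsom")) {
    cfg <- train_config(mode, sf = 0.6, rf = 1, batch_size = 30, max_iter = 2,
                        seed = 13, som_rows = 3, som_cols = 3)
    kernel <- train_network(d$x, cfg)
    set.seed(cfg$seed)
    manual <- pgsom:::.init_network(d$x, cfg)
    for (it in 1:2) {
      idx <- sample.int(nrow(d$x), cfg$batch_size)
      for (j in idx) present_sample(manual, d$x[j, ], cfg)
      manual$eta <- decay_eta(manual$eta, cfg$r, manual$n, cfg$eta_min)
    }
    expect_identical(neuron_weights(kernel), neuron_weights(manual))
    expect_identical(neurons(kernel), neurons(manual))
    expect_equal(kernel$eta, manual$eta)
    expect_identical(kernel$presentations, manual$presentations)
  }
})

test_that("training rejects empty or non-finite input", {
  cfg <- train_config("gsom", batch_size = 10, max_iter = 1)
  expect_error(train_network(matrix(numeric(), 0, 3), cfg), "empty")
  x <- matrix(rnorm(30), 10, 3)
  x[4, 2] <- NA
  expect_error(train_network(x, cfg), "non-finite")
})
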