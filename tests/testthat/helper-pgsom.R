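# Test builders: hand-assembled networks and small seeded datasets.

# network with explicitly placed neurons (one row of `positions`/`weights`
# per neuron, in id order)
build_network <- function(positions, weights, mode = "gsom", eta = 0.3) {
  weights <- as.matrix(weights)
  st <- new_network(ncol(weights), mode, eta)
  for (i in seq_len(nrow(positions)))
    add_neuron(st, positions[i, 1], positions[i, 2], weights[i, ])
  st
}

# fully occupied rows x cols block with seeded random weights
block_network <- function(rows, cols, dim = 2, seed = 1, mode = "gsom") {
  set.seed(seed)
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  build_network(cbind(grid$row, grid$col),
                matrix(rnorm(rows * cols * dim), ncol = dim), mode = mode)
}

# plus-shaped network: interior center at (0,0) with its four neighbors
plus_network <- function(dim = 2, seed = 1) {
  set.seed(seed)
  build_network(rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
                matrix(rnorm(5 * dim), ncol = dim))
}

# two well-separated seeded Gaussian clusters in D dimensions
two_cluster_data <- function(n = 200, dim = 2, seed = 1, gap = 10) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * dim), ncol = dim),
             matrix(rnorm(n / 2 * dim, mean = gap), ncol = dim))
  list(x = x, y = rep(1:2, each = n / 2))
}

# a plausible 500 x 7 signal window with optional seeded noise
random_window <- function(seed = 1, width = 500) {
  set.seed(seed)
  t <- seq_len(width) / 30
  m <- vapply(seq_len(7), function(ch)
    sin(2 * pi * ch / 4 * t) + rnorm(width, sd = 0.3), numeric(width))
  colnames(m) <- raw_channel_names()
  m
}
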