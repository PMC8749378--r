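# Training protocol: seeded batch iterations over a sample pool. Defaults
# mirror the reference protocol (SF 0.8, RF 1.5, batches of 4000, 50
# iterations, calibration subset of 2000). The learning rate decays once per
# presentation and is continuous across iterations (no per-iteration reset).

#' Training configuration
#'
#' @param mode `"pgsom"` (grow and prune), `"gsom"` (grow only) or `"som"`
#'   (fixed `som_rows` x `som_cols` grid).
#' @param sf spread factor in (0, 1); larger values ease growth.
#' @param rf ratio factor; the age threshold is `round(rf * batch_size)`.
#'   Ignored when `m` is given or in SOM/GSOM modes.
#' @param m explicit age threshold overriding `rf`; `Inf` disables pruning.
#' @param eta0 initial learning rate.
#' @param r learning-rate decay constant: the decay step multiplies eta by
#'   `1 - r / n_neurons` (floored at `eta_min`).
#' @param eta_decay cadence of the decay step. `"iteration"` (default) decays
#'   once per training iteration, so eta anneals over the `max_iter` batches;
#'   `"presentation"` decays after every sample. With per-presentation decay
#'   and the default `r`, eta hits the floor within a few dozen samples while
#'   the network is still small (the factor is `1 - r/n`), which freezes the
#'   map early; the per-iteration cadence matches a batch-training protocol
#'   where eta is meant to shrink as iterations advance.
#' @param eta_min learning-rate floor.
#' @param tau damping scale of the neighbor weight update, see
#'   [update_weights()]. The default `NULL` resolves to the input
#'   dimensionality D at training time, so the damping compares the mean
#'   per-dimension squared distance rather than its sum: the plain
#'   `exp(-d_i)` form (`tau = 1`) underflows to zero once D is large, which
#'   silently disables the whole neighborhood update.
#' @param batch_size samples drawn per training iteration (with replacement
#'   when the pool is smaller).
#' @param calib_size labeled samples drawn from the training pool for neuron
#'   calibration by [cross_validate()] and the command-line interface.
#' @param max_iter number of training iterations.
#' @param seed integer seed; every source of randomness in a run derives from
#'   it.
#' @param som_rows,som_cols fixed grid shape in SOM mode.
#' @return An object of class `pgsom_config`.
#' @export
train_config <- function(mode = c("pgsom", "gsom", "som"),
                         sf = 0.8, rf = 1.5, m = NULL,
                         eta0 = 0.3, r = 1.0,
                         eta_decay = c("iteration", "presentation"),
                         eta_min = 1e-4, tau = NULL,
                         batch_size = 4000L, calib_size = 2000L,
                         max_iter = 50L, seed = 1L,
                         som_rows = 20L, som_cols = 20L) {
  mode <- match.arg(mode)
  eta_decay <- match.arg(eta_decay)
  if (mode != "som" && (!is.finite(sf) || sf <= 0 || sf >= 1))
    stop("spread factor must lie strictly between 0 and 1")
  if (is.null(m) && (!is.finite(rf) || rf <= 0))
    stop("ratio factor must be positive (or give an explicit age threshold m)")
  stopifnot(eta0 > 0, r >= 0, eta_min >= 0, is.null(tau) || tau > 0,
            batch_size >= 1, calib_size >= 1, max_iter >= 0,
            som_rows >= 1, som_cols >= 1)
  structure(list(mode = mode, sf = sf, rf = rf, m = m,
                 eta0 = eta0, r = r, eta_decay = eta_decay,
                 eta_min = eta_min, tau = tau,
                 batch_size = as.integer(batch_size),
                 calib_size = as.integer(calib_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 som_rows = as.integer(som_rows),
                 som_cols = as.integer(som_cols)),
            class = "pgsom_config")
}

#' Age threshold in effect for a configuration
#'
#' PGSOM mode resolves the explicit `m` if given, otherwise
#' [age_threshold()]`(rf, batch_size)`; SOM and GSOM modes never prune and
#' resolve to `Inf`.
#'
#' @param config a [train_config()] object.
#' @return A scalar age threshold (possibly `Inf`).
#' @export
resolve_age_threshold <- function(config) {
  if (config$mode != "pgsom") return(Inf)
  if (!is.null(config$m)) return(config$m)
  age_threshold(config$rf, config$batch_size)
}

# seeded network initialization: SOM gets its fixed grid, GSOM/PGSOM start
# from the canonical 2x2 square at (0,0),(0,1),(1,0),(1,1). Weights are drawn
# uniformly within the per-dimension data range.
.init_network <- function(X, config) {
  D <- ncol(X)
  mins <- apply(X, 2L, min)
  spans <- apply(X, 2L, max) - mins
  st <- .new_state(D, config$mode, config$eta0)
  st$scale <- spans
  if (config$mode == "som") {
    grid <- expand.grid(col = seq_len(config$som_cols),
                        row = seq_len(config$som_rows))
    for (k in seq_len(nrow(grid)))
      add_neuron(st, grid$row[k], grid$col[k], mins + stats::runif(D) * spans)
  } else {
    corners <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), ncol = 2L, byrow = TRUE)
    for (k in seq_len(4L))
      add_neuron(st, corners[k, 1L], corners[k, 2L], mins + stats::runif(D) * spans)
  }
  st
}

# Hot training loop. Mirrors present_sample() exactly (one shared presentation
# semantics; a regression test pins the two paths together) but keeps the
# arrays as locals so subassignments stay in place.
.train_kernel <- function(state, X, config, n_iter, verbose = FALSE) {
  W <- state$W;     state$W <- NULL
  wsq <- state$wsq; state$wsq <- NULL
  pos <- state$pos; state$pos <- NULL
  ceq <- state$ceq; state$ceq <- NULL
  age <- state$age; state$age <- NULL
  id <- state$id;   state$id <- NULL
  index <- state$index
  n <- state$n
  eta <- state$eta
  pres <- state$presentations
  next_id <- state$next_id
  scale <- state$scale
  D <- state$dim
  mode <- state$mode
  grow_on <- mode != "som"
  gt <- if (grow_on) growth_threshold(D, config$sf) else Inf
  m <- resolve_age_threshold(config)
  prune_on <- mode == "pgsom" && is.finite(m)
  decay_each <- identical(config$eta_decay, "presentation")
  r_decay <- config$r
  eta_min <- config$eta_min
  tau <- if (is.null(config$tau)) D else config$tau
  n_pool <- nrow(X)
  bs <- config$batch_size
  log_it <- integer(n_iter); log_n <- integer(n_iter)
  log_qe <- numeric(n_iter); log_eta <- numeric(n_iter)

  for (it in seq_len(n_iter)) {
    idx <- sample.int(n_pool, bs, replace = bs > n_pool)
    qe_sum <- 0
    for (j in seq_along(idx)) {
      x <- X[idx[j], ]
      ## winner
      res <- .winner_from(W, wsq, n, x)
      ws <- res$slot
      d <- res$d
      qe_sum <- qe_sum + d
      ## accumulate error with the current eta, then decay (if per-sample)
      ceq[ws] <- ceq[ws] + eta * d
      if (decay_each) eta <- decay_eta(eta, r_decay, n, eta_min)
      ## weight updates: winner toward input, occupied neighbors toward the
      ## winner's pre-update weight, damped by exp(-d_i / tau)
      w_old <- W[, ws]
      w_new <- w_old + eta * (x - w_old)
      W[, ws] <- w_new
      wsq[ws] <- sum(w_new * w_new)
      wr <- pos[1L, ws]
      wc <- pos[2L, ws]
      nrs <- c(wr - 1L, wr + 1L, wr, wr)
      ncs <- c(wc, wc, wc - 1L, wc + 1L)
      nslot <- c(get0(.pos_key(nrs[1L], ncs[1L]), envir = index, ifnotfound = 0L),
                 get0(.pos_key(nrs[2L], ncs[2L]), envir = index, ifnotfound = 0L),
                 get0(.pos_key(nrs[3L], ncs[3L]), envir = index, ifnotfound = 0L),
                 get0(.pos_key(nrs[4L], ncs[4L]), envir = index, ifnotfound = 0L))
      for (k in seq_len(4L)) {
        ns <- nslot[k]
        if (ns > 0L) {
          wi <- W[, ns]
          di <- sum((x - wi)^2)
          wi <- wi + eta * (w_old - wi) * exp(-di / tau)
          W[, ns] <- wi
          wsq[ns] <- sum(wi * wi)
        }
      }
      ## growth / redistribution
      new_slots <- integer(0)
      if (grow_on && ceq[ws] >= gt) {
        free_k <- which(nslot == 0L)
        if (length(free_k) > 0L) {
          # snapshot semantics: all interpolated weights from pre-growth state
          w_grow <- lapply(free_k, function(k)
            .interp_from(W, pos, index, ws, nrs[k], ncs[k], scale))
          for (g in seq_along(free_k)) {
            if (n == ncol(W)) {  # double capacity
              cap <- ncol(W)
              W <- cbind(W, matrix(0, nrow = D, ncol = cap))
              wsq <- c(wsq, rep(Inf, cap))
              pos <- cbind(pos, matrix(NA_integer_, nrow = 2L, ncol = cap))
              ceq <- c(ceq, numeric(cap))
              age <- c(age, integer(cap))
              id <- c(id, integer(cap))
            }
            n <- n + 1L
            k <- free_k[g]
            W[, n] <- w_grow[[g]]
            wsq[n] <- sum(w_grow[[g]]^2)
            pos[, n] <- c(nrs[k], ncs[k])
            ceq[n] <- 0
            age[n] <- 0L
            id[n] <- next_id
            next_id <- next_id + 1L
            assign(.pos_key(nrs[k], ncs[k]), n, envir = index)
            new_slots <- c(new_slots, n)
          }
          ceq[ws] <- 0
        } else {
          nbs <- nslot[nslot > 0L]
          ceq_old <- ceq[ws]
          ceq[ws] <- ceq_old / 2
          ceq[nbs] <- ceq[nbs] + ceq_old / (2 * length(nbs))
        }
      }
      ## ages: winner and newborns to 0, everyone else +1
      live <- seq_len(n)
      age[live] <- age[live] + 1L
      age[ws] <- 0L
      if (length(new_slots) > 0L) age[new_slots] <- 0L
      ## pruning
      if (prune_on) {
        over <- live[age[live] > m]
        if (length(over) > 0L) {
          if (length(over) == n) {
            warning("pruning would empty the network; retaining the youngest neuron")
            over <- setdiff(live, which.min(age[live]))
          }
          keep <- setdiff(live, over)
          nk <- length(keep)
          if (nk > 0L) {
            W[, seq_len(nk)] <- W[, keep, drop = FALSE]
            wsq[seq_len(nk)] <- wsq[keep]
            pos[, seq_len(nk)] <- pos[, keep, drop = FALSE]
            ceq[seq_len(nk)] <- ceq[keep]
            age[seq_len(nk)] <- age[keep]
            id[seq_len(nk)] <- id[keep]
          }
          if (nk < n) {
            gone <- (nk + 1L):n
            W[, gone] <- 0
            wsq[gone] <- Inf
            pos[, gone] <- NA_integer_
            ceq[gone] <- 0
            age[gone] <- 0L
            id[gone] <- 0L
          }
          n <- nk
          index <- new.env(parent = emptyenv())
          for (s in seq_len(n))
            assign(.pos_key(pos[1L, s], pos[2L, s]), s, envir = index)
        }
      }
      pres <- pres + 1L
    }
    if (!decay_each) eta <- decay_eta(eta, r_decay, n, eta_min)
    log_it[it] <- it
    log_n[it] <- n
    log_qe[it] <- qe_sum / length(idx)
    log_eta[it] <- eta
    if (verbose)
      message(sprintf("iteration %d: %d neurons, mean QE %.4f, eta %.3g",
                      it, n, qe_sum / length(idx), eta))
  }

  state$W <- W
  state$wsq <- wsq
  state$pos <- pos
  state$ceq <- ceq
  state$age <- age
  state$id <- id
  state$index <- index
  state$n <- n
  state$eta <- eta
  state$presentations <- pres
  state$next_id <- next_id
  state$log <- rbind(state$log,
                     data.frame(iteration = log_it, neuron_count = log_n,
                                mean_qe = log_qe, eta = log_eta))
  invisible(state)
}

#' Train a SOM, GSOM or PGSOM network
#'
#' Initializes a network from the data (a seeded `som_rows` x `som_cols` grid
#' in SOM mode; the canonical four-neuron 2 x 2 square otherwise, with weights
#' uniform within the per-dimension data range) and runs `max_iter` training
#' iterations, each presenting a seeded random batch of `batch_size` samples
#' (drawn with replacement when the pool is smaller than the batch). The
#' learning rate decays per presentation, continuously across iterations.
#'
#' @param X numeric sample matrix (rows = samples).
#' @param config a [train_config()] object.
#' @param verbose print one progress line per iteration.
#' @return The trained `pgsom_network`; `$log` holds one record per iteration
#'   (iteration, neuron_count, mean quantization error, eta) and `$config`
#'   echoes the configuration.
#' @examples
#' d <- make_feature_dataset(synth_config(n_samples = 300, dim = 8, seed = 1))
#' cfg <- train_config("pgsom", sf = 0.5, batch_size = 100, max_iter = 2, seed = 1)
#' net <- train_network(d$x, cfg)
#' neuron_count(net)
#' @export
train_network <- function(X, config, verbose = FALSE) {
  stopifnot(inherits(config, "pgsom_config"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stop("training matrix is empty")
  if (!all(is.finite(X))) stop("training data contain non-finite values")
  set.seed(config$seed)
  st <- .init_network(X, config)
  st$config <- config
  st$log <- data.frame(iteration = integer(), neuron_count = integer(),
                       mean_qe = numeric(), eta = numeric())
  if (config$max_iter > 0L)
    .train_kernel(st, X, config, config$max_iter, verbose)
  st
}
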