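# SOM / GSOM / PGSOM training engine.
#
# One presentation of a sample x runs, in order: winner search (squared
# Euclidean distance), error accumulation on the winner, learning-rate decay,
# weight update of the winner and its occupied lattice neighbors, growth or
# error redistribution (GSOM/PGSOM), age update, and pruning (PGSOM).
#
# Exported operations act on the network state one call at a time;
# train_network() runs the identical sequence through an inlined kernel that
# holds the hot arrays as function locals (R would otherwise copy the weight
# matrix on every in-environment subassignment).

# ---- pure helpers shared by the exported operations and the kernel --------

# winner over live slots: vectorized norm expansion ||x||^2 - 2 x.w + ||w||^2,
# then exact recomputation among near-minimal candidates so reported distances
# are exact and ties break to the lowest slot (= lowest id).
.winner_from <- function(W, wsq, n, x) {
  xx <- sum(x * x)
  d2 <- wsq - 2 * as.vector(crossprod(W, x)) + xx
  m0 <- min(d2[seq_len(n)])
  cand <- which(d2 <= m0 + 1e-7 * (1 + abs(m0) + xx))
  cand <- cand[cand <= n]
  de <- colSums((W[, cand, drop = FALSE] - x)^2)
  j <- which.min(de)             # first minimum -> lowest slot -> lowest id
  list(slot = cand[[j]], d = de[[j]])
}

# interpolated weight for a new neuron at (nr, nc) adjacent to winner slot ws:
# (a) opposite neighbor occupied -> linear extrapolation 2 w_winner - w_opp;
# (b) any other occupied neighbor -> midpoint with the lowest-id one;
# (c) isolated winner -> w_winner plus a small seeded perturbation, each
#     component uniform in +-0.01 of the per-dimension data range.
.interp_from <- function(W, pos, index, ws, nr, nc, scale) {
  wr <- pos[1L, ws]
  wc <- pos[2L, ws]
  os <- get0(.pos_key(2L * wr - nr, 2L * wc - nc), envir = index, ifnotfound = 0L)
  if (os > 0L) return(2 * W[, ws] - W[, os])
  nrs <- c(wr - 1L, wr + 1L, wr, wr)
  ncs <- c(wc, wc, wc - 1L, wc + 1L)
  nbr <- vapply(seq_len(4L), function(k)
    get0(.pos_key(nrs[k], ncs[k]), envir = index, ifnotfound = 0L), integer(1))
  nbr <- nbr[nbr > 0L]
  if (length(nbr) > 0L)
    return((W[, ws] + W[, min(nbr)]) / 2)
  W[, ws] + stats::runif(nrow(W), -0.01, 0.01) * scale
}

# ---- exported operations ---------------------------------------------------

#' Growth threshold from spread factor
#'
#' `GT = -D * ln(SF)`. A winner whose cumulative quantization error reaches GT
#' triggers growth (boundary winner) or error redistribution (interior
#' winner). Larger spread factors lower the threshold and ease growth.
#'
#' @param dim input dimensionality D (>= 1).
#' @param sf spread factor in (0, 1).
#' @return The positive scalar growth threshold.
#' @export
growth_threshold <- function(dim, sf) {
  if (!is.finite(sf) || sf <= 0 || sf >= 1)
    stop("spread factor must lie strictly between 0 and 1")
  stopifnot(dim >= 1)
  -dim * log(sf)
}

#' Age threshold from ratio factor and batch size
#'
#' The age threshold M is the ratio factor times the per-iteration batch size,
#' rounded half-up: with a batch of 4000 and RF = 1.25, M = 5000. Neurons
#' whose age exceeds M are pruned.
#'
#' @param rf ratio factor (> 0).
#' @param batch_size samples presented per training iteration (>= 1).
#' @return Integer age threshold.
#' @export
age_threshold <- function(rf, batch_size) {
  stopifnot(is.finite(rf), rf > 0, batch_size >= 1)
  as.integer(floor(rf * batch_size + 0.5))
}

#' Decay the learning rate
#'
#' `eta <- max(eta_min, (1 - R / n_neurons) * eta)`, applied once per sample
#' presentation. The factor shrinks eta whenever `0 < R < n_neurons`; if
#' `R >= n_neurons` the configuration is degenerate, a warning is emitted and
#' the floor is returned.
#'
#' @param eta current learning rate (> 0).
#' @param r decay constant R.
#' @param n_neurons current number of live neurons.
#' @param eta_min lower floor for the learning rate.
#' @return The decayed learning rate.
#' @export
decay_eta <- function(eta, r, n_neurons, eta_min = 1e-4) {
  stopifnot(eta > 0, n_neurons >= 1)
  fac <- 1 - r / n_neurons
  if (fac < 0) {
    warning("decay constant R >= neuron count; learning rate clamped to floor")
    return(eta_min)
  }
  max(eta_min, fac * eta)
}

#' Find the best-matching neuron for an input
#'
#' Returns the live neuron minimizing the squared Euclidean distance to `x`,
#' ties broken by lowest neuron id.
#'
#' @param state a `pgsom_network` with at least one neuron.
#' @param x input vector of length `state$dim`.
#' @return A list with `id` (winner neuron id) and `d` (squared distance).
#' @export
find_winner <- function(state, x) {
  if (length(x) != state$dim)
    stop("input has length ", length(x), " but the network dimension is ", state$dim)
  stopifnot(state$n >= 1L)
  res <- .winner_from(state$W, state$wsq, state$n, as.numeric(x))
  list(id = state$id[res$slot], d = res$d)
}

#' Accumulate quantization error on the winner
#'
#' Adds `eta * d` to the winner's cumulative quantization error (CEQ); no
#' other neuron is touched.
#'
#' @param state a `pgsom_network`.
#' @param winner_id id of the winner neuron.
#' @param d squared distance of the presented sample to the winner.
#' @param eta learning rate used for the presentation.
#' @return The state, invisibly (updated in place).
#' @export
accumulate_error <- function(state, winner_id, d, eta = state$eta) {
  ws <- .slot_of(state, winner_id)
  state$ceq[ws] <- state$ceq[ws] + eta * d
  invisible(state)
}

#' Update the winner and its lattice neighborhood
#'
#' The winner moves toward the input with plain rate eta:
#' `w <- w + eta * (x - w)`. Each occupied 4-neighbor i then moves toward the
#' winner's pre-update weight, damped by its own distance to the input:
#' `w_i <- w_i + eta * (w_winner_old - w_i) * exp(-d_i / tau)` with
#' `d_i = ||x - w_i||^2`. `tau` rescales the damping because exp(-d) underflows
#' for high-dimensional standardized data; `tau = 1` is the plain form.
#'
#' @inheritParams accumulate_error
#' @param x the presented input vector.
#' @param tau damping scale for the neighbor update.
#' @return The state, invisibly (updated in place).
#' @export
update_weights <- function(state, winner_id, x, eta = state$eta, tau = 1) {
  ws <- .slot_of(state, winner_id)
  x <- as.numeric(x)
  w_old <- state$W[, ws]
  w_new <- w_old + eta * (x - w_old)
  state$W[, ws] <- w_new
  state$wsq[ws] <- sum(w_new * w_new)
  nb <- neighbor_positions(state$pos[, ws])
  for (k in seq_len(4L)) {
    ns <- .slot_at(state, nb[k, 1L], nb[k, 2L])
    if (ns > 0L) {
      wi <- state$W[, ns]
      di <- sum((x - wi)^2)
      wi <- wi + eta * (w_old - wi) * exp(-di / tau)
      state$W[, ns] <- wi
      state$wsq[ns] <- sum(wi * wi)
    }
  }
  invisible(state)
}

#' Interpolate the weight of a prospective new neuron
#'
#' Deterministic case ladder for initializing a neuron grown at a free
#' neighbor position of the winner: (a) if the position opposite the new slot
#' across the winner is occupied, linear extrapolation `2 w_winner - w_opp`;
#' (b) otherwise the midpoint with the winner's lowest-id occupied neighbor;
#' (c) for an isolated winner, the winner's weight plus a small seeded
#' perturbation (each component uniform within 0.01 of the per-dimension data
#' range).
#'
#' @param state a `pgsom_network`.
#' @param winner_id id of the winner neuron.
#' @param new_pos integer `c(row, col)`, a free neighbor of the winner.
#' @return Weight vector of length `state$dim`.
#' @export
interpolate_weight <- function(state, winner_id, new_pos) {
  ws <- .slot_of(state, winner_id)
  if (.slot_at(state, new_pos[[1]], new_pos[[2]]) != 0L)
    stop("interpolate_weight(): target position is occupied")
  .interp_from(state$W, state$pos, state$index, ws,
               as.integer(new_pos[[1]]), as.integer(new_pos[[2]]), state$scale)
}

#' Grow new neurons or redistribute accumulated error
#'
#' If the winner's CEQ is below `gt` nothing happens. Otherwise a boundary
#' winner spawns one neuron at every free neighbor slot (interpolated weight,
#' ceq 0, age 0; all weights computed from the pre-growth state) and its own
#' CEQ resets to 0; an interior winner keeps half its CEQ and spreads the
#' other half equally over its occupied neighbors, conserving the total.
#'
#' @param state a `pgsom_network` in GSOM or PGSOM mode.
#' @param winner_id id of the winner neuron.
#' @param gt growth threshold (> 0), see [growth_threshold()].
#' @return Integer vector of newly created neuron ids (empty if none).
#' @export
grow_or_redistribute <- function(state, winner_id, gt) {
  stopifnot(gt > 0)
  ws <- .slot_of(state, winner_id)
  if (state$ceq[ws] < gt) return(invisible(integer(0)))
  free <- free_neighbor_positions(state, state$pos[, ws])
  if (nrow(free) > 0L) {
    w_new <- lapply(seq_len(nrow(free)), function(k)
      .interp_from(state$W, state$pos, state$index, ws,
                   free[k, 1L], free[k, 2L], state$scale))
    ids <- integer(nrow(free))
    for (k in seq_len(nrow(free)))
      ids[k] <- add_neuron(state, free[k, 1L], free[k, 2L], w_new[[k]])
    state$ceq[.slot_of(state, winner_id)] <- 0
    return(invisible(ids))
  }
  nb <- neighbor_positions(state$pos[, ws])
  nbs <- vapply(seq_len(4L), function(k) .slot_at(state, nb[k, 1L], nb[k, 2L]),
                integer(1))
  nbs <- nbs[nbs > 0L]
  ceq_old <- state$ceq[ws]
  state$ceq[ws] <- ceq_old / 2
  state$ceq[nbs] <- state$ceq[nbs] + ceq_old / (2 * length(nbs))
  invisible(integer(0))
}

#' Update neuron ages after a presentation
#'
#' The winner and any newly grown neurons get age 0; every other neuron ages
#' by one presentation.
#'
#' @param state a `pgsom_network`.
#' @param winner_id id of the winner neuron.
#' @param new_ids ids of neurons grown in this presentation.
#' @return The state, invisibly (updated in place).
#' @export
update_ages <- function(state, winner_id, new_ids = integer()) {
  s <- seq_len(state$n)
  state$age[s] <- state$age[s] + 1L
  state$age[.slot_of(state, winner_id)] <- 0L
  for (id in new_ids) state$age[.slot_of(state, id)] <- 0L
  invisible(state)
}

#' Prune neurons older than the age threshold
#'
#' Removes every neuron whose age strictly exceeds `m`; their lattice slots
#' become free (holes are allowed and the map may split into disconnected
#' clusters). If pruning would empty the network, the single youngest neuron
#' (lowest id on ties) is retained and a warning is emitted.
#'
#' @param state a `pgsom_network`.
#' @param m age threshold; `Inf` makes pruning a no-op.
#' @return Integer vector of removed neuron ids.
#' @export
prune <- function(state, m) {
  s <- seq_len(state$n)
  over <- s[state$age[s] > m]
  if (length(over) == 0L) return(invisible(integer(0)))
  if (length(over) == state$n) {
    warning("pruning would empty the network; retaining the youngest neuron")
    over <- setdiff(s, which.min(state$age[s]))
    if (length(over) == 0L) return(invisible(integer(0)))
  }
  removed <- state$id[over]
  .remove_slots(state, over)
  invisible(removed)
}

#' Present a single sample to the network
#'
#' Runs one full presentation: winner search, error accumulation (with the
#' current learning rate), learning-rate decay (when the configured cadence
#' is per-presentation; under the default per-iteration cadence the training
#' loop decays eta at the end of each batch instead), weight update, growth
#' or redistribution (GSOM/PGSOM), age update, and pruning (PGSOM). The
#' presentation counter is incremented.
#'
#' @param state a `pgsom_network`.
#' @param x input vector of length `state$dim`.
#' @param config a [train_config()] object; its `mode` must match the state.
#' @return The state, invisibly (updated in place).
#' @export
present_sample <- function(state, x, config) {
  stopifnot(state$mode == config$mode)
  fw <- find_winner(state, x)
  accumulate_error(state, fw$id, fw$d, state$eta)
  if (identical(config$eta_decay, "presentation"))
    state$eta <- decay_eta(state$eta, config$r, state$n, config$eta_min)
  tau <- if (is.null(config$tau)) state$dim else config$tau
  update_weights(state, fw$id, x, state$eta, tau)
  new_ids <- integer(0)
  if (state$mode != "som") {
    gt <- growth_threshold(state$dim, config$sf)
    new_ids <- grow_or_redistribute(state, fw$id, gt)
  }
  update_ages(state, fw$id, new_ids)
  if (state$mode == "pgsom") {
    m <- resolve_age_threshold(config)
    if (is.finite(m)) prune(state, m)
  }
  state$presentations <- state$presentations + 1L
  invisible(state)
}
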