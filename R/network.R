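# Network state container. The map is stored column-wise in preallocated
# arrays (weights D x capacity, positions 2 x capacity, plus ceq/age/id
# vectors); columns 1..n hold live neurons in id-ascending order, so the
# lowest slot is always the lowest id, which keeps argmin tie-breaking
# deterministic. Free capacity columns carry weight 0 and cached squared
# norm Inf so the vectorized winner search can run over the full arrays.
# The state is an environment: training mutates it in place.

.new_state <- function(dim, mode, eta, capacity = 64L) {
  st <- new.env(parent = emptyenv())
  st$dim <- as.integer(dim)
  st$mode <- mode
  st$eta <- eta
  st$presentations <- 0L
  st$n <- 0L
  st$W <- matrix(0, nrow = dim, ncol = capacity)
  st$wsq <- rep(Inf, capacity)
  st$pos <- matrix(NA_integer_, nrow = 2L, ncol = capacity)
  st$ceq <- numeric(capacity)
  st$age <- integer(capacity)
  st$id <- integer(capacity)
  st$next_id <- 1L
  st$index <- new.env(parent = emptyenv())
  st$scale <- rep(1, dim)   # per-dimension data range, set by train_network()
  st$config <- NULL
  st$log <- NULL
  class(st) <- "pgsom_network"
  st
}

#' Create an empty network
#'
#' Low-level constructor used together with [add_neuron()] to build networks
#' by hand (mainly for experimentation and tests). [train_network()] is the
#' high-level entry point and initializes the map itself.
#'
#' @param dim input dimensionality D.
#' @param mode one of `"som"`, `"gsom"`, `"pgsom"`.
#' @param eta initial learning rate.
#' @return An empty `pgsom_network`.
#' @export
new_network <- function(dim, mode = c("gsom", "pgsom", "som"), eta = 0.3) {
  mode <- match.arg(mode)
  stopifnot(dim >= 1, eta > 0)
  .new_state(as.integer(dim), mode, eta)
}

.ensure_capacity <- function(state, extra) {
  need <- state$n + extra
  cap <- ncol(state$W)
  if (need <= cap) return(invisible(state))
  new_cap <- max(need, 2L * cap)
  add <- new_cap - cap
  state$W <- cbind(state$W, matrix(0, nrow = state$dim, ncol = add))
  state$wsq <- c(state$wsq, rep(Inf, add))
  state$pos <- cbind(state$pos, matrix(NA_integer_, nrow = 2L, ncol = add))
  state$ceq <- c(state$ceq, numeric(add))
  state$age <- c(state$age, integer(add))
  state$id <- c(state$id, integer(add))
  invisible(state)
}

#' Insert a neuron at a free lattice position
#'
#' @param state a `pgsom_network`.
#' @param row,col lattice coordinates (must be free).
#' @param w weight vector of length `state$dim`.
#' @param ceq initial cumulative quantization error.
#' @param age initial age.
#' @return The id of the new neuron, invisibly the state is updated in place.
#' @export
add_neuron <- function(state, row, col, w, ceq = 0, age = 0L) {
  if (length(w) != state$dim)
    stop("add_neuron(): weight length ", length(w), " != dim ", state$dim)
  if (.slot_at(state, row, col) != 0L)
    stop("add_neuron(): position (", row, ",", col, ") is already occupied")
  .ensure_capacity(state, 1L)
  slot <- state$n + 1L
  state$W[, slot] <- w
  state$wsq[slot] <- sum(w * w)
  state$pos[, slot] <- c(as.integer(row), as.integer(col))
  state$ceq[slot] <- ceq
  state$age[slot] <- as.integer(age)
  id <- state$next_id
  state$id[slot] <- id
  state$next_id <- id + 1L
  state$n <- slot
  assign(.pos_key(row, col), slot, envir = state$index)
  id
}

.slot_of <- function(state, id) {
  slot <- match(id, state$id[seq_len(state$n)])
  if (is.na(slot)) stop("no live neuron with id ", id)
  slot
}

.rebuild_index <- function(state) {
  idx <- new.env(parent = emptyenv())
  for (s in seq_len(state$n))
    assign(.pos_key(state$pos[1L, s], state$pos[2L, s]), s, envir = idx)
  state$index <- idx
  invisible(state)
}

# remove the given slots, compacting the arrays (id order is preserved)
.remove_slots <- function(state, slots) {
  if (length(slots) == 0L) return(invisible(state))
  n <- state$n
  keep <- setdiff(seq_len(n), slots)
  k <- length(keep)
  if (k > 0L) {
    state$W[, seq_len(k)] <- state$W[, keep, drop = FALSE]
    state$wsq[seq_len(k)] <- state$wsq[keep]
    state$pos[, seq_len(k)] <- state$pos[, keep, drop = FALSE]
    state$ceq[seq_len(k)] <- state$ceq[keep]
    state$age[seq_len(k)] <- state$age[keep]
    state$id[seq_len(k)] <- state$id[keep]
  }
  if (k < n) {
    gone <- (k + 1L):n
    state$W[, gone] <- 0
    state$wsq[gone] <- Inf
    state$pos[, gone] <- NA_integer_
    state$ceq[gone] <- 0
    state$age[gone] <- 0L
    state$id[gone] <- 0L
  }
  state$n <- k
  .rebuild_index(state)
}

#' Number of live neurons
#' @param state a `pgsom_network`.
#' @return Integer count.
#' @export
neuron_count <- function(state) state$n

#' Live neurons as a data frame
#'
#' @param state a `pgsom_network`.
#' @return A data frame with columns `id`, `row`, `col`, `age`, `ceq`, one row
#'   per live neuron in id order. Weights are returned separately by
#'   [neuron_weights()] because D is typically large.
#' @export
neurons <- function(state) {
  s <- seq_len(state$n)
  data.frame(id = state$id[s],
             row = state$pos[1L, s],
             col = state$pos[2L, s],
             age = state$age[s],
             ceq = state$ceq[s])
}

#' Weight matrix of the live neurons
#'
#' @param state a `pgsom_network`.
#' @return An n x D numeric matrix, row names the neuron ids.
#' @export
neuron_weights <- function(state) {
  s <- seq_len(state$n)
  w <- t(state$W[, s, drop = FALSE])
  rownames(w) <- state$id[s]
  w
}

#' @export
print.pgsom_network <- function(x, ...) {
  cat("<pgsom_network> mode=", x$mode, " dim=", x$dim,
      " neurons=", x$n, " eta=", signif(x$eta, 4),
      " presentations=", x$presentations, "\n", sep = "")
  invisible(x)
}
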