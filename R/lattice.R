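# Lattice geometry: the map lives on an unbounded 2-D integer grid with
# 4-connectivity (von Neumann). Coordinates may go negative as the network
# grows in any direction; at most one live neuron occupies a grid position.

.pos_key <- function(row, col) paste0(row, ",", col)

# slot (column index into the state arrays) at a grid position, 0L if free
.slot_at <- function(state, row, col) {
  get0(.pos_key(row, col), envir = state$index, ifnotfound = 0L)
}

#' Four-connected neighborhood of a lattice position
#'
#' Returns the four axis-adjacent grid positions of `pos` in the fixed order
#' up, down, left, right. The order is part of the contract: growth and
#' interpolation iterate free slots in this order, which makes tie-breaking
#' deterministic.
#'
#' @param pos integer vector `c(row, col)`.
#' @return A 4 x 2 integer matrix with rows `up`, `down`, `left`, `right` and
#'   columns `row`, `col`.
#' @examples
#' neighbor_positions(c(0L, 0L))
#' @export
neighbor_positions <- function(pos) {
  r <- as.integer(pos[[1]])
  c <- as.integer(pos[[2]])
  matrix(c(r - 1L, c,
           r + 1L, c,
           r,      c - 1L,
           r,      c + 1L),
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("up", "down", "left", "right"), c("row", "col")))
}

#' Is an occupied lattice position on the network boundary?
#'
#' A neuron is a boundary neuron when at least one of its four neighbor slots
#' is unoccupied. Only boundary winners can trigger growth; interior winners
#' redistribute their accumulated error instead.
#'
#' @param state a `pgsom_network` object.
#' @param pos integer vector `c(row, col)`; must be occupied.
#' @return `TRUE` iff at least one 4-neighbor slot is free.
#' @export
is_boundary <- function(state, pos) {
  if (.slot_at(state, pos[[1]], pos[[2]]) == 0L)
    stop("is_boundary(): position (", pos[[1]], ",", pos[[2]], ") is not occupied")
  nrow(free_neighbor_positions(state, pos)) > 0L
}

#' Unoccupied neighbor slots of an occupied position
#'
#' @inheritParams is_boundary
#' @return The subset of rows of [neighbor_positions()] that are unoccupied,
#'   preserving the up/down/left/right order (possibly 0 rows).
#' @export
free_neighbor_positions <- function(state, pos) {
  nb <- neighbor_positions(pos)
  occ <- vapply(seq_len(4L), function(k) .slot_at(state, nb[k, 1L], nb[k, 2L]),
                integer(1))
  nb[occ == 0L, , drop = FALSE]
}
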