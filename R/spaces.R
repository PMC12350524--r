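#' Enumerate integer tuples on a mixed-radix grid
#'
#' Generates every tuple \code{(x_1, ..., x_k)} with \code{0 <= x_j < radices[j]},
#' in lexicographic order with the last component varying fastest. This is the
#' canonical state/action enumeration order used throughout the package, so a
#' tuple's row number can be recovered arithmetically by [tuple_index()] without
#' a hash table.
#'
#' @param radices positive integer vector; \code{radices[j]} is the number of
#'   admissible values of component \code{j}.
#' @return integer matrix with \code{prod(radices)} rows and
#'   \code{length(radices)} columns.
#' @seealso [tuple_index()]
#' @export
#' @examples
#' enumerate_tuples(c(2, 3))
enumerate_tuples <- function(radices) {
  radices <- as.integer(radices)
  stopifnot(length(radices) >= 1, all(radices >= 1))
  n <- prod(radices)
  if (n > .Machine$integer.max) {
    stop("tuple grid has more than 2^31 - 1 cells; refusing to enumerate")
  }
  k <- length(radices)
  out <- matrix(0L, nrow = n, ncol = k)
  rep_each <- n
  for (j in seq_len(k)) {
    rep_each <- rep_each %/% radices[j]
    out[, j] <- rep(rep(0:(radices[j] - 1L), each = rep_each),
                    length.out = n)
  }
  out
}

#' Index of tuples in the canonical enumeration
#'
#' Inverse of [enumerate_tuples()]: maps tuples to their 1-based row number in
#' the canonical (last component fastest) enumeration.
#'
#' @param tuples integer matrix (or vector for a single tuple), one tuple per row.
#' @param radices the radix vector the enumeration was built with.
#' @return integer vector of 1-based indices.
#' @export
tuple_index <- function(tuples, radices) {
  if (is.null(dim(tuples))) tuples <- matrix(tuples, nrow = 1)
  radices <- as.numeric(radices)
  k <- length(radices)
  stopifnot(ncol(tuples) == k)
  if (any(tuples < 0) || any(t(tuples) >= radices)) {
    stop("tuple component out of range for the declared radices")
  }
  mult <- rev(cumprod(rev(c(radices[-1], 1))))
  as.integer(as.numeric(tuples %*% mult) + 1)
}

#' State space of an enumerated finite MDP
#'
#' A thin container bundling the ordered state list with its index map.
#'
#' @param states integer matrix, one state tuple per row, unique rows.
#' @param radices optional mixed-radix vector; when supplied (states enumerated
#'   by [enumerate_tuples()]) the index map is arithmetic, otherwise a
#'   dictionary lookup is used.
#' @return an object of class \code{"state_space"} with elements
#'   \code{states}, \code{n_states}, \code{state_arity} and \code{index_of}
#'   (a function mapping state tuples to ordinals in \code{1..n_states}).
#' @export
state_space <- function(states, radices = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (anyDuplicated(states)) stop("states must be unique")
  if (any(states < 0)) stop("state components must be non-negative integers")
  index_of <- if (!is.null(radices)) {
    force(radices)
    function(s) tuple_index(s, radices)
  } else {
    key <- apply(states, 1, paste, collapse = ",")
    env <- new.env(hash = TRUE, size = nrow(states))
    for (i in seq_along(key)) assign(key[i], i, envir = env)
    function(s) {
      if (is.null(dim(s))) s <- matrix(s, nrow = 1)
      k <- apply(s, 1, paste, collapse = ",")
      idx <- vapply(k, function(kk) {
        v <- mget(kk, envir = env, ifnotfound = list(NA_integer_))[[1]]
        as.integer(v)
      }, integer(1), USE.NAMES = FALSE)
      if (anyNA(idx)) stop("unknown state: not a member of the state space")
      idx
    }
  }
  structure(
    list(states = states, n_states = nrow(states),
         state_arity = ncol(states), radices = radices, index_of = index_of),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State space: %s states, arity %d\n",
              format(x$n_states, big.mark = ","), x$state_arity))
  invisible(x)
}

#' Pad a state list into a (devices x batches x batch size) layout
#'
#' Computes the padded layout used by the batched sweep: states are grouped
#' into equally sized batches, with the same number of batches per device, so
#' that a full update can be expressed as a rectangular map over
#' \code{(device, batch, slot)}. Surplus slots are padding and never influence
#' the values of real states.
#'
#' @param n_states number of (real) states, or a \code{state_space}.
#' @param batch_size states updated per batch; \code{Inf} means one batch.
#' @param n_devices number of identical devices in the layout contract.
#' @return a list with \code{n_states}, \code{batch_size}, \code{n_devices},
#'   \code{n_batches} (per device), \code{total_slots}, \code{n_padding}, and
#'   \code{slot_state}: an integer vector of length \code{total_slots} holding
#'   the 1-based state index of each slot (\code{NA} for padding). Unpadding is
#'   the identity: real slots appear in the original state order.
#' @export
#' @examples
#' pad_states(121, batch_size = 50)  # 3 batches, 150 slots, 29 padding
pad_states <- function(n_states, batch_size = Inf, n_devices = 1L) {
  if (inherits(n_states, "state_space")) n_states <- n_states$n_states
  stopifnot(n_states >= 1, n_devices >= 1, batch_size >= 1)
  if (!is.finite(batch_size)) batch_size <- as.integer(ceiling(n_states / n_devices))
  batch_size <- as.integer(batch_size)
  n_devices <- as.integer(n_devices)
  n_batches <- as.integer(ceiling(n_states / (batch_size * n_devices)))
  total <- n_devices * n_batches * batch_size
  slot_state <- rep(NA_integer_, total)
  slot_state[seq_len(n_states)] <- seq_len(n_states)
  list(n_states = as.integer(n_states), batch_size = batch_size,
       n_devices = n_devices, n_batches = n_batches,
       total_slots = as.integer(total),
       n_padding = as.integer(total - n_states),
       slot_state = slot_state)
}
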