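#' Truncated integer state space
#'
#' A rectangular box of molecule-number states `[0, upper_i]` per species,
#' optionally coarsened by an integer scale factor `S`: the enumerated lattice
#' then consists of the multiples of `S` within the box, i.e.
#' `0, S, 2S, ..., floor(upper_i/S)*S`. `S = 1` is the ordinary lattice.
#' Transitions that would leave the box are assigned zero rate by the
#' generator builders (mass-conserving reflecting truncation), so truncation
#' error is controlled by enlarging the bounds.
#'
#' @param upper Named integer vector of per-species upper bounds (lower
#'   bounds are all 0). Names define the species order.
#' @param scale Integer scale factor `S >= 1`; `1` means no coarsening.
#' @return An object of class `cme_space` with fields `species`, `upper`,
#'   `scale` and `dims` (number of lattice points per species).
#' @examples
#' sp <- state_space(c(u = 60, v = 60))
#' n_states(sp)
#' @export
state_space <- function(upper, scale = 1L) {
  if (is.null(names(upper)) || any(!nzchar(names(upper)))) {
    stop("`upper` must be a named vector (names are the species)", call. = FALSE)
  }
  if (any(upper < 0) || any(upper != floor(upper))) {
    stop("upper bounds must be nonnegative integers", call. = FALSE)
  }
  scale <- as.integer(scale)
  if (length(scale) != 1L || is.na(scale) || scale < 1L) {
    stop("scale factor S must be an integer >= 1", call. = FALSE)
  }
  species <- names(upper)
  upper <- stats::setNames(as.integer(upper), species)
  structure(
    list(
      species = species,
      upper = upper,
      scale = scale,
      dims = floor(upper / scale) + 1L
    ),
    class = "cme_space"
  )
}

#' @export
print.cme_space <- function(x, ...) {
  cat("<cme_space> ", length(x$species), " species, ",
      format(n_states(x), big.mark = ","), " lattice points",
      if (x$scale > 1L) paste0(" (scale S = ", x$scale, ")"), "\n", sep = "")
  cat("  ", paste0(x$species, " in [0, ", x$upper, "]", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of lattice points in a state space
#' @param space A [state_space()].
#' @export
n_states <- function(space) prod(space$dims)

#' Enumerate all lattice states
#'
#' States are listed in column-major order: the first species varies fastest.
#' Values are actual molecule numbers (multiples of the scale factor).
#'
#' @param space A [state_space()].
#' @return Integer matrix, one row per lattice point, one column per species.
#' @export
enumerate_states <- function(space) {
  grids <- lapply(seq_along(space$species), function(i) {
    as.integer(seq(0L, by = space$scale, length.out = space$dims[i]))
  })
  idx <- arrayInd(seq_len(n_states(space)), space$dims)
  out <- vapply(seq_along(grids), function(i) grids[[i]][idx[, i]], integer(nrow(idx)))
  out <- matrix(out, ncol = length(grids))
  colnames(out) <- space$species
  out
}

#' Map states to linear indices and back
#'
#' The mapping is a bijection between lattice points and `1:n_states(space)`
#' (column-major, first species fastest).
#'
#' @param space A [state_space()].
#' @param states Integer matrix (rows = states) or a single state vector.
#'   Entries must be in-box multiples of the scale factor.
#' @return Integer vector of 1-based linear indices.
#' @export
state_to_index <- function(space, states) {
  states <- as_state_matrix(states, space)
  S <- space$scale
  if (any(states < 0L) || any(t(t(states) > space$upper))) {
    stop("state outside the truncation box", call. = FALSE)
  }
  if (any(states %% S != 0L)) {
    stop("state is not on the scale-S coarse lattice", call. = FALSE)
  }
  sub <- states %/% S  # 0-based per-species grid positions
  mult <- cumprod(c(1L, space$dims[-length(space$dims)]))
  as.integer(sub %*% mult + 1L)
}

#' @rdname state_to_index
#' @param index Integer vector of linear indices.
#' @export
index_to_state <- function(space, index) {
  sub <- arrayInd(index, space$dims) - 1L
  out <- sub * space$scale
  colnames(out) <- space$species
  out
}

# Coerce a single state vector or matrix to a matrix with species columns.
as_state_matrix <- function(states, space) {
  if (is.null(dim(states))) {
    if (!is.null(names(states))) states <- states[space$species]
    states <- matrix(as.integer(states), nrow = 1L)
  } else {
    cn <- colnames(states)
    if (!is.null(cn) && !identical(cn, space$species)) states <- states[, space$species, drop = FALSE]
    states <- matrix(as.integer(states), nrow = nrow(states))
  }
  if (ncol(states) != length(space$species)) {
    stop("state has ", ncol(states), " entries; expected ", length(space$species), call. = FALSE)
  }
  colnames(states) <- space$species
  states
}

in_box <- function(space, states) {
  states <- as_state_matrix(states, space)
  ok <- rep(TRUE, nrow(states))
  for (i in seq_along(space$species)) {
    ok <- ok & states[, i] >= 0L & states[, i] <= space$upper[i]
  }
  ok
}
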