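#' Detailed-balance conditional distribution along a lattice line
#'
#' Builds the 1-D sampling distribution over an ordered set of in-box
#' lattice points by chaining detailed-balance ratios between consecutive
#' points. Each inter-point step is decomposed into axis-aligned unit moves
#' in fixed species order (first species axis first); a unit up-step along
#' species `i` at state `x` contributes the factor
#' `a_s_i(x) / a_d_i(x + e_i)`, where `a_s_i` (`a_d_i`) is the summed
#' propensity of reactions increasing (decreasing) species `i` by one, and
#' a unit down-step contributes the reciprocal ratio evaluated at the
#' corresponding states. Detailed balance is exact for 1-D birth-death
#' chains and an approximation otherwise; the path decomposition is the
#' minimal per-species extension and its path-dependence is part of the
#' method's stated approximation error.
#'
#' Degenerate rates: a required step with zero "denominator" rate but a
#' positive "numerator" rate sends the chained weight to infinity, i.e. the
#' conditional mass accumulates at the boundary point(s) so reached; a step
#' with zero numerator rate terminates the line (zero mass beyond).
#'
#' @param network A [reaction_network()] whose fixed-change reactions move
#'   single species in unit steps.
#' @param anchor State the line passes through (used only for validation).
#' @param line Ordered integer matrix of in-box lattice points (one column
#'   per species); consecutive points may differ in several species.
#' @return Numeric probability vector over the rows of `line`.
#' @export
conditional_line_distribution <- function(network, anchor, line) {
  line <- matrix(as.integer(line), nrow = nrow(line),
                 dimnames = list(NULL, colnames(line)))
  logw <- line_log_weights(network, line)
  w <- exp(logw - max(logw[is.finite(logw)], -Inf))
  if (any(is.infinite(logw) & logw > 0)) {
    w <- as.numeric(is.infinite(logw) & logw > 0)  # boundary accumulation
  }
  if (all(w == 0)) stop("conditional line distribution has no mass", call. = FALSE)
  w / sum(w)
}

# Log relative weights of line points (first point = 0), by unit-step
# decomposition. Vectorized over the whole walk.
line_log_weights <- function(network, line) {
  L <- nrow(line); d <- ncol(line)
  if (L == 1) return(0)
  deltas <- diff(line)
  counts <- abs(deltas)
  n_mv <- sum(counts)
  if (n_mv == 0) return(numeric(L))
  # moves ordered by (segment, species): species 1 axis first within a step
  mv_sp <- rep(rep(seq_len(d), L - 1), times = as.vector(t(counts)))
  mv_sg <- rep(as.vector(t(sign(deltas))), times = as.vector(t(counts)))
  steps <- matrix(0L, n_mv, d)
  steps[cbind(seq_len(n_mv), mv_sp)] <- mv_sg
  cs <- apply(steps, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)  # single-move path
  path <- rbind(line[1, ], sweep(cs, 2, line[1, ], "+"))
  colnames(path) <- colnames(line)
  # per-species synthesis/degradation rates along the path, computed lazily
  rate_cache <- new.env(parent = emptyenv())
  rates <- function(i, dir) {
    key <- paste0(i, dir)
    if (is.null(rate_cache[[key]])) {
      a <- axis_rates(network, path, i, dir)
      if (!attr(a, "found")) {
        stop("species `", colnames(line)[i], "` has no reactions moving it in ",
             "direction ", dir, "; conditional undefined", call. = FALSE)
      }
      rate_cache[[key]] <- as.numeric(a)
    }
    rate_cache[[key]]
  }
  logfac <- numeric(n_mv)
  for (i in unique(mv_sp)) {
    up <- which(mv_sp == i & mv_sg == 1L)
    if (length(up)) logfac[up] <- log(rates(i, 1L)[up]) - log(rates(i, -1L)[up + 1L])
    dn <- which(mv_sp == i & mv_sg == -1L)
    if (length(dn)) logfac[dn] <- log(rates(i, -1L)[dn]) - log(rates(i, 1L)[dn + 1L])
  }
  cum <- cumsum(logfac)
  cum[is.nan(cum)] <- -Inf
  pos <- 1L + c(0L, cumsum(rowSums(counts)))
  c(0, cum)[pos]
}

#' Random rotation of the sampling axes
#'
#' Draws a slope `m` with `atan(m)` uniform on (-90, 90) degrees and
#' materializes the two rounded lattice lines with slopes `m` and `-1/m`
#' through the anchor: the first-axis line visits
#' `(u, round(v0 + m (u - u0)))` and the second
#' `(round(u0 - (v - v0)/m), v)`, keeping in-box points only. Both lines
#' contain the anchor exactly and consist of integer lattice points. A
#' near-vertical slope degenerates to the axis-aligned pair.
#'
#' @param anchor Named state (2 entries used: the rotated species pair).
#' @param space A [state_space()] (scale 1).
#' @param pair Indices of the two species to rotate (default 1:2).
#' @return An object of class `cme_axes`: list with `m`, `anchor`, `pair`,
#'   and `lines` (two integer matrices over all species).
#' @export
draw_rotated_axes <- function(anchor, space, pair = c(1L, 2L)) {
  m <- tan(stats::runif(1, -pi / 2, pi / 2))
  make_axes(anchor, space, m, pair)
}

make_axes <- function(anchor, space, m, pair = c(1L, 2L)) {
  anchor <- drop(as_state_matrix(anchor, space))
  if (!all(in_box(space, anchor))) stop("anchor outside the box", call. = FALSE)
  i1 <- pair[1]; i2 <- pair[2]
  if (!is.finite(m) || abs(m) > 1e8) {
    # degenerate vertical slope: the axis-aligned pair
    lines <- list(axis_line(anchor, space, i1), axis_line(anchor, space, i2))
    m <- 0
  } else {
    u0 <- anchor[i1]; v0 <- anchor[i2]
    u <- 0:space$upper[i1]
    l1 <- state_line(anchor, space, i1, u, i2, as.integer(round(v0 + m * (u - u0))))
    v <- 0:space$upper[i2]
    u_of_v <- if (m == 0) rep(u0, length(v)) else as.integer(round(u0 - (v - v0) / m))
    l2 <- state_line(anchor, space, i2, v, i1, u_of_v)
    lines <- list(l1, l2)
  }
  structure(list(m = m, anchor = anchor, pair = pair, lines = lines),
            class = "cme_axes")
}

# A full axis-aligned line through `anchor` along species i.
axis_line <- function(anchor, space, i) {
  vals <- 0:space$upper[i]
  out <- matrix(rep(anchor, each = length(vals)), nrow = length(vals),
                dimnames = list(NULL, space$species))
  out[, i] <- vals
  out
}

# Line with species ia taking values `va` and species ib the paired values
# `vb`; other species fixed at anchor. In-box rows only.
state_line <- function(anchor, space, ia, va, ib, vb) {
  out <- matrix(rep(anchor, each = length(va)), nrow = length(va),
                dimnames = list(NULL, space$species))
  out[, ia] <- va
  out[, ib] <- vb
  out[out[, ib] >= 0 & out[, ib] <= space$upper[ib], , drop = FALSE]
}

#' Sample the steady-state CME by modified Gibbs sampling
#'
#' Gibbs sampling of the steady-state distribution using detailed-balance
#' conditional distributions along lattice lines. With `rotate = TRUE`
#' (the modification that lets the sampler escape isolated modes of a
#' multimodal distribution) each cycle rotates the sampling axes of a
#' species pair by a random angle and samples along the two rounded rotated
#' lines through the current point; remaining coordinates (d > 2) are
#' sampled axis-aligned, with the rotated pair re-drawn each cycle.
#'
#' @param network A [reaction_network()] with unit-step fixed-change
#'   reactions.
#' @param space A [state_space()] with scale 1.
#' @param n Number of retained samples.
#' @param burn_in Cycles discarded before retention (default 1000).
#' @param seed Optional RNG seed recorded in the result.
#' @param rotate Rotate sampling axes each cycle (default TRUE).
#' @param init Initial state; `"mode"` (default) starts from the
#'   deterministic fixed point reached by following the reaction-rate drift
#'   from the box midpoint. With `mode_weights`, a list of one initial
#'   state per mode.
#' @param mode_weights Optional per-mode probabilities: each mode is
#'   sampled separately from its own initialization (same burn-in) and the
#'   chains are pooled with these weights. Used when modes are so isolated
#'   that even rotated sampling mixes slowly.
#' @return A `cme_samples` tibble (`n` rows, one column per species, plus
#'   `.mode` when `mode_weights` is given) with attributes `seed`,
#'   `burn_in`, `rotate`.
#' @examples
#' tog <- make_toggle(bounds = c(30, 30))
#' s <- mgs_sample(tog$network, tog$space, n = 200, burn_in = 50, seed = 1)
#' summarize_dist(s)
#' @export
mgs_sample <- function(network, space, n, burn_in = 1000, seed = NULL,
                       rotate = TRUE, init = "mode", mode_weights = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(mode_weights)) {
    if (!is.list(init) || length(init) != length(mode_weights)) {
      stop("with `mode_weights`, `init` must be a list of one state per mode",
           call. = FALSE)
    }
    mode_weights <- mode_weights / sum(mode_weights)
    nk <- round(n * mode_weights)
    nk[length(nk)] <- n - sum(nk[-length(nk)])
    parts <- lapply(seq_along(nk), function(k) {
      if (nk[k] == 0) return(NULL)
      out <- mgs_chain(network, space, nk[k], burn_in, rotate, init[[k]])
      out$.mode <- k
      out
    })
    out <- dplyr::bind_rows(parts)
  } else {
    if (identical(init, "mode")) init <- deterministic_mode(network, space)
    out <- mgs_chain(network, space, n, burn_in, rotate, init)
  }
  attr(out, "space") <- space
  attr(out, "seed") <- seed
  attr(out, "burn_in") <- burn_in
  attr(out, "rotate") <- rotate
  class(out) <- c("cme_samples", class(out))
  out
}

mgs_chain <- function(network, space, n, burn_in, rotate, init) {
  d <- length(space$species)
  cur <- drop(as_state_matrix(init, space))
  if (!all(in_box(space, cur))) stop("`init` outside the box", call. = FALSE)
  out <- matrix(0L, n, d, dimnames = list(NULL, space$species))
  total <- burn_in + n
  for (it in seq_len(total)) {
    cur <- mgs_cycle(network, space, cur, rotate)
    if (it > burn_in) out[it - burn_in, ] <- cur
  }
  tibble::as_tibble(as.data.frame(out))
}

# One full sampling cycle from state `cur`; returns the new state.
# A cycle always sweeps the d species axes (the basic Gibbs cycle, whose
# detailed-balance conditionals carry little stationary bias); with
# `rotate`, the coordinate system of one species pair is then rotated by a
# random angle and the two rounded rotated lines are sampled as well, which
# is what lets the chain hop between isolated modes.
mgs_cycle <- function(network, space, cur, rotate) {
  d <- length(space$species)
  for (i in seq_len(d)) {
    cur <- sample_line(network, cur, axis_line(cur, space, i))
  }
  if (rotate && d >= 2) {
    pair <- if (d == 2) c(1L, 2L) else sort(sample.int(d, 2))
    m <- tan(stats::runif(1, -pi / 2, pi / 2))
    for (step in 1:2) {
      ax <- make_axes(cur, space, if (step == 1) m else slope_perp(m), pair)
      cur <- sample_line(network, cur, ax$lines[[step]])
    }
  }
  cur
}

slope_perp <- function(m) if (m == 0) Inf else -1 / m

sample_line <- function(network, cur, line) {
  p <- conditional_line_distribution(network, cur, line)
  line[sample.int(nrow(line), 1L, prob = p), ]
}

# Deterministic fixed point by damped Euler descent of the reaction-rate
# drift from the box midpoint (fixed-change reactions only).
deterministic_mode <- function(network, space, start = NULL) {
  ch <- lapply(network$reactions, function(r) change_vector(network, r))
  if (any(vapply(ch, is.null, logical(1)))) {
    stop("deterministic-mode initialization requires fixed-change reactions; ",
         "give `init` explicitly", call. = FALSE)
  }
  V <- do.call(rbind, ch)
  x <- if (is.null(start)) space$upper / 2 else as.numeric(start)
  for (it in 1:2000) {
    a <- propensity_matrix(network, matrix(pmax(x, 0), nrow = 1,
                                           dimnames = list(NULL, space$species)))
    drift <- drop(a %*% V)
    x_new <- pmin(pmax(x + 0.2 * drift, 0), space$upper)
    if (max(abs(x_new - x)) < 1e-10) break
    x <- x_new
  }
  stats::setNames(as.integer(round(x)), space$species)
}

#' Detailed-balance error diagnostic
#'
#' Quantifies how far the per-species detailed-balance approximation used
#' by the Gibbs conditionals is from the truth, given the exact solution:
#' for species `i`, compares the true probability ratio
#' `r_true = P(x + e_i)/P(x)` with the detailed-balance ratio
#' `r_DB = a_s_i(x)/a_d_i(x + e_i)` and averages the relative error
#' `|r_DB - r_true| / r_true` weighted by `P(x)` (renormalized over the
#' included states: those where `r_true` is defined and nonzero and
#' `r_DB` is defined). Exactly zero for any 1-D birth-death chain, where
#' detailed balance holds.
#'
#' @param network A [reaction_network()].
#' @param p_direct Exact solution from [solve_steady_state()].
#' @return A tibble with columns `species`, `error` (source-weighted, the
#'   declared convention) and `error_dest` (weighted by `P(x + e_i)`, an
#'   alternative convention reported alongside). Species with no
#'   synthesis or degradation reactions get `NA`.
#' @examples
#' tog <- make_toggle()
#' detailed_balance_error(tog$network, solve_model(tog))
#' @export
detailed_balance_error <- function(network, p_direct) {
  space <- dist_space(p_direct)
  states <- enumerate_states(space)
  P <- p_direct$prob
  d <- length(space$species)
  strides <- cumprod(c(1L, space$dims[-d]))
  rows <- lapply(seq_len(d), function(i) {
    a_s <- axis_rates(network, states, i, 1L)
    a_d <- axis_rates(network, states, i, -1L)
    if (!attr(a_s, "found") || !attr(a_d, "found")) {
      return(tibble::tibble(species = space$species[i],
                            error = NA_real_, error_dest = NA_real_))
    }
    src <- which(states[, i] < space$upper[i])
    up <- src + strides[i]
    ok <- P[src] > 0 & P[up] > 0 & a_d[up] > 0
    src <- src[ok]; up <- up[ok]
    r_true <- P[up] / P[src]
    r_db <- a_s[src] / a_d[up]
    rel <- abs(r_db - r_true) / r_true
    tibble::tibble(
      species = space$species[i],
      error = sum(P[src] * rel) / sum(P[src]),
      error_dest = sum(P[up] * rel) / sum(P[up])
    )
  })
  dplyr::bind_rows(rows)
}
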