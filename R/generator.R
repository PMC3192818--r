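#' Build the steady-state CME generator matrix
#'
#' Assembles the rate (generator) matrix `M` of the chemical master equation
#' over the enumerated lattice of `space`, such that the steady-state
#' probability vector solves `M P = 0`. Entry `(x', x)` accumulates
#' `a_j(x) * kernel_j(x -> x')` over reactions; the diagonal holds minus the
#' total outflow, restricted to in-box destinations, so every column sums to
#' zero (mass-conserving reflecting truncation: transitions that would leave
#' the box get zero rate).
#'
#' On a coarse lattice (`space$scale = S > 1`) each fixed-change reaction
#' `j` moves `x -> x + S * v_j` at rate `a_j(x)` evaluated at the coarse
#' source point; this finite-difference construction reduces exactly to the
#' unscaled generator at `S = 1`. Jump-kernel reactions are rejected when
#' `S > 1`; under `S = 1` their destinations are clamped per-species into the
#' box (out-of-box binomial tail mass lands on the boundary cell).
#'
#' @param network A [reaction_network()].
#' @param space A [state_space()]. Guard: at most 5e6 lattice points.
#' @return A sparse `dgCMatrix` (columns sum to 0, off-diagonals >= 0).
#' @examples
#' bd <- make_birth_death(1, 1, 2)
#' as.matrix(build_generator(bd$network, bd$space))
#' @export
build_generator <- function(network, space) {
  N <- n_states(space)
  if (N > 5e6) {
    stop("state space has ", N, " points (> 5e6); enlarge the scale factor ",
         "or use the modified Gibbs sampler", call. = FALSE)
  }
  S <- space$scale
  states <- enumerate_states(space)
  A <- propensity_matrix(network, states)
  ii <- jj <- integer(0); xx <- numeric(0)
  diag_out <- numeric(N)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    ch <- change_vector(network, r)
    if (!is.null(ch)) {
      dest <- states + matrix(S * ch, nrow = N, ncol = length(ch), byrow = TRUE)
      ok <- in_box(space, dest) & A[, j] > 0
      if (!any(ok)) next
      di <- state_to_index(space, dest[ok, , drop = FALSE])
      ii <- c(ii, di); jj <- c(jj, which(ok)); xx <- c(xx, A[ok, j])
      diag_out[ok] <- diag_out[ok] + A[ok, j]
    } else {
      if (S > 1L) {
        stop("reaction `", r$name, "`: jump-kernel reactions are not supported ",
             "on a scaled lattice (S > 1)", call. = FALSE)
      }
      kern <- resolve_kernel(network, r)
      src <- which(A[, j] > 0)
      for (s in src) {
        k <- kern(states[s, ])
        dm <- as_state_matrix(k$states, space)
        for (i in seq_along(space$species)) {
          dm[, i] <- pmin(pmax(dm[, i], 0L), space$upper[i])
        }
        di <- state_to_index(space, dm)
        w <- rowsum(A[s, j] * k$prob, di)
        ii <- c(ii, as.integer(rownames(w))); jj <- c(jj, rep(s, nrow(w)))
        xx <- c(xx, w[, 1])
        diag_out[s] <- diag_out[s] + A[s, j]
      }
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  M - Matrix::Diagonal(N, diag_out)
}

#' Build the rescaled generator explicitly
#'
#' Convenience wrapper: sets the scale factor on `space` and calls
#' [build_generator()]. At `S = 1` the result is bit-identical to the
#' unscaled generator.
#'
#' @inheritParams build_generator
#' @param S Integer scale factor (>= 1).
#' @return A sparse generator on the coarse lattice.
#' @export
build_scaled_generator <- function(network, space, S) {
  build_generator(network, state_space(space$upper, scale = S))
}

#' Solve the steady-state CME
#'
#' Solves `M P = 0`, `sum(P) = 1` by replacing one balance row of the sparse
#' generator with the normalization row and solving the resulting
#' nonsingular system. Tiny negative entries (> -1e-12) are clipped to zero
#' and the vector renormalized; the residual `max|M P|` is checked against
#' 1e-9.
#'
#' @param matrix Generator from [build_generator()].
#' @param space The [state_space()] the generator was built on.
#' @return A `cme_dist`; attribute `residual` holds `max|M P|`.
#' @examples
#' bd <- make_birth_death(1, 1, 2)
#' solve_steady_state(build_generator(bd$network, bd$space), bd$space)$prob
#' @export
solve_steady_state <- function(matrix, space) {
  N <- ncol(matrix)
  if (!is.null(space) && n_states(space) != N) {
    stop("generator dimension does not match the state space", call. = FALSE)
  }
  M2 <- matrix
  M2[N, ] <- 1
  b <- c(rep(0, N - 1), 1)
  p <- tryCatch(
    as.numeric(Matrix::solve(M2, b)),
    error = function(e) stop("steady-state solve failed (", conditionMessage(e),
                             "); the truncated chain may be disconnected - check bounds",
                             call. = FALSE)
  )
  if (any(p < -1e-8)) {
    stop("solution has substantially negative entries; the chain appears ",
         "numerically rank-deficient beyond one null dimension - check bounds",
         call. = FALSE)
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  res <- max(abs(matrix %*% p))
  if (res > 1e-9) {
    stop("steady-state residual max|MP| = ", signif(res, 3),
         " exceeds 1e-9; check bounds/conditioning", call. = FALSE)
  }
  out <- new_cme_dist(space, p)
  attr(out, "residual") <- res
  out
}

#' Solve a model end to end
#'
#' One-call convenience: builds the generator for `model` (a
#' `list(network, space)` as returned by the model constructors or
#' [parse_model_config()]) and solves it.
#'
#' @param model A list with elements `network` and `space`.
#' @param S Optional scale factor overriding the space's.
#' @return A `cme_dist`.
#' @export
solve_model <- function(model, S = NULL) {
  space <- model$space
  if (!is.null(S)) space <- state_space(space$upper, scale = S)
  solve_steady_state(build_generator(model$network, space), space)
}

#' Normalize raw coarse-lattice mass
#'
#' Converts a raw nonnegative vector on a scale-`S` coarse lattice into a
#' `cme_dist`: each coarse point represents the aggregated mass of the
#' `S^d` underlying fine states, masses are normalized to total 1, and the
#' per-fine-state density view is attached as attribute `density`
#' (`prob / S^d`).
#'
#' @param raw Nonnegative mass per coarse point.
#' @param space The coarse [state_space()].
#' @return A `cme_dist` with attribute `density`.
#' @export
normalize_scaled <- function(raw, space) {
  if (all(raw == 0)) stop("all-zero raw mass", call. = FALSE)
  out <- new_cme_dist(space, raw)
  attr(out, "density") <- out$prob / space$scale^length(space$species)
  out
}
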