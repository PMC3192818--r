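#' Gillespie stochastic simulation (direct method)
#'
#' Exact stochastic simulation of the reaction network on the truncated
#' state space, used as an independent oracle for the steady-state
#' solutions: waiting times are exponential in the total propensity, the
#' firing reaction is chosen proportionally to its propensity, and
#' jump-kernel reactions sample their destination from the kernel. The
#' simulation runs on the same truncated chain as the direct solver
#' (transitions leaving the box have zero rate), so long-run occupancy and
#' the solved steady state estimate the same distribution; enlarge the
#' bounds of `space` to probe truncation effects.
#'
#' Propensities and destinations are tabulated per state once and the event
#' loop runs in compiled code, so long horizons (`t_max = 1e5` with total
#' propensities of order 10-100) are practical.
#'
#' @param network A [reaction_network()].
#' @param space A [state_space()] (scale 1).
#' @param init Initial state (named vector); defaults to the origin.
#' @param t_max Simulation horizon (> 0, model time units).
#' @param seed Optional RNG seed (identical seeds give identical
#'   trajectories).
#' @param burn_in Time discarded before occupancy accumulation
#'   (default `0.1 * t_max`).
#' @param record Keep the per-event record (times + states)? Records up to
#'   `record_max` events; beyond that only occupancy is kept.
#' @param record_max Event-record capacity (default 2e6).
#' @return A `cme_trajectory`: list with `times`, `states` (tibble, one row
#'   per recorded event), `occupancy` (post-burn-in residence times per
#'   lattice state), `t_end`, `n_events`, `absorbed` flag, `burn_in`,
#'   `seed` and the `space`.
#' @examples
#' bd <- make_birth_death(20, 1, 60)
#' tr <- gillespie_simulate(bd$network, bd$space, t_max = 1000, seed = 1)
#' occupancy_distribution(tr) |> summarize_dist()
#' @export
gillespie_simulate <- function(network, space, init = NULL, t_max, seed = NULL,
                               burn_in = 0.1 * t_max, record = TRUE,
                               record_max = 2e6) {
  stopifnot(t_max > 0)
  if (space$scale != 1L) stop("simulation requires an unscaled lattice", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- stats::setNames(integer(length(space$species)),
                                             space$species)
  init_idx <- state_to_index(space, init)
  tab <- ssa_tables(network, space)
  res <- ssa_run_cpp(tab$A, tab$dest, init_idx, t_max, burn_in,
                     if (record) as.integer(record_max) else 0L)
  states <- if (res$recorded && length(res$state_idx)) {
    tibble::as_tibble(as.data.frame(index_to_state(space, res$state_idx)))
  } else NULL
  structure(
    list(times = if (res$recorded) res$times else NULL,
         states = states,
         occupancy = res$occupancy,
         t_end = res$t_end, n_events = res$n_events,
         absorbed = res$absorbed, burn_in = burn_in, init = init,
         seed = seed, space = space),
    class = "cme_trajectory"
  )
}

#' @export
print.cme_trajectory <- function(x, ...) {
  cat("<cme_trajectory> ", format(x$n_events, big.mark = ","), " events to t = ",
      format(x$t_end), if (x$absorbed) " (absorbed)", "\n", sep = "")
  invisible(x)
}

# Precompute per-state propensity and destination tables.
ssa_tables <- function(network, space) {
  states <- enumerate_states(space)
  A <- propensity_matrix(network, states)
  N <- nrow(states)
  dest <- vector("list", length(network$reactions))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    ch <- change_vector(network, r)
    if (!is.null(ch)) {
      dm <- states + matrix(ch, N, length(ch), byrow = TRUE)
      ok <- in_box(space, dm)
      di <- integer(N)
      di[ok] <- state_to_index(space, dm[ok, , drop = FALSE])
      A[!ok, j] <- 0  # reflecting truncation, as in the generator
      dest[[j]] <- di
    } else {
      kern <- resolve_kernel(network, r)
      ptr <- integer(N + 1L)
      idx_l <- vector("list", N); cum_l <- vector("list", N)
      for (s in seq_len(N)) {
        if (A[s, j] > 0) {
          k <- kern(states[s, ])
          dm <- as_state_matrix(k$states, space)
          for (i in seq_along(space$species)) {
            dm[, i] <- pmin(pmax(dm[, i], 0L), space$upper[i])
          }
          di <- state_to_index(space, dm)
          w <- rowsum(k$prob, di)
          idx_l[[s]] <- as.integer(rownames(w))
          cum_l[[s]] <- cumsum(w[, 1]) / sum(w[, 1])
        }
        ptr[s + 1L] <- ptr[s] + length(idx_l[[s]])
      }
      dest[[j]] <- list(ptr = ptr, idx = unlist(idx_l, use.names = FALSE),
                        cum = unlist(cum_l, use.names = FALSE))
      if (is.null(dest[[j]]$idx)) dest[[j]]$idx <- integer(0)
      if (is.null(dest[[j]]$cum)) dest[[j]]$cum <- numeric(0)
    }
  }
  list(A = A, dest = dest)
}

#' Time-weighted occupancy distribution of a trajectory
#'
#' State probabilities proportional to total residence time after the
#' burn-in window (time-weighted, not event-weighted).
#'
#' @param trajectory A `cme_trajectory`.
#' @param burn_in Burn-in time; default: the value used at simulation time.
#'   Other values require an intact event record.
#' @return A `cme_dist` of occupancy frequencies.
#' @export
occupancy_distribution <- function(trajectory, burn_in = NULL) {
  if (is.null(burn_in) || isTRUE(all.equal(burn_in, trajectory$burn_in))) {
    occ <- trajectory$occupancy
  } else {
    if (is.null(trajectory$times)) {
      stop("event record unavailable; rerun with `record = TRUE` or use the ",
           "simulation-time burn-in", call. = FALSE)
    }
    if (burn_in >= trajectory$t_end) stop("burn-in leaves no time window", call. = FALSE)
    sp <- trajectory$space
    tt <- c(0, trajectory$times, trajectory$t_end)
    si <- c(state_to_index(sp, trajectory$init),
            state_to_index(sp, as.matrix(trajectory$states)))
    dur <- pmax(pmin(tt[-1], trajectory$t_end) - pmax(tt[-length(tt)], burn_in), 0)
    occ <- numeric(n_states(sp))
    agg <- rowsum(dur, si)
    occ[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (sum(occ) <= 0) stop("empty post-burn-in window", call. = FALSE)
  new_cme_dist(trajectory$space, occ)
}
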