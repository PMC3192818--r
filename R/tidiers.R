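#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a steady-state distribution
#'
#' Returns the per-state table (species columns + `prob`) as a plain tibble.
#'
#' @param x A `cme_dist`.
#' @param ... Unused.
#' @export
tidy.cme_dist <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  out
}

#' One-row summary of a steady-state distribution
#'
#' Reports the lattice size, the linear-system residual (when the
#' distribution came from [solve_steady_state()]), total mass and the
#' per-species means as `mean_<species>` columns.
#'
#' @param x A `cme_dist`.
#' @param ... Unused.
#' @export
glance.cme_dist <- function(x, ...) {
  sp <- dist_space(x)
  mom <- summarize_dist(x)
  means <- stats::setNames(as.list(mom$mean), paste0("mean_", mom$species))
  tibble::as_tibble(c(
    list(n_states = nrow(x),
         residual = attr(x, "residual") %||% NA_real_,
         total_prob = sum(x$prob)),
    means
  ))
}

#' Tidy / summarize a Gillespie trajectory
#'
#' `tidy()` returns the recorded event table (time + state); `glance()` the
#' run metadata.
#'
#' @param x A `cme_trajectory`.
#' @param ... Unused.
#' @export
tidy.cme_trajectory <- function(x, ...) {
  if (is.null(x$times)) stop("event record unavailable (record = FALSE or overflow)",
                             call. = FALSE)
  dplyr::bind_cols(tibble::tibble(time = x$times), x$states)
}

#' @rdname tidy.cme_trajectory
#' @export
glance.cme_trajectory <- function(x, ...) {
  tibble::tibble(t_end = x$t_end, n_events = x$n_events,
                 absorbed = x$absorbed, burn_in = x$burn_in,
                 seed = x$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
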