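#' Analytic steady state of a 1-D birth-death chain
#'
#' For a single species with synthesis rate `a_s(n)` and degradation rate
#' `a_d(n)`, the steady state satisfies the detailed-balance product
#' recursion `P(n) = P(n-1) * a_s(n-1) / a_d(n)`, with `P(0)` fixed by
#' normalization over `[0, n_max]`. Computed in log space for numerical
#' stability.
#'
#' @param a_s Vectorized synthesis rate function of `n`.
#' @param a_d Vectorized degradation rate function of `n`; must be positive
#'   for `1 <= n <= n_max`.
#' @param n_max Upper truncation bound.
#' @return A 1-D `cme_dist` over species `n`.
#' @examples
#' birth_death_analytic(function(n) 20, function(n) n, 60)
#' @export
birth_death_analytic <- function(a_s, a_d, n_max) {
  n <- seq_len(n_max)
  dn <- a_d(n)
  if (any(dn <= 0)) {
    stop("a_d(n) must be positive for 1 <= n <= n_max (zero degradation at n = ",
         n[which(dn <= 0)[1]], ")", call. = FALSE)
  }
  sn <- a_s(n - 1)
  if (any(sn < 0)) stop("a_s(n) must be nonnegative", call. = FALSE)
  logw <- c(0, cumsum(log(sn) - log(dn)))
  new_cme_dist(state_space(c(n = n_max)), exp(logw - max(logw)))
}

#' Truncated Poisson steady state of constitutive expression
#'
#' Constitutive expression (zeroth-order synthesis `k_s`, first-order decay
#' `k_d * n`) has steady state `P(n) = exp(-lambda) lambda^n / n!` with
#' `lambda = k_s / k_d`, renormalized on `[0, n_max]`.
#'
#' @param k_s Synthesis rate.
#' @param k_d Degradation rate constant.
#' @param n_max Upper truncation bound. A warning is issued when
#'   `n_max < lambda + 6*sqrt(lambda)`, i.e. when the box captures less
#'   than about `1 - 1e-6` of the mass.
#' @return A 1-D `cme_dist`.
#' @export
poisson_constitutive <- function(k_s, k_d, n_max) {
  stopifnot(k_s > 0, k_d > 0)
  lambda <- k_s / k_d
  if (n_max < lambda + 6 * sqrt(lambda)) {
    warning("n_max = ", n_max, " < lambda + 6*sqrt(lambda); truncation captures ",
            "less than 1 - 1e-6 of the Poisson mass", call. = FALSE)
  }
  birth_death_analytic(function(n) rep(k_s, length(n)), function(n) k_d * n, n_max)
}

#' Gamma-mixed constitutive expression (extrinsic parameter variability)
#'
#' Models extrinsic noise in constitutive expression by drawing the mean
#' `y = k_s / k_d` from a gamma distribution with shape `alpha` and scale
#' `theta` and integrating the Poisson steady state over it. The mixture
#' integrates in closed form to a negative binomial:
#' `P(n) = dnbinom(n, size = alpha, prob = 1/(1 + theta))`, with mean
#' `alpha * theta` and variance `alpha * theta + alpha * theta^2`
#' (intrinsic Poisson variance plus the mixing variance), renormalized on
#' `[0, n_max]`.
#'
#' @param alpha Gamma shape (> 0).
#' @param theta Gamma scale (> 0), in molecules.
#' @param n_max Upper truncation bound.
#' @return A 1-D `cme_dist`.
#' @examples
#' gamma_mixed_birth_death(20, 1, 120) |> summarize_dist()
#' @export
gamma_mixed_birth_death <- function(alpha, theta, n_max) {
  stopifnot(alpha > 0, theta > 0)
  new_cme_dist(state_space(c(n = n_max)),
               stats::dnbinom(0:n_max, size = alpha, prob = 1 / (1 + theta)))
}
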