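#' Birth-death (constitutive expression) model
#'
#' One species `n` with zeroth-order synthesis at rate `k_s` and first-order
#' degradation at rate `k_d * n`. Its steady state is Poisson with mean
#' `k_s / k_d`, truncated to `[0, n_max]`.
#'
#' @param k_s Synthesis rate (molecules/time).
#' @param k_d Degradation rate constant (/time).
#' @param n_max Upper truncation bound.
#' @return `list(network, space)`.
#' @export
make_birth_death <- function(k_s, k_d, n_max) {
  stopifnot(k_s > 0, k_d > 0)
  list(
    network = reaction_network(
      species = "n",
      reactions = list(
        reaction("synthesis", "k_s", change = c(n = 1)),
        reaction("degradation", "k_d * n", change = c(n = -1))
      ),
      parameters = c(k_s = k_s, k_d = k_d)
    ),
    space = state_space(c(n = n_max))
  )
}

#' Genetic toggle switch model
#'
#' Two mutually repressing proteins U and V with Hill-repression synthesis
#' and linear degradation:
#' U synthesis `r_u / (1 + (v/K_v)^beta)`, U degradation `d_u * u`,
#' V synthesis `r_v / (1 + (u/K_u)^gamma)`, V degradation `d_v * v`.
#' With the optional antibiotic perturbation block (`d_v0`, `d_v1`, `k_A`,
#' `A`), V's degradation rate constant becomes
#' `d_v0 + d_v1 * A / (A + k_A)` (basal rate `d_v0`, maximal
#' `d_v0 + d_v1`, half-maximal antibiotic concentration `k_A`).
#'
#' @param K_u,K_v Repression half-max constants (molecules). `K_v` gates
#'   repression of U (by V); `K_u` gates repression of V (by U).
#' @param r_u,r_v Maximal synthesis rates (molecules/time).
#' @param beta,gamma Hill exponents for repression of U and of V.
#' @param d_u,d_v Degradation rate constants (/time).
#' @param nfx Optional list `list(d_v0, d_v1, k_A, A)` replacing `d_v`.
#' @param bounds Length-2 vector of upper truncation bounds for (u, v).
#'   The default (60, 60) keeps boundary mass below 1e-8 for the reference
#'   parameter sets.
#' @return `list(network, space)`.
#' @examples
#' tog <- make_toggle()           # reference parameter set 1
#' propensity_vector(tog$network, c(u = 0, v = 0))
#' @export
make_toggle <- function(K_u = 1, K_v = 1, r_u = 10, r_v = 9, beta = 2,
                        gamma = 2, d_u = 1, d_v = 1, nfx = NULL,
                        bounds = c(60, 60)) {
  pars <- c(K_u = K_u, K_v = K_v, r_u = r_u, r_v = r_v, beta = beta,
            gamma = gamma, d_u = d_u)
  if (is.null(nfx)) {
    pars <- c(pars, d_v = d_v)
    v_deg <- "d_v * v"
  } else {
    pars <- c(pars, d_v0 = nfx$d_v0, d_v1 = nfx$d_v1, k_A = nfx$k_A, A = nfx$A)
    v_deg <- "(d_v0 + d_v1 * A / (A + k_A)) * v"
  }
  list(
    network = reaction_network(
      species = c("u", "v"),
      reactions = list(
        reaction("synth_u", "r_u / (1 + (v / K_v)^beta)", change = c(u = 1)),
        reaction("degr_u", "d_u * u", change = c(u = -1)),
        reaction("synth_v", "r_v / (1 + (u / K_u)^gamma)", change = c(v = 1)),
        reaction("degr_v", v_deg, change = c(v = -1))
      ),
      parameters = pars
    ),
    space = state_space(c(u = bounds[1], v = bounds[2]))
  )
}

#' T7 RNAP growth-coupled positive-feedback circuit
#'
#' State `(n, m)`: `n` free T7 RNA polymerase molecules and `m` inactive
#' promoters out of `M` total (so `M - m` are active, each binding one
#' polymerase molecule). Five chemical reactions: synthesis from an
#' inactive promoter at `k_0 * m`, synthesis from an active promoter at
#' `k_1 * (M - m)`, activation (`O_0` + T7 -> `O_1`) at `k_f * m * n`,
#' deactivation at `k_b * (M - m)`, and degradation at `d_x0 * n`. The
#' sixth reaction is cell division: propensity `mu / (1 + n / theta)`
#' (growth slows with expression), with a jump kernel that splits the free
#' pool binomially with p = 1/2 and resets all promoters to the inactive
#' state; promoter-bound molecules are not carried into the tracked
#' daughter's free pool (see the methods vignette for why this convention
#' is used).
#'
#' Bistability requires ongoing growth; the solution is the pseudo-steady
#' state of log-phase growth with `mu` the fitted effective growth rate.
#'
#' @param M Promoter count.
#' @param k_0,k_1 Synthesis rate constants per promoter (/time).
#' @param k_f Activation rate (/molecule/time).
#' @param k_b Deactivation rate (/time).
#' @param d_x0 Degradation rate constant (/time).
#' @param mu Effective growth (division) rate (/time).
#' @param theta Growth-slowdown constant (molecules).
#' @param n_max Upper truncation bound for free T7 RNAP.
#' @return `list(network, space)`.
#' @export
make_t7 <- function(M = 10, k_0 = 0.0011, k_1 = 0.0087, k_f = 0.01,
                    k_b = 0.11, d_x0 = 0.003, mu = 0.007, theta = 1,
                    n_max = 120) {
  stopifnot(M >= 1, n_max >= 1)
  list(
    network = reaction_network(
      species = c("n", "m"),
      reactions = list(
        reaction("synth_O0", "k_0 * m", change = c(n = 1)),
        reaction("synth_O1", "k_1 * (M - m)", change = c(n = 1)),
        reaction("activate", "k_f * m * n", change = c(n = -1, m = -1)),
        reaction("deactivate", "k_b * (M - m)", change = c(n = 1, m = 1)),
        reaction("degrade", "d_x0 * n", change = c(n = -1)),
        reaction("divide", "mu / (1 + n / theta)", kernel = "t7_division")
      ),
      parameters = c(M = M, k_0 = k_0, k_1 = k_1, k_f = k_f, k_b = k_b,
                     d_x0 = d_x0, mu = mu, theta = theta)
    ),
    space = state_space(c(n = n_max, m = M))
  )
}
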