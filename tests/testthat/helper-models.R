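# Shared fixtures, built in code.

# Two-state chain: 0 -> 1 at rate 1, 1 -> 0 at rate 2; steady state (2/3, 1/3).
two_state_chain <- function() {
  list(
    network = reaction_network(
      species = "x",
      reactions = list(
        reaction("up", "k_up * (1 - x)", change = c(x = 1)),
        reaction("down", "k_dn * x", change = c(x = -1))
      ),
      parameters = c(k_up = 1, k_dn = 2)
    ),
    space = state_space(c(x = 1))
  )
}

toggle_set1 <- function(bounds = c(60, 60)) make_toggle(bounds = bounds)
toggle_set2 <- function() make_toggle(r_u = 5, r_v = 5, beta = 1)
toggle_symmetric <- function(r = 10, bounds = c(60, 60)) {
  make_toggle(r_u = r, r_v = r, bounds = bounds)
}

# Mutual-activation switch with sharp (Hill-6) feedback: modes near (1, 1)
# and (45, 45) are separated along the diagonal, so no single-coordinate
# update can cross between them -- the regime where plain Gibbs sampling
# genuinely traps and rotated lines are needed.
mutual_activation <- function(K = 15, bounds = 80) {
  list(
    network = reaction_network(
      species = c("u", "v"),
      reactions = list(
        reaction("synth_u", "b + r * v^6 / (K^6 + v^6)", change = c(u = 1)),
        reaction("degr_u", "d * u", change = c(u = -1)),
        reaction("synth_v", "b + r * u^6 / (K^6 + u^6)", change = c(v = 1)),
        reaction("degr_v", "d * v", change = c(v = -1))
      ),
      parameters = c(b = 1, r = 45, K = K, d = 1)
    ),
    space = state_space(c(u = bounds, v = bounds))
  )
}

expect_prob_vector <- function(p, tol = 1e-10) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = tol)
}
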