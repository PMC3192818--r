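test_that("generator of the two-state chain matches the hand construction", {
  ch <- two_state_chain()
  M <- as.matrix(build_generator(ch$network, ch$space))
  expect_equal(unname(M), matrix(c(-1, 1, 2, -2), 2, 2))
  p <- solve_steady_state(build_generator(ch$network, ch$space), ch$space)
  expect_equal(p$prob, c(2, 1) / 3, tolerance = 1e-12)
})

test_that("generator columns sum to zero with correct sign structure", {
  for (model in list(make_birth_death(1, 1, 2), toggle_set1(bounds = c(20, 20)),
                     make_t7(n_max = 40))) {
    M <- build_generator(model$network, model$space)
    expect_lt(max(abs(Matrix::colSums(M))), 1e-10)
    d <- Matrix::diag(M)
    expect_true(all(d <= 0))
    expect_true(all((M - Matrix::Diagonal(ncol(M), d))@x >= 0))
  }
})

test_that("truncated birth-death solves to the product recursion", {
  bd <- make_birth_death(1, 1, 2)
  p <- solve_model(bd)
  expect_equal(p$prob, c(0.4, 0.4, 0.2), tolerance = 1e-12)

  # analytic recursion, closed-form Poisson and the linear solve agree
  pa <- birth_death_analytic(function(n) rep(20, length(n)), function(n) n, 60)
  pp <- poisson_constitutive(20, 1, 60)
  ps <- solve_model(make_birth_death(20, 1, 60))
  expect_equal(pa$prob, pp$prob, tolerance = 1e-14)
  expect_lt(max(abs(pa$prob - ps$prob)), 1e-10)
})

test_that("Poisson steady state has the right moments and modal tie", {
  p <- poisson_constitutive(20, 1, 80)
  mom <- summarize_dist(p)
  expect_equal(mom$mean, 20, tolerance = 1e-9)
  expect_equal(mom$sd^2, 20, tolerance = 1e-8)
  # mass ratio P(20)/P(19) = lambda/20 = 1: modes tie
  expect_equal(p$prob[21] / p$prob[20], 1, tolerance = 1e-12)
  expect_warning(poisson_constitutive(20, 1, 30), "truncation")
})

test_that("steady-state solutions conserve mass with small residuals", {
  for (model in list(make_birth_death(5, 1, 40), toggle_set1(), make_t7())) {
    p <- solve_model(model)
    expect_prob_vector(p$prob)
    expect_lt(attr(p, "residual"), 1e-9)
  }
})

test_that("toggle statistics are stable under doubling of the truncation", {
  s1 <- summarize_dist(solve_model(toggle_set1(bounds = c(60, 60))))
  s2 <- summarize_dist(solve_model(toggle_set1(bounds = c(120, 120))))
  expect_lt(max(abs(s1$mean - s2$mean)), 1e-4)
  expect_lt(max(abs(s1$sd - s2$sd)), 1e-4)
})

test_that("disconnected chains are reported as solve failures", {
  # two absorbing halves: no transitions at all beyond state 0
  net <- reaction_network("n", list(reaction("null", "0 * n", change = c(n = 1))))
  expect_error(solve_steady_state(build_generator(net, state_space(c(n = 3))),
                                  state_space(c(n = 3))),
               "bounds|singular|disconnected")
})

test_that("oversized state spaces hit the memory guard", {
  big <- state_space(c(a = 2999, b = 2999))
  bd <- make_birth_death(1, 1, 10)
  net <- reaction_network(c("a", "b"),
                          list(reaction("s", "1 + 0 * a", change = c(a = 1))))
  expect_error(build_generator(net, big), "5e6|scale|Gibbs")
})
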