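test_that("scaled generator reduces bit-exactly to the unscaled one at S = 1", {
  tog <- toggle_set1(bounds = c(30, 30))
  M1 <- build_generator(tog$network, tog$space)
  M2 <- build_scaled_generator(tog$network, tog$space, 1L)
  expect_identical(as(M1, "generalMatrix")@x, as(M2, "generalMatrix")@x)
  expect_identical(M1@i, M2@i)
  expect_identical(M1@p, M2@p)
})

test_that("jump-kernel reactions are rejected on a coarse lattice", {
  t7 <- make_t7(n_max = 40)
  expect_error(build_scaled_generator(t7$network, t7$space, 2L), "jump-kernel")
})

test_that("scaled birth-death peaks at k_s/k_d for every scale factor", {
  k_s <- 1000
  for (S in c(1L, 2L, 5L, 10L, 25L)) {
    bd <- make_birth_death(k_s, 1, 2000)
    sp <- state_space(c(n = 2000), scale = S)
    p <- solve_steady_state(build_generator(bd$network, sp), sp)
    # the successive-point ratio P(n)/P(n-S) = k_s/(k_d n) crosses 1 exactly
    # at n = k_s/k_d, so the mass peaks there, tied with the point one step
    # below (the ratio equals 1 at the crossing)
    expect_lte(abs(p$n[which.max(p$prob)] - k_s), S)
    expect_equal(p$prob[p$n == k_s] / p$prob[p$n == k_s - S], 1,
                 tolerance = 1e-9)
    expect_lt(p$prob[p$n == k_s + S] / p$prob[p$n == k_s], 1)
    expect_gt(p$prob[p$n == k_s - S] / p$prob[p$n == k_s - 2 * S], 1)
  }
})

test_that("normalize_scaled exposes aggregated-mass and density views", {
  sp <- state_space(c(n = 90), scale = 10)
  u <- normalize_scaled(rep(2, n_states(sp)), sp)
  expect_equal(u$prob, rep(0.1, 10))
  expect_equal(attr(u, "density"), rep(0.01, 10))
  expect_error(normalize_scaled(rep(0, 10), sp), "zero")

  # coarse mean of the scaled solve tracks the Poisson mean within 1%
  bd <- make_birth_death(1000, 1, 2000)
  spc <- state_space(c(n = 2000), scale = 10)
  p <- solve_steady_state(build_generator(bd$network, spc), spc)
  expect_lt(abs(summarize_dist(p)$mean - 1000) / 1000, 0.01)
})

test_that("scaled solution converges to the binned Poisson as lambda grows", {
  ssd_at <- function(lambda, S) {
    n_max <- lambda + ceiling(8 * sqrt(lambda) / S) * S
    sp <- state_space(c(n = n_max), scale = S)
    bd <- make_birth_death(lambda, 1, n_max)
    p <- solve_steady_state(build_generator(bd$network, sp), sp)
    # exact Poisson aggregated into width-S bins centred on the coarse points
    bins <- findInterval(0:n_max, p$n - S / 2)
    q <- as.numeric(rowsum(stats::dpois(0:n_max, lambda), bins))
    sum((p$prob - q / sum(q))^2)
  }
  # at fixed S the coarse bin narrows relative to the sqrt(lambda) width of
  # the distribution, so the discretization error falls monotonically
  errs <- vapply(c(100, 400, 1600), ssd_at, numeric(1), S = 4)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)
})
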