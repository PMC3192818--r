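test_that("zero-width kernel is the identity and mass is conserved", {
  p <- poisson_constitutive(20, 1, 80)
  expect_equal(convolve_grid(p, extrinsic_noise(0))$prob, p$prob, tolerance = 1e-14)
  for (spec in list(extrinsic_noise(2), extrinsic_noise(5, a = 0.1),
                    extrinsic_noise(c(1, 3)))) {
    out <- convolve_grid(solve_model(toggle_set1(bounds = c(40, 40))), spec)
    expect_prob_vector(out$prob)
  }
  expect_error(extrinsic_noise(2, a = 1), "\\[0, 1\\)")
  expect_error(extrinsic_noise(matrix(c(1, 2, 2, 1), 2)), "semidefinite")
})

test_that("successive convolutions compose in quadrature away from boundaries", {
  p <- poisson_constitutive(60, 1, 160)  # interior-supported
  ab <- convolve_grid(convolve_grid(p, extrinsic_noise(3)), extrinsic_noise(4))
  once <- convolve_grid(p, extrinsic_noise(5))
  expect_lt(ssd(ab, once), 1e-4)
})

test_that("toggle peaks widen but barely move under symmetric noise", {
  d <- solve_model(toggle_set1())
  blur <- convolve_grid(d, extrinsic_noise(2))
  m_u <- marginal(d, "u"); b_u <- marginal(blur, "u")
  peak_shift <- abs(m_u$u[which.max(m_u$prob)] - b_u$u[which.max(b_u$prob)])
  expect_lte(peak_shift, 1)
  # spreading: the modal mass flattens (the joint SD need not grow, because
  # the boundary-renormalized kernel pushes near-zero mass inward)
  expect_lt(max(blur$prob), 0.8 * max(d$prob))
})

test_that("gamma-Poisson mixture has the closed-form moments and limits", {
  g1 <- summarize_dist(gamma_mixed_birth_death(20, 1, 200))
  expect_equal(g1$mean, 20, tolerance = 1e-6)
  expect_equal(g1$sd^2, 40, tolerance = 1e-4)
  g2 <- summarize_dist(gamma_mixed_birth_death(10, 2, 300))
  expect_equal(g2$mean, 20, tolerance = 1e-6)
  expect_equal(g2$sd^2, 60, tolerance = 1e-4)
  # degenerate mixing: theta -> 0 with alpha*theta = 20 recovers the Poisson
  narrow <- gamma_mixed_birth_death(2000, 0.01, 80)
  expect_lt(ssd(narrow, poisson_constitutive(20, 1, 80)), 1e-4)
})

test_that("closed-form mixture matches numerical quadrature over the gamma", {
  for (par in list(c(20, 1), c(10, 2))) {
    alpha <- par[1]; theta <- par[2]
    n <- 0:150
    quad <- vapply(n, function(k) {
      stats::integrate(function(y) stats::dpois(k, y) * stats::dgamma(y, alpha, scale = theta),
                       0, Inf, rel.tol = 1e-12)$value
    }, numeric(1))
    closed <- gamma_mixed_birth_death(alpha, theta, 150)$prob
    expect_lt(max(abs(closed - quad / sum(quad))), 1e-8)
  }
})

test_that("sample shifting adds the kernel variance and matches the grid route", {
  p <- poisson_constitutive(40, 1, 160)
  set.seed(1)
  x <- sample_dist(p, 1e5)
  y <- shift_samples(x, extrinsic_noise(3), seed = 2)
  expect_equal(nrow(y), nrow(x))
  v_in <- stats::var(x$n); v_out <- stats::var(y$n)
  se <- sqrt(2 / nrow(x)) * v_out  # rough SE of a variance estimate
  expect_lt(abs(v_out - (v_in + 9)), 3 * se)

  hist_shift <- as_cme_dist(y, dist_space(p))
  grid_conv <- convolve_grid(as_cme_dist(x, dist_space(p)), extrinsic_noise(3))
  expect_lte(ssd(grid_conv, hist_shift), 0.002)

  # zero covariance leaves samples untouched; background draws are appended
  expect_equal(shift_samples(x, extrinsic_noise(0), seed = 3)$n, as.numeric(x$n))
  yb <- shift_samples(x, extrinsic_noise(1, a = 0.2), seed = 4)
  expect_equal(nrow(yb), nrow(x) + round(nrow(x) * 0.25))
})

test_that("fitting recovers a known sigma and the mixture widths", {
  p <- poisson_constitutive(20, 1, 120)
  target <- convolve_grid(p, extrinsic_noise(3))
  fit <- fit_extrinsic_sigma(p, target)
  expect_equal(fit$sigma, 3, tolerance = 0.05 / 3)

  # gamma-mixed targets: best-fit Gaussian widths near the quadrature values
  f1 <- fit_extrinsic_sigma(p, gamma_mixed_birth_death(20, 1, 120), shift = TRUE)
  expect_equal(f1$sigma, 4.4, tolerance = 0.15)
  f2 <- fit_extrinsic_sigma(p, gamma_mixed_birth_death(10, 2, 120), shift = TRUE)
  expect_equal(f2$sigma, 6.1, tolerance = 0.15)
  expect_warning(
    fit_extrinsic_sigma(p, new_cme_dist(dist_space(p), rep(1, 121))),
    "flat"
  )
})

test_that("per-mode widths convolve each mode with its own kernel", {
  d <- solve_model(toggle_set1(bounds = c(40, 40)))
  spec <- extrinsic_noise(1, modes = list(
    list(center = c(u = 10, v = 0), sigma = 4),
    list(center = c(u = 0, v = 9), sigma = 0.5)
  ))
  out <- convolve_grid(d, spec)
  expect_prob_vector(out$prob)
  # the widely-blurred U mode flattens more than the barely-blurred V mode
  sd_u <- summarize_dist(out)$sd[1] - summarize_dist(d)$sd[1]
  sd_v <- summarize_dist(out)$sd[2] - summarize_dist(d)$sd[2]
  expect_gt(sd_u, sd_v)
})
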