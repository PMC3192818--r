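test_that("state indexing is a bijection and counts lattice points", {
  spaces <- list(
    state_space(c(n = 99)),
    state_space(c(u = 60, v = 60)),
    state_space(c(a = 9, b = 9, c = 9)),
    state_space(c(n = 100, m = 10), scale = 5)
  )
  for (sp in spaces) {
    expect_equal(n_states(sp), prod(floor(sp$upper / sp$scale) + 1))
    st <- enumerate_states(sp)
    idx <- state_to_index(sp, st)
    expect_identical(idx, seq_len(n_states(sp)))
    expect_identical(unname(index_to_state(sp, idx)), unname(st))
  }
  expect_error(state_space(c(n = -1)), "nonnegative")
  expect_error(state_space(c(n = 10), scale = 0), ">= 1")
  expect_error(state_space(c(10, 10)), "named")
})

test_that("propensities evaluate per the rate laws", {
  bd <- make_birth_death(20, 1, 60)
  expect_equal(unname(propensity_vector(bd$network, c(n = 5))), c(20, 5))

  tog <- toggle_set1()
  a0 <- propensity_vector(tog$network, c(u = 0, v = 0))
  expect_equal(unname(a0), c(10, 0, 9, 0))  # bare synthesis at zero repressor
  a1 <- propensity_vector(tog$network, c(u = 1, v = 1))
  expect_equal(unname(a1[1]), 10 / (1 + 1^2))  # Hill term at v = K_v
  expect_equal(unname(a1[3]), 9 / 2)
})

test_that("undeclared symbols and negative propensities are rejected", {
  expect_error(
    reaction_network("n", list(reaction("s", "k_mystery", change = c(n = 1))),
                     parameters = c(k_s = 1)),
    "k_mystery"
  )
  expect_error(
    reaction_network("n", list(reaction("s", "system('ls')", change = c(n = 1)))),
    "not allowed"
  )
  bad <- reaction_network("n",
    list(reaction("s", "k_s - 5", change = c(n = 1))),
    parameters = c(k_s = 1))
  expect_error(propensity_matrix(bad, matrix(0L, 1, 1, dimnames = list(NULL, "n"))),
               "negative")
})

test_that("jump kernels are normalized and fixed changes are degenerate kernels", {
  k <- kernel_registry("t7_division")
  out <- k(c(n = 7, m = 3), c(M = 10))
  expect_equal(sum(out$prob), 1, tolerance = 1e-12)
  expect_true(all(out$states[, "m"] == 10))
  # free pool of 2 molecules splits as Binomial(2, 1/2)
  out2 <- k(c(n = 2, m = 10), c(M = 10))
  expect_equal(out2$prob, c(1, 2, 1) / 4)
})

test_that("model configs round-trip with identical propensities", {
  path <- system.file("extdata", "models", "toggle_set1.model",
                      package = "cmenoise")
  model <- parse_model_config(path)
  expect_length(model$network$reactions, 4)
  expect_identical(model$network$species, c("u", "v"))
  expect_equal(model$network$parameters[["r_u"]], 10)

  model2 <- parse_model_config(write_model_config(model))
  set.seed(42)
  probe <- cbind(u = sample(0:60, 100, TRUE), v = sample(0:60, 100, TRUE))
  expect_equal(propensity_matrix(model$network, probe),
               propensity_matrix(model2$network, probe))
  expect_identical(model2$space$upper, model$space$upper)
})

test_that("malformed configs fail with informative errors", {
  expect_error(parse_model_config("species: [n]\nreactions: ["), "parse error")
  cfg <- "
species: [n]
parameters: {k_s: 1}
bounds: {n: 10}
reactions:
  - name: s
    propensity: k_s * k_lost
    change: {n: 1}
"
  expect_error(parse_model_config(cfg), "k_lost")
  expect_error(parse_model_config(gsub("n: 10", "n: -3", cfg)), "negative")
  expect_error(
    parse_model_config("species: [n]\nbounds: {n: 4}\nscale: 0\nreactions: []\n"),
    "S must be"
  )
})
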