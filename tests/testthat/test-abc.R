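test_that("curve distance is a weighted quadratic form", {
  a <- list(x = c(1, 2, 3), y = c(0, 1, 0))
  expect_equal(curve_distance(a, a, weights = c(x = 1, y = 1)), 0)

  # constant offset delta grows as delta^2
  shift <- function(delta) list(x = a$x + delta, y = a$y)
  d1 <- curve_distance(shift(0.1), a, weights = c(x = 1, y = 1))
  d2 <- curve_distance(shift(0.2), a, weights = c(x = 1, y = 1))
  expect_equal(d2 / d1, 4, tolerance = 1e-12)

  # hand-computed value on two 3-point toy curves:
  # x: mean((0.5, -1, 2)^2) = 5.25/3; y: mean((1, 0, -1)^2) = 2/3, weight 0.5
  m <- list(x = c(1.5, 1, 5), y = c(1, 1, -1))
  expect_equal(curve_distance(m, a, weights = c(x = 1, y = 0.5)),
               5.25 / 3 + 0.5 * 2 / 3, tolerance = 1e-12)

  expect_error(curve_distance(list(x = 1:3), a, weights = c(x = 1)),
               "same substrates")
  expect_error(curve_distance(list(x = 1:4, y = a$y), a,
                              weights = c(x = 1, y = 1)), "grids differ")
})

test_that("capacity weights temper the long substrates", {
  w <- curve_weights(c("dN-5p", "dN-8", "dN-50"))
  expect_equal(unname(w), c(1, 1 / 4, 1 / 256))
})

test_that("an infinite first tolerance reproduces the log-uniform prior", {
  sim <- toy_simulator()
  data <- sim(c(amp = 1, rate = 0.3))
  fit <- abc_smc_fit(sim, data, toy_priors(), n_particles = 400L,
                     n_generations = 1L, seed = 99,
                     weights = c(toy = 1))
  pop <- final_population(fit)
  expect_equal(sum(pop$weights), 1, tolerance = 1e-12)
  expect_identical(pop$epsilon, Inf)
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(
      pop$log10_particles[, j], "punif",
      log10(toy_priors()$lower[j]), log10(toy_priors()$upper[j])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("tolerances shrink and accepted particles respect them", {
  sim <- toy_simulator()
  data <- sim(c(amp = 1, rate = 0.3))
  fit <- abc_smc_fit(sim, data, toy_priors(), n_particles = 128L,
                     n_generations = 8L, quantile = 0.3, seed = 17,
                     weights = c(toy = 1))
  eps <- vapply(fit$generations, `[[`, numeric(1), "epsilon")
  expect_true(all(diff(eps[-1]) < 0))
  for (g in fit$generations[-1]) {
    expect_true(all(g$distances <= g$epsilon))
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
    expect_true(all(g$log10_particles >= log10(toy_priors()$lower)[col(g$log10_particles)]))
  }
  # the toy posterior concentrates on the generating parameters
  mode <- posterior_mode(fit)
  expect_equal(unname(mode["amp"]), 1, tolerance = 0.25)
  expect_equal(unname(mode["rate"]), 0.3, tolerance = 0.25 * 0.3)
})

test_that("a fixed seed reproduces populations bit for bit", {
  sim <- toy_simulator()
  data <- sim(c(amp = 2, rate = 0.1))
  f1 <- abc_smc_fit(sim, data, toy_priors(), n_particles = 64L,
                    n_generations = 3L, seed = 5, weights = c(toy = 1))
  f2 <- abc_smc_fit(sim, data, toy_priors(), n_particles = 64L,
                    n_generations = 3L, seed = 5, weights = c(toy = 1))
  expect_identical(f1$generations, f2$generations)
})

test_that("posterior mode estimation behaves on degenerate populations", {
  pop1 <- list(log10_particles = matrix(log10(2), 1, 1,
                                        dimnames = list(NULL, "a")),
               weights = 1)
  expect_equal(unname(posterior_mode(pop1)), 2, tolerance = 1e-12)

  # two equal-weight particles far apart: deterministic lower tie-break
  pop2 <- list(log10_particles = matrix(c(0, 4), 2, 1,
                                        dimnames = list(NULL, "a")),
               weights = c(0.5, 0.5))
  expect_equal(unname(posterior_mode(pop2)), 1, tolerance = 1e-6)

  expect_error(posterior_mode(list(log10_particles = NULL, weights = NULL)),
               "empty")
})

test_that("kernel mode recovers the mode of a log-normal sample", {
  set.seed(123)
  # X ~ lognormal(meanlog = 1, sdlog = 0.4); mode of log10(X) is 1/log(10)
  x <- stats::rlnorm(1e4, meanlog = 1, sdlog = 0.4)
  pop <- list(log10_particles = matrix(log10(x), ncol = 1,
                                       dimnames = list(NULL, "x")),
              weights = rep(1e-4, 1e4))
  mode <- posterior_mode(pop)
  expect_equal(unname(mode), exp(1), tolerance = 0.05 * exp(1))
})

test_that("acceptance collapse aborts with diagnostics", {
  sim <- toy_simulator()
  data <- sim(c(amp = 1, rate = 0.3))
  # an unmeetable acceptance floor trips the guard instead of spinning
  expect_error(
    abc_smc_fit(sim, data, toy_priors(), n_particles = 64L,
                n_generations = 4L, quantile = 0.2, seed = 1,
                weights = c(toy = 1), min_acceptance = 0.9),
    "acceptance collapse")
})

test_that("invalid configurations are rejected", {
  sim <- toy_simulator()
  data <- sim(c(amp = 1, rate = 0.3))
  expect_error(abc_smc_fit(sim, data, toy_priors(), quantile = 0))
  expect_error(abc_smc_fit(sim, data, toy_priors(), n_particles = 1L))
  expect_error(prior_spec(data.frame(name = "a", lower = 0, upper = 1)),
               "lower")
  expect_error(prior_spec(data.frame(name = "a", lower = 2, upper = 1)),
               "lower")
})
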