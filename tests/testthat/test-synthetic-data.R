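# Observation maps, multiplicative noise, benchmark fixtures and dataset IO.

test_that("log-normal noise is multiplicative, median-unbiased and seeded", {
  lib <- decay_library()
  tr <- simulate_network(lib, c(0.3, 0, 0, 0), c(A = 5, B = 5), seq(0, 1, 0.5))
  o1 <- apply_lognormal_noise(tr, 0.2, 123)
  o2 <- apply_lognormal_noise(tr, 0.2, 123)
  expect_identical(o1, o2)
  expect_false(identical(o1, apply_lognormal_noise(tr, 0.2, 124)))
  # Monte-Carlo check of the noise law: sample sd of log residuals ~ sigma
  big <- matrix(1, 2500, 2)
  res <- log(apply_lognormal_noise(big, 0.2, 5) / big)
  n <- length(res)
  se <- 0.2 / sqrt(2 * (n - 1))  # se of a normal sd estimate
  expect_lt(abs(sd(res) - 0.2), 3 * se)
  expect_lt(abs(mean(res)), 3 * 0.2 / sqrt(n))
  expect_error(apply_lognormal_noise(matrix(c(1, 0), 1), 0.2, 1), "positive")
  expect_error(apply_lognormal_noise(big, 0, 1), "positive")
})

test_that("the Lotka-Volterra fixture reproduces the benchmark design", {
  fx <- make_lotka_volterra_dataset(dt = 0.2, sigma = 0.2, seed = 4)
  expect_equal(length(fx$dataset$times), 76L)  # t = 0, 0.2, ..., 15
  expect_equal(n_reactions(fx$library), 16L)
  expect_equal(sum(fx$true_k > 0), 3L)
  expect_equal(unname(fx$true_k[fx$true_index]), c(1, 0.01, 0.3))
  expect_equal(unname(fx$x0), c(50, 100))
  expect_true(all(fx$dataset$observations > 0))
  # determinism and seed sensitivity
  fx2 <- make_lotka_volterra_dataset(dt = 0.2, sigma = 0.2, seed = 4)
  expect_identical(fx$dataset$observations, fx2$dataset$observations)
  fx3 <- make_lotka_volterra_dataset(dt = 0.2, sigma = 0.2, seed = 5)
  expect_false(identical(fx$dataset$observations, fx3$dataset$observations))
  # sparse variant
  expect_equal(length(make_lotka_volterra_dataset(dt = 2, seed = 1)$dataset$times),
               8L)
})

test_that("the auto-regulation fixture matches its printed design", {
  fx <- make_autoregulation_dataset(seed = 2)
  expect_equal(length(fx$dataset$times), 11L)  # t = 0, 0.05, ..., 0.5
  expect_equal(fx$true_k, c(0.5, 1, 0.15, 1, 0.5, 0.5, 1.5, 0.3))
  expect_equal(n_reactions(fx$library), 8L)
  expect_equal(unname(fx$x0), rep(20, 5))
  # g and P decay rapidly over the window
  tr <- fx$trajectory$states
  expect_lt(tr[11, "g"], tr[1, "g"] / 2)
  expect_lt(tr[11, "P"], tr[1, "P"] / 2)
})

test_that("observation maps compose and validate", {
  sp <- species_set(c("P", "Y"))
  states <- matrix(c(1, 2, 3, 4), 2, dimnames = list(NULL, c("P", "Y")))
  full <- observation_map("full", sp)
  sub <- observation_map("subset", sp, indices = "Y")
  expect_equal(apply_observation_map(full, states)[, "Y", drop = FALSE],
               apply_observation_map(sub, states))
  sums <- observation_map("linear_sum", sp, weights = c(1, 1))
  expect_equal(drop(apply_observation_map(sums, states)), rowSums(states))
  expect_error(observation_map("subset", sp, indices = c(1, 1)), "distinct")
  expect_error(observation_map("linear_sum", sp, weights = c(0, 0)),
               "positive|zero")
})

test_that("datasets round-trip through CSV and enforce positivity", {
  fx <- make_lotka_volterra_dataset(dt = 1, sigma = 0.2, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_dataset(fx$dataset, f)
  back <- read_dataset(f, fx$dataset$map)
  expect_equal(back$times, fx$dataset$times)
  expect_equal(back$observations, fx$dataset$observations, tolerance = 1e-12)
  # nonpositive entry rejected with location
  df <- read.csv(f)
  df$P[3] <- 0
  write.csv(df, f, row.names = FALSE)
  expect_error(read_dataset(f, fx$dataset$map), "row 3")
  # a subset-map dataset feeds the partial-observation model
  sub <- observation_map("subset", fx$library$species, indices = "Y")
  dsY <- time_series_dataset(fx$dataset$times,
                             fx$dataset$observations[, "Y", drop = FALSE], sub)
  model <- horseshoe_model(fx$library, dsY, horseshoe_config(tau = 1e-4),
                           x0 = fx$x0)
  params <- list(k_free = fx$true_k, lambda = rep(1, 16), c = 1, sigma = 0.2)
  expect_true(is.finite(log_likelihood(params, model)))
})

test_that("replicate datasets share the grid and serialize", {
  lib <- decay_library()
  tr <- simulate_network(lib, c(0.5, 0, 0, 0), c(A = 4, B = 1), seq(0, 2, 0.5))
  map <- observation_map("full", lib$species)
  reps <- list(apply_lognormal_noise(tr, 0.1, 1),
               apply_lognormal_noise(tr, 0.1, 2))
  ds <- time_series_dataset(tr$times, reps, map)
  expect_equal(length(ds$replicates), 2L)
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f, map)
  expect_equal(length(back$replicates), 2L)
  expect_equal(back$replicates[[2]], ds$replicates[[2]], tolerance = 1e-12)
  expect_error(time_series_dataset(tr$times, list(reps[[1]], reps[[2]][-1, ]),
                                   map), "shape")
})
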