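# The joint probability model: horseshoe scales, prior densities, derivative
# estimation, likelihood variants, and analytic gradients.

test_that("the slab-regularized scale has the published limit behavior", {
  # strong-signal regime: (tau*lambda)^2 >> c^2 pushes the scale to the slab c
  expect_equal(regularized_scale(1000, tau = 1, c = 1), 0.9999995,
               tolerance = 1e-7)
  # shrinkage regime: tau*lambda << c leaves the plain horseshoe scale
  expect_equal(regularized_scale(1, tau = 1e-8, c = 1), 1e-8,
               tolerance = 1e-16)
  # c -> Inf recovers the unregularized horseshoe (checked at 1e6 * c)
  lam <- c(0.1, 1, 50)
  expect_equal(regularized_scale(lam, tau = 0.3, c = 1e6),
               0.3 * lam, tolerance = 1e-6)
  # monotone in lambda, bounded by c
  grid <- regularized_scale(10^seq(-3, 12, 0.5), tau = 1e-4, c = 2.5)
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid < 2.5))
})

test_that("log_prior matches closed-form densities", {
  lib <- decay_library()
  model <- horseshoe_model(lib, NULL, horseshoe_config(tau = 1e-3, slab_a = 4,
                                                       slab_b = 4))
  params <- list(k_free = rep(0, 4), lambda = rep(1, 4), c = 1, sigma = 0.5)
  lp <- log_prior(params, model)
  q <- regularized_scale(1, 1e-3, 1)
  manual <- 4 * log(2 / (pi * (1 + 1^2))) +                      # half-Cauchy
    4 * (log(2) + dnorm(0, 0, q, log = TRUE)) +                  # truncated N
    (4 * log(4) - lgamma(4) - 5 * log(1) - 4) +                  # Inv-Gamma
    (log(2) + dnorm(0.5, 0, 1, log = TRUE))                      # half-normal
  expect_equal(lp, manual, tolerance = 1e-10)
  # the two fitted slab priors evaluate correctly against dgamma on 1/c
  for (ab in list(c(4, 4), c(5, 25))) {
    x <- 2.7
    direct <- crninfer:::.log_invgamma(x, ab[1], ab[2])
    via_gamma <- dgamma(1 / x, ab[1], rate = ab[2], log = TRUE) - 2 * log(x)
    expect_equal(direct, via_gamma, tolerance = 1e-12)
  }
  expect_equal(log_prior(modifyList(params, list(c = -1)), model), -Inf)
})

test_that("fixed reactions contribute likelihood but no prior terms", {
  fix <- decay_fixture()
  free_model <- horseshoe_model(fix$library, fix$dataset,
                                horseshoe_config(tau = 1e-3))
  fixed_model <- horseshoe_model(fix$library, fix$dataset,
                                 horseshoe_config(tau = 1e-3),
                                 fixed_reactions = c("A -> B" = 0.8))
  expect_equal(length(fixed_model$free_idx), 3L)
  p_free <- list(k_free = c(0.8, 0, 0, 0), lambda = rep(1, 4), c = 1,
                 sigma = 0.1)
  p_fixed <- list(k_free = c(0, 0, 0), lambda = rep(1, 3), c = 1, sigma = 0.1)
  # same full rate vector -> identical likelihood (solver tolerance scale)
  expect_equal(log_likelihood(p_free, free_model),
               log_likelihood(p_fixed, fixed_model), tolerance = 1e-6)
  # prior of the fixed model has one fewer (lambda, k) pair
  diff_terms <- log_prior(p_free, free_model) - log_prior(p_fixed, fixed_model)
  q <- regularized_scale(1, 1e-3, 1)
  expect_equal(diff_terms, log(2 / (2 * pi)) +
                 (log(2) + dnorm(0.8, 0, q, log = TRUE)), tolerance = 1e-8)
})

test_that("finite differences are second order", {
  t_u <- seq(0, 1, 0.1)
  quad <- cbind(a = t_u^2, b = 3 * t_u^2 - t_u)
  d <- estimate_derivatives(t_u, quad)
  expect_equal(d[, "a"], 2 * t_u, tolerance = 1e-10)   # exact on quadratics
  expect_equal(d[, "b"], 6 * t_u - 1, tolerance = 1e-9)
  expect_equal(estimate_derivatives(t_u, matrix(5, 11, 1))[, 1],
               rep(0, 11), tolerance = 1e-12)
  # O(dt^2) convergence on a cubic, interior points
  errs <- sapply(c(0.1, 0.05, 0.025), function(h) {
    tt <- seq(0, 1, h)
    est <- estimate_derivatives(tt, matrix(tt^3))
    max(abs(est[-c(1, length(tt)), 1] - 3 * tt[-c(1, length(tt))]^2))
  })
  rate <- log2(errs[1] / errs[2])
  expect_gt(rate, 1.7)
  # non-uniform grid stays second order (exact on quadratics)
  t_n <- c(0, 0.1, 0.25, 0.33, 0.5, 0.8, 1)
  dn <- estimate_derivatives(t_n, matrix(t_n^2 - 2 * t_n))
  expect_equal(dn[, 1], 2 * t_n - 2, tolerance = 1e-9)
  expect_error(estimate_derivatives(c(0, 1), matrix(1:2)), "3 time points")
})

test_that("latent likelihood peaks at the generating rates on a profile slice", {
  fix <- decay_fixture(sigma = 0.01)
  model <- horseshoe_model(fix$library, fix$dataset,
                           horseshoe_config(tau = 1e-3))
  slice <- sapply(seq(0.5, 1.1, 0.05), function(k1) {
    log_likelihood(list(k_free = c(k1, 0, 0, 0), lambda = rep(1, 4), c = 1,
                        sigma = 0.01), model)
  })
  k_grid <- seq(0.5, 1.1, 0.05)
  expect_lt(abs(k_grid[which.max(slice)] - 0.8), 0.051)
})

test_that("full and all-species-subset observation maps give equal likelihoods", {
  fix <- decay_fixture()
  sub <- observation_map("subset", fix$library$species, indices = c(1, 2))
  ds_sub <- time_series_dataset(fix$dataset$times, fix$dataset$observations,
                                sub)
  m_full <- horseshoe_model(fix$library, fix$dataset,
                            horseshoe_config(tau = 1e-3), x0 = fix$x0)
  m_sub <- horseshoe_model(fix$library, ds_sub, horseshoe_config(tau = 1e-3),
                           x0 = fix$x0)
  params <- list(k_free = c(0.8, 0, 0, 0), lambda = rep(1, 4), c = 1,
                 sigma = 0.1)
  expect_equal(log_likelihood(params, m_full), log_likelihood(params, m_sub))
})

test_that("replicate trajectories sum their likelihood terms", {
  lib <- decay_library()
  tr <- simulate_network(lib, c(0.8, 0, 0, 0), c(A = 10, B = 2), seq(0, 2, 0.2))
  map <- observation_map("full", lib$species)
  o1 <- apply_lognormal_noise(tr, 0.05, 1)
  o2 <- apply_lognormal_noise(tr, 0.05, 2)
  params <- list(k_free = c(0.8, 0, 0, 0), lambda = rep(1, 4), c = 1,
                 sigma = 0.05)
  ll <- function(obs) {
    ds <- time_series_dataset(tr$times, obs, map)
    log_likelihood(params, horseshoe_model(lib, ds,
                                           horseshoe_config(tau = 1e-3),
                                           x0 = c(10, 2)))
  }
  expect_equal(ll(list(o1, o2)), ll(o1) + ll(o2), tolerance = 1e-8)
})

test_that("log_posterior gradients agree with finite differences", {
  fix <- decay_fixture()
  configs <- list(
    latent = horseshoe_model(fix$library, fix$dataset,
                             horseshoe_config(tau = 1e-4)),
    inferred_z0 = horseshoe_model(fix$library, fix$dataset,
                                  horseshoe_config(tau = 1e-4),
                                  init_state = "inferred"),
    derivative = horseshoe_model(fix$library, fix$dataset,
                                 horseshoe_config(tau = 1e-4),
                                 variant = "derivative",
                                 derivative_scale = "estimated"))
  for (nm in names(configs)) {
    obj <- crninfer:::.model_objective(configs[[nm]])
    set.seed(2024)
    for (rep in 1:3) {
      th <- runif(obj$dim, -1.5, 1.5)
      if (nm == "inferred_z0") {
        th[obj$dim - 1:0] <- log(c(10, 2)) + runif(2, -0.1, 0.1)
      }
      if (rep == 3) th[obj$n_free + 1] <- 7  # a partially escaped local scale
      o <- obj$fn(th)
      g_fd <- fd_gradient(function(x) obj$fn(x)$lp, th)
      expect_lt(max(abs(g_fd - o$grad) / (1 + abs(g_fd))), 1e-4,
                label = paste("sampler gradient,", nm))
    }
  }
  # natural-scale gradient of log_posterior
  model <- configs$latent
  params <- list(k_free = c(0.7, 0.01, 0.005, 0.02), lambda = c(5, 1, 0.5, 2),
                 c = 1.3, sigma = 0.08)
  lp <- log_posterior(params, model)
  g <- attr(lp, "gradient")
  pack <- function(p) c(p$k_free, p$lambda, p$c, p$sigma)
  unpack2 <- function(v) list(k_free = v[1:4], lambda = v[5:8], c = v[9],
                              sigma = v[10])
  g_fd <- fd_gradient(function(v) as.numeric(log_posterior(unpack2(v), model,
                                                           gradient = FALSE)),
                      pack(params), h = 1e-5)
  g_an <- c(g$k_free, g$lambda, g$c, g$sigma)
  expect_lt(max(abs(g_fd - g_an) / (1 + abs(g_fd))), 5e-4)
})

test_that("the Poisson observation option is a valid density with gradients", {
  lib <- decay_library()
  tr <- simulate_network(lib, c(0.5, 0, 0, 0), c(A = 30, B = 10),
                         seq(0, 2, 0.25))
  set.seed(8)
  counts <- matrix(rpois(length(tr$states), tr$states), nrow(tr$states))
  counts[counts == 0] <- 1  # dataset requires positivity
  ds <- time_series_dataset(tr$times, counts,
                            observation_map("full", lib$species))
  model <- horseshoe_model(lib, ds, horseshoe_config(tau = 1e-3),
                           noise_model = "poisson", x0 = c(30, 10))
  obj <- crninfer:::.model_objective(model)
  set.seed(3)
  th <- runif(obj$dim, -1, 1)
  o <- obj$fn(th)
  expect_true(is.finite(o$lp))
  g_fd <- fd_gradient(function(x) obj$fn(x)$lp, th)
  expect_lt(max(abs(g_fd - o$grad) / (1 + abs(g_fd))), 1e-4)
})

test_that("a prior-only model returns the prior and tiny tau shrinks the prior predictive", {
  lib <- decay_library()
  model <- horseshoe_model(lib, NULL, horseshoe_config(tau = 1e-8))
  params <- list(k_free = c(0.1, 0, 0, 0), lambda = rep(1, 4), c = 1,
                 sigma = 0.3)
  expect_equal(as.numeric(log_posterior(params, model, gradient = FALSE)),
               log_prior(params, model))
  # direct prior simulation: nearly all rates below 1e-6 at tau = 1e-8
  set.seed(99)
  n <- 20000
  lam <- abs(rcauchy(n))
  cc <- 1 / rgamma(n, 4, rate = 4)
  k <- regularized_scale(lam, 1e-8, cc) * abs(rnorm(n))
  expect_gte(mean(k < 1e-6), 0.95)
})

test_that("solver failure inside the likelihood rejects rather than aborts", {
  sp <- species_set(c("A", "B"))
  lib <- ansatz_library(sp, list("A -> 2 A", "A -> B"))
  tr_time <- seq(0, 30, 5)
  ds <- time_series_dataset(tr_time, matrix(1, 7, 2),
                            observation_map("full", sp))
  model <- horseshoe_model(lib, ds, horseshoe_config(tau = 1), x0 = c(1, 1))
  # an explosive autocatalytic rate makes the solve blow up -> -Inf, no error
  params <- list(k_free = c(5, 0.1), lambda = c(1, 1), c = 1, sigma = 0.1)
  expect_identical(log_likelihood(params, model), -Inf)
})
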