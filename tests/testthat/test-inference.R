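# Sampler behavior: determinism, prior recovery, diagnostics, mode grouping.

test_that("run_mcmc is deterministic under a fixed seed", {
  fix <- decay_fixture()
  model <- horseshoe_model(fix$library, fix$dataset,
                           horseshoe_config(tau = 1e-3))
  p1 <- run_mcmc(model, chains = 1, warmup = 60, draws = 40, seed = 12)
  p2 <- run_mcmc(model, chains = 1, warmup = 60, draws = 40, seed = 12)
  expect_identical(p1$chains[[1]]$k, p2$chains[[1]]$k)
  p3 <- run_mcmc(model, chains = 1, warmup = 60, draws = 40, seed = 13)
  expect_false(identical(p1$chains[[1]]$k, p3$chains[[1]]$k))
})

test_that("with no data the sampler reproduces the prior marginals", {
  lib <- decay_library()
  model <- horseshoe_model(lib, NULL,
                           horseshoe_config(tau = 0.1, slab_a = 4,
                                            slab_b = 4))
  post <- run_mcmc(model, chains = 2, warmup = 400, draws = 800, seed = 21)
  lam <- do.call(rbind, lapply(post$chains, function(ch) ch$lambda))
  # half-Cauchy(0,1) quantiles: median 1, quartiles tan(pi/8), tan(3pi/8);
  # compare on the log scale where the density is logistic-like
  eta <- log(as.numeric(lam))
  expect_lt(abs(median(eta) - 0), 0.2)
  expect_lt(abs(IQR(eta) - log(tan(3 * pi / 8) / tan(pi / 8))), 0.5)
  # slab marginal: Inv-Gamma(4,4) median
  cc <- unlist(lapply(post$chains, function(ch) ch$c))
  expect_lt(abs(median(cc) - 4 / qgamma(0.5, 4, rate = 1)) /
              (4 / qgamma(0.5, 4, rate = 1)), 0.2)
  # sigma marginal: half-normal(0,1) median
  sig <- unlist(lapply(post$chains, function(ch) ch$sigma))
  expect_lt(abs(median(sig) - qnorm(0.75)), 0.15)
})

test_that("variational inference recovers the prior slab location without data", {
  lib <- decay_library()
  model <- horseshoe_model(lib, NULL,
                           horseshoe_config(tau = 0.1, slab_a = 4,
                                            slab_b = 4))
  post <- run_vi(model, iterations = 1500, seed = 5, n_draws = 500)
  cc <- post$chains[[1]]$c
  prior_median <- 4 / qgamma(0.5, 4, rate = 1)
  expect_lt(abs(median(cc) - prior_median) / prior_median, 0.3)
  # determinism
  post2 <- run_vi(model, iterations = 1500, seed = 5, n_draws = 500)
  expect_identical(post$chains[[1]]$k, post2$chains[[1]]$k)
})

test_that("VI finds the dominant rate on the decay system", {
  fix <- decay_fixture(sigma = 0.02)
  model <- horseshoe_model(fix$library, fix$dataset,
                           horseshoe_config(tau = 1e-3))
  post <- run_vi(model, iterations = 2500, seed = 6, n_draws = 400)
  k1 <- median(post$chains[[1]]$k[, 1])
  expect_lt(abs(k1 - 0.8) / 0.8, 0.25)
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(11)
  mixed <- lapply(1:4, function(i) rnorm(500))
  expect_lt(split_rhat(mixed), 1.02)
  expect_gt(ess_bulk(mixed), 800)
  separated <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(split_rhat(separated), 2)
  # strong autocorrelation lowers the effective sample size
  ar <- lapply(1:2, function(i) as.numeric(arima.sim(list(ar = 0.95), 500)))
  expect_lt(ess_bulk(ar), 300)
  expect_true(is.na(split_rhat(list(rep(1, 100), rep(1, 100)))))
})

test_that("chains group by pruned support and order by mean log posterior", {
  n <- 50
  # chain 1 and 3: only reaction 1 escapes; chain 2: only reaction 2
  sc_on <- cbind(rep(0.5, n), rep(1e-5, n), rep(1e-5, n), rep(1e-5, n))
  sc_alt <- cbind(rep(1e-5, n), rep(0.5, n), rep(1e-5, n), rep(1e-5, n))
  k_on <- cbind(rep(0.8, n), rep(0, n), rep(0, n), rep(0, n))
  k_alt <- cbind(rep(0, n), rep(0.6, n), rep(0, n), rep(0, n))
  post <- synthetic_posterior(
    chain_scales = list(sc_on, sc_alt, sc_on),
    chain_ks = list(k_on, k_alt, k_on),
    lps = list(rep(-10, n), rep(-2, n), rep(-11, n)))
  modes <- group_chains_by_mode(post, prune_config(1e-3, 0.9))
  expect_equal(length(modes), 2L)
  # brute-force ordering oracle: group mean lp, descending
  expect_equal(modes[[1]]$support, 2L)       # mean lp -2 beats (-10, -11)/2
  expect_setequal(modes[[2]]$chains, c(1L, 3L))
  expect_equal(modes[[2]]$support, 1L)
  expect_equal(modes[[1]]$mean_lp, -2)
  expect_equal(modes[[2]]$mean_lp, mean(c(rep(-10, n), rep(-11, n))))
  # all chains agreeing -> a single group
  post1 <- synthetic_posterior(list(sc_on, sc_on), list(k_on, k_on))
  expect_equal(length(group_chains_by_mode(post1)), 1L)
})

test_that("posterior archives serialize draws with provenance", {
  fix <- decay_fixture()
  model <- horseshoe_model(fix$library, fix$dataset,
                           horseshoe_config(tau = 1e-3))
  post <- run_mcmc(model, chains = 2, warmup = 50, draws = 30, seed = 2)
  d <- tempfile()
  write_posterior(post, d)
  draws <- read.csv(file.path(d, "draws.csv"))
  expect_equal(nrow(draws), 60L)
  expect_true(all(c("chain", "iteration", "k1", "lambda1", "c", "sigma",
                    "lp") %in% names(draws)))
  side <- jsonlite::read_json(file.path(d, "posterior.json"),
                              simplifyVector = TRUE)
  expect_equal(side$seed, 2L)
  expect_equal(side$n_chains, 2L)
  expect_equal(length(side$reactions), 4L)
})
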