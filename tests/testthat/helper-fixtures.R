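# Shared fixtures. Heavy posterior fits are computed once per test run and
# memoized, so the acceptance checks that share a fit do not repeat it.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 2-species, 4-reaction first-order toy with one active decay reaction;
# closed forms are available and fits take seconds
decay_library <- function() {
  sp <- species_set(c("A", "B"))
  ansatz_library(sp, list("A -> B", "A -> 0", "B -> 0", "B -> A"))
}

decay_fixture <- function(sigma = 0.02, dt = 0.1, t_end = 4, seed = 7) {
  lib <- decay_library()
  k_true <- c(0.8, 0, 0, 0)
  times <- seq(0, t_end, dt)
  traj <- simulate_network(lib, k_true, c(A = 10, B = 2), times)
  obs <- if (sigma > 0) apply_lognormal_noise(traj, sigma, seed) else traj$states
  ds <- time_series_dataset(times, obs, observation_map("full", lib$species))
  list(library = lib, dataset = ds, true_k = k_true, trajectory = traj,
       x0 = c(A = 10, B = 2))
}

# central-difference gradient of a scalar function, the oracle for the
# analytic gradients of the log posterior
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# ---- memoized benchmark fits (shared across acceptance checks) -------------

lv_dense_fit <- function() {
  .cached("lv_dense", {
    fx <- make_lotka_volterra_dataset(dt = 0.2, sigma = 0.2, seed = 11)
    model <- horseshoe_model(fx$library, fx$dataset,
                             horseshoe_config(tau = 1e-8, slab_a = 4,
                                              slab_b = 4))
    post <- run_mcmc(model, chains = 2, warmup = 500, draws = 500, seed = 3,
                     control = list(max_treedepth = 9))
    list(fx = fx, post = post)
  })
}

lv_sparse_fit <- function() {
  .cached("lv_sparse", {
    fx <- make_lotka_volterra_dataset(dt = 2.0, sigma = 0.2, seed = 11)
    model <- horseshoe_model(fx$library, fx$dataset,
                             horseshoe_config(tau = 1e-8, slab_a = 4,
                                              slab_b = 4))
    post <- run_mcmc(model, chains = 2, warmup = 1000, draws = 500, seed = 3,
                     control = list(max_treedepth = 10, adapt_delta = 0.95,
                                    tau_anneal_frac = 0.7))
    list(fx = fx, post = post)
  })
}

autoreg_fit <- function() {
  .cached("autoreg", {
    fx <- make_autoregulation_dataset(seed = 11)
    lib <- library_preset("autoreg-reduced")
    fixed <- setNames(fx$true_k[1:4], reaction_strings(lib)[1:4])
    model <- horseshoe_model(lib, fx$dataset,
                             horseshoe_config(tau = 1e-6, slab_a = 5,
                                              slab_b = 25),
                             fixed_reactions = fixed)
    post <- run_mcmc(model, chains = 4, warmup = 700, draws = 400, seed = 9,
                     control = list(max_treedepth = 9, adapt_delta = 0.95))
    list(fx = fx, lib = lib, post = post)
  })
}

# hand-built posterior object with prescribed per-chain scale/rate draws, for
# deterministic pruning and mode-grouping tests
synthetic_posterior <- function(chain_scales, chain_ks, lps = NULL,
                                library = decay_library(),
                                fixed_idx = integer(0),
                                fixed_k = numeric(0), tau = 1e-3) {
  D <- n_reactions(library)
  free_idx <- setdiff(seq_len(D), fixed_idx)
  model <- list(library = library, config = horseshoe_config(tau = tau),
                fixed_idx = fixed_idx, fixed_k = fixed_k,
                free_idx = free_idx, datasets = list(),
                variant = "latent_ode", noise_model = "lognormal",
                init_state = "fixed_to_first_observation",
                x0 = rep(1, length(library$species$names)),
                derivative_scale = "fixed",
                solver = list(rtol = 1e-6, atol = 1e-8, max_steps = 1e5,
                              err_z_only = FALSE))
  class(model) <- "crn_hs_model"
  chains <- lapply(seq_along(chain_scales), function(ci) {
    sc <- chain_scales[[ci]]
    kk <- chain_ks[[ci]]
    n <- nrow(sc)
    k_full <- matrix(0, n, D)
    k_full[, free_idx] <- kk
    if (length(fixed_idx)) {
      k_full[, fixed_idx] <- matrix(fixed_k, n, length(fixed_idx),
                                    byrow = TRUE)
    }
    list(k = k_full, lambda = sc / tau, c = rep(1, n), sigma = rep(0.1, n),
         scale = sc, lp = if (is.null(lps)) rep(-1, n) else lps[[ci]],
         diagnostics = list(divergences = 0L, max_treedepth_hits = 0L))
  })
  structure(list(model = model, chains = chains, method = "synthetic",
                 seed = 0L, free_idx = free_idx, fixed_idx = fixed_idx,
                 diagnostics = list()),
            class = "crn_posterior")
}
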