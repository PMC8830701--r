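# Posterior computation: MCMC (NUTS) and variational approximation, chain
# management, convergence diagnostics (split R-hat, effective sample size),
# posterior archives, and grouping of chains by discovered network mode.

#' Draw posterior samples with the No-U-Turn sampler
#'
#' Runs gradient-based NUTS chains on the unconstrained parameterization of a
#' [horseshoe_model()]. Each chain is initialized by jittering all
#' unconstrained parameters Uniform(-2, 2); dispersed starts let different
#' chains settle in different network modes when the posterior is multimodal.
#'
#' @param model a `crn_hs_model`.
#' @param chains number of chains.
#' @param warmup adaptation iterations per chain (discarded).
#' @param draws post-warmup iterations per chain.
#' @param seed integer seed; the run is reproducible given (seed, model,
#'   budget).
#' @param control list of sampler controls: `max_treedepth` (default 10),
#'   `adapt_delta` (default 0.9), `max_delta` divergence threshold,
#'   `init_retries` (default 20), and the warmup continuation schedule
#'   `tau_anneal_from` (default 1e-2) / `tau_anneal_frac` (default 0.6).
#'   When the configured `tau` is far below `tau_anneal_from`, warmup starts
#'   at the milder shrinkage scale and lowers it geometrically to the target
#'   over the first `tau_anneal_frac` of warmup; adaptation then continues on
#'   the exact target, and all retained draws are sampled at the configured
#'   `tau`. This is a sampler continuation strategy for the extreme-shrinkage
#'   funnel, not a change of model.
#' @return an object of class `crn_posterior`: per-chain draws of
#'   `k` (full rate vectors), `lambda`, `c`, `sigma` (and `z0` when
#'   inferred), per-draw log posterior, per-parameter split R-hat and bulk
#'   effective sample size, and sampler diagnostics.
#' @export
run_mcmc <- function(model, chains = 4L, warmup = 500L, draws = 1000L,
                     seed = 1L, control = list()) {
  obj <- .model_objective(model)
  init_retries <- if (is.null(control$init_retries)) 20L else control$init_retries
  anneal_from <- if (is.null(control$tau_anneal_from)) 1e-2 else
    control$tau_anneal_from
  anneal_frac <- if (is.null(control$tau_anneal_frac)) 0.6 else
    control$tau_anneal_frac
  control$init_retries <- NULL
  control$tau_anneal_from <- NULL
  control$tau_anneal_frac <- NULL
  tau_target <- model$config$tau
  anneal <- tau_target < anneal_from / 10
  n_anneal <- floor(warmup * anneal_frac)
  hook <- if (anneal && n_anneal > 1L) {
    function(it) {
      if (it > n_anneal + 1L) return(FALSE)
      frac <- min(1, (it - 1) / n_anneal)
      obj$set_tau(exp(log(anneal_from) +
                        frac * (log(tau_target) - log(anneal_from))))
      TRUE
    }
  } else NULL
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    old <- .save_rng_state()
    set.seed((as.integer(seed) + 1009L * ch) %% .Machine$integer.max)
    obj$set_tau(if (anneal && !is.null(hook)) anneal_from else tau_target)
    init <- NULL
    for (try in seq_len(init_retries)) {
      cand <- runif(obj$dim, -2, 2)
      if (is.finite(obj$fn(cand)$lp)) { init <- cand; break }
    }
    if (is.null(init)) {
      stop("chain ", ch, ": could not find a finite initial point after ",
           init_retries, " tries")
    }
    chain_res[[ch]] <- .nuts_chain(obj$fn, init, warmup, draws, control, hook)
    .restore_rng_state(old)
  }
  obj$set_tau(tau_target)
  .posterior_from_chains(model, obj, chain_res, method = "nuts", seed = seed)
}

#' Approximate the posterior by mean-field variational inference
#'
#' Fits a diagonal Gaussian on the unconstrained scale by stochastic ELBO
#' maximization, then resamples draws from the fitted approximation. Fast but
#' approximate; useful as a quick screening pass before MCMC.
#'
#' @param model a `crn_hs_model`.
#' @param iterations optimizer iterations.
#' @param seed integer seed.
#' @param n_draws draws resampled from the fitted approximation.
#' @param n_mc Monte Carlo samples per ELBO gradient.
#' @param lr Adam learning rate.
#' @return a `crn_posterior` (single "chain" of resampled draws) with the
#'   fitted `vi` parameters attached.
#' @export
run_vi <- function(model, iterations = 3000L, seed = 1L, n_draws = 1000L,
                   n_mc = 4L, lr = 0.02) {
  obj <- .model_objective(model)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  init <- NULL
  for (try in seq_len(50L)) {
    cand <- runif(obj$dim, -2, 2)
    if (is.finite(obj$fn(cand)$lp)) { init <- cand; break }
  }
  if (is.null(init)) stop("could not find a finite initial point")
  fit <- .advi_fit(obj$fn, init, iterations = iterations, n_mc = n_mc,
                   lr = lr)
  sd_q <- exp(fit$omega)
  draws <- matrix(rnorm(n_draws * obj$dim), n_draws, obj$dim)
  draws <- sweep(sweep(draws, 2, sd_q, "*"), 2, fit$m, "+")
  lp <- apply(draws, 1, function(th) obj$fn(th)$lp)
  res <- list(list(draws = draws, lp = lp,
                   diagnostics = list(divergences = 0L,
                                      max_treedepth_hits = 0L,
                                      elbo = fit$elbo)))
  out <- .posterior_from_chains(model, obj, res, method = "vi", seed = seed)
  out$vi <- fit
  out
}

# assemble a crn_posterior from raw unconstrained chain results
.posterior_from_chains <- function(model, obj, chain_res, method, seed) {
  Df <- obj$n_free
  D <- n_reactions(model$library)
  N <- length(model$library$species$names)
  tau <- model$config$tau
  chains <- lapply(chain_res, function(cr) {
    th <- cr$draws
    n <- nrow(th)
    lam <- exp(th[, Df + seq_len(Df), drop = FALSE])
    cc <- exp(th[, 2 * Df + 1])
    sig <- exp(th[, 2 * Df + 2])
    z <- exp(th[, seq_len(Df), drop = FALSE])
    q <- matrix(0, n, Df)
    for (i in seq_len(Df)) {
      q[, i] <- tau * cc * lam[, i] / sqrt(cc^2 + tau^2 * lam[, i]^2)
    }
    k_free <- q * z
    k_full <- matrix(0, n, D)
    k_full[, model$free_idx] <- k_free
    if (length(model$fixed_idx)) {
      k_full[, model$fixed_idx] <- matrix(model$fixed_k, n,
                                          length(model$fixed_idx),
                                          byrow = TRUE)
    }
    colnames(k_full) <- paste0("k", seq_len(D))
    colnames(lam) <- paste0("lambda", seq_len(Df))
    out <- list(k = k_full, lambda = lam, c = cc, sigma = sig,
                scale = q, lp = cr$lp, diagnostics = cr$diagnostics)
    if (obj$infer_z0) {
      out$z0 <- exp(th[, 2 * Df + 2 + seq_len(N), drop = FALSE])
      colnames(out$z0) <- model$library$species$names
    }
    out
  })
  post <- structure(list(model = model, chains = chains, method = method,
                         seed = seed,
                         free_idx = model$free_idx,
                         fixed_idx = model$fixed_idx),
                    class = "crn_posterior")
  post$diagnostics <- .posterior_diagnostics(post)
  post
}

#' @export
print.crn_posterior <- function(x, ...) {
  n <- sum(vapply(x$chains, function(c2) length(c2$lp), numeric(1)))
  cat("Posterior samples (", x$method, "): ", length(x$chains), " chain(s), ",
      n, " total draws, ", length(x$free_idx), " free reactions\n", sep = "")
  div <- sum(vapply(x$chains, function(c2) c2$diagnostics$divergences,
                    numeric(1)))
  cat("  divergences:", div, "| max split R-hat (free rates):",
      round(max(x$diagnostics$rhat_k[x$free_idx], na.rm = TRUE), 3), "\n")
  invisible(x)
}

# stack a per-chain matrix-valued component into iterations x chains x cols
.stack_component <- function(post, component, col = NULL) {
  lapply(post$chains, function(ch) {
    m <- ch[[component]]
    if (!is.null(col)) m <- m[, col, drop = TRUE]
    m
  })
}

#' Split R-hat of a set of chains
#'
#' Classic split-chain potential scale reduction: each chain is halved, and
#' the ratio of pooled to within variance is returned.
#'
#' @param chain_values list of numeric vectors (one per chain) or a matrix
#'   (iterations x chains).
#' @return scalar R-hat (NA if the parameter is essentially constant).
#' @export
split_rhat <- function(chain_values) {
  if (is.matrix(chain_values)) {
    chain_values <- lapply(seq_len(ncol(chain_values)),
                           function(j) chain_values[, j])
  }
  halves <- list()
  for (v in chain_values) {
    n2 <- floor(length(v) / 2)
    if (n2 < 2) next
    halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  m <- length(halves)
  if (m < 2) return(NA_real_)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Geyer initial-monotone-sequence estimator on the rank-normalized draws is
#' not attempted; this is the classic autocorrelation-based ESS pooled across
#' chains.
#'
#' @param chain_values list of numeric vectors (one per chain) or a matrix.
#' @return scalar effective sample size.
#' @export
ess_bulk <- function(chain_values) {
  if (is.matrix(chain_values)) {
    chain_values <- lapply(seq_len(ncol(chain_values)),
                           function(j) chain_values[, j])
  }
  n <- min(lengths(chain_values))
  m <- length(chain_values)
  if (n < 4) return(NA_real_)
  W <- mean(vapply(chain_values, var, numeric(1)))
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  # mean autocovariance across chains
  acov <- function(v) {
    v <- v - mean(v)
    stats::acf(v, lag.max = n - 2, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1, 1]
  }
  rho_hat <- Reduce(`+`, lapply(chain_values, acov)) / m / W
  # Geyer: sum of adjacent pairs while positive
  s <- 0
  t <- 1
  while (t + 1 <= length(rho_hat)) {
    pair <- rho_hat[t + 1] + if (t + 2 <= length(rho_hat)) rho_hat[t + 2] else 0
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

.posterior_diagnostics <- function(post) {
  D <- n_reactions(post$model$library)
  # R-hat / ESS on log(k) for free rates (constant for fixed ones)
  rhat_k <- rep(NA_real_, D)
  ess_k <- rep(NA_real_, D)
  for (d in post$free_idx) {
    vals <- lapply(post$chains, function(ch) log(pmax(ch$k[, d], 1e-300)))
    rhat_k[d] <- split_rhat(vals)
    ess_k[d] <- ess_bulk(vals)
  }
  sig_vals <- lapply(post$chains, function(ch) log(ch$sigma))
  c_vals <- lapply(post$chains, function(ch) log(ch$c))
  list(rhat_k = rhat_k, ess_k = ess_k,
       rhat_sigma = split_rhat(sig_vals), rhat_c = split_rhat(c_vals),
       divergences = vapply(post$chains,
                            function(ch) ch$diagnostics$divergences,
                            numeric(1)))
}

#' Group chains by their pruned network mode
#'
#' Applies the pruning rule chain by chain; chains whose retained reaction
#' sets coincide are merged into one mode group. Groups are ordered by
#' decreasing mean within-group log posterior. Diagnostics and summaries are
#' computed per group, never pooled across groups that disagree about the
#' network.
#'
#' @param post a `crn_posterior`.
#' @param config a [prune_config()].
#' @return list of objects of class `crn_mode_group`, each with `chains`
#'   (indices), `support` (retained reaction indices), `mean_lp`, and a
#'   per-group posterior (`crn_posterior` restricted to member chains).
#' @export
group_chains_by_mode <- function(post, config = prune_config()) {
  supports <- lapply(seq_along(post$chains), function(ci) {
    sub <- .subset_posterior(post, ci)
    pr <- prune_network(sub, config)
    pr$retained_idx
  })
  keys <- vapply(supports, function(s) paste(s, collapse = ","), character(1))
  groups <- split(seq_along(post$chains), keys)
  out <- lapply(groups, function(chain_idx) {
    sub <- .subset_posterior(post, chain_idx)
    mean_lp <- mean(unlist(lapply(sub$chains, function(ch) ch$lp)))
    structure(list(chains = chain_idx,
                   support = supports[[chain_idx[1]]],
                   mean_lp = mean_lp, posterior = sub),
              class = "crn_mode_group")
  })
  out <- out[order(-vapply(out, function(g) g$mean_lp, numeric(1)))]
  names(out) <- paste0("mode", seq_along(out))
  out
}

#' @export
print.crn_mode_group <- function(x, ...) {
  strs <- reaction_strings(x$posterior$model$library)
  cat("Mode group: chains [", paste(x$chains, collapse = ", "),
      "], mean log-posterior ", round(x$mean_lp, 2), "\n", sep = "")
  cat("  support:", if (length(x$support)) paste(strs[x$support],
                                                 collapse = "; ")
      else "(empty network)", "\n")
  invisible(x)
}

.subset_posterior <- function(post, chain_idx) {
  out <- post
  out$chains <- post$chains[chain_idx]
  out$diagnostics <- .posterior_diagnostics(out)
  out
}

#' Write a posterior archive to disk
#'
#' Tabular draws (one row per draw with `chain` and `iteration` columns) as
#' CSV plus a JSON sidecar with diagnostics and provenance.
#'
#' @param post a `crn_posterior`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(post, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(seq_along(post$chains), function(ci) {
    ch <- post$chains[[ci]]
    df <- data.frame(chain = ci, iteration = seq_along(ch$lp), ch$k,
                     ch$lambda, c = ch$c, sigma = ch$sigma, lp = ch$lp,
                     check.names = FALSE)
    if (!is.null(ch$z0)) df <- cbind(df, setNames(as.data.frame(ch$z0),
                                                  paste0("z0_",
                                                         colnames(ch$z0))))
    df
  })
  write.csv(do.call(rbind, tabs), file.path(dir, "draws.csv"),
            row.names = FALSE)
  side <- list(method = post$method, seed = post$seed,
               n_chains = length(post$chains),
               reactions = reaction_strings(post$model$library),
               free_idx = post$free_idx, fixed_idx = post$fixed_idx,
               diagnostics = post$diagnostics)
  jsonlite::write_json(side, file.path(dir, "posterior.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
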