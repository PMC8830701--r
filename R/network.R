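# Network extraction: posterior pruning of negligible reactions, recovered
# network summaries, posterior-predictive trajectory reconstruction, and the
# (delta, p0) sensitivity sweep.

#' Pruning rule configuration
#'
#' A free reaction is pruned when the posterior probability that its
#' effective prior scale `tau * lambda_tilde` lies below `delta` exceeds
#' `p0`.
#'
#' @param delta scale threshold (> 0); default 1e-3.
#' @param p0 posterior-probability threshold in (0, 1); default 0.90.
#' @return an object of class `crn_prune_config`.
#' @export
prune_config <- function(delta = 1e-3, p0 = 0.90) {
  stopifnot(delta > 0, p0 > 0, p0 < 1)
  structure(list(delta = delta, p0 = p0), class = "crn_prune_config")
}

#' Prune negligible reactions from a posterior
#'
#' Computes, for every free reaction, the exceedance probability
#' `p_i = P(tau * lambda_tilde_i < delta)` from the posterior draws, prunes
#' reactions with `p_i > p0`, and summarizes retained rates by their
#' posterior median and central 90% credible interval. Fixed (known)
#' reactions are always retained at their fixed rates.
#'
#' @param post a `crn_posterior` or a `crn_mode_group`.
#' @param config a [prune_config()].
#' @return an object of class `crn_network`: `retained_idx`, `pruned_idx`,
#'   `p_below` (per free reaction), `summary` data frame (reaction string,
#'   median, q05, q95, fixed flag) and the originating posterior.
#' @export
prune_network <- function(post, config = prune_config()) {
  if (inherits(post, "crn_mode_group")) post <- post$posterior
  stopifnot(inherits(post, "crn_posterior"))
  D <- n_reactions(post$model$library)
  strs <- reaction_strings(post$model$library)
  scale_draws <- do.call(rbind, lapply(post$chains, function(ch) ch$scale))
  k_draws <- do.call(rbind, lapply(post$chains, function(ch) ch$k))
  p_below <- rep(NA_real_, D)
  p_below[post$free_idx] <- colMeans(scale_draws < config$delta)
  pruned_free <- post$free_idx[p_below[post$free_idx] > config$p0]
  retained <- sort(c(setdiff(post$free_idx, pruned_free), post$fixed_idx))
  med <- apply(k_draws, 2, median)
  q05 <- apply(k_draws, 2, quantile, 0.05)
  q95 <- apply(k_draws, 2, quantile, 0.95)
  summary <- data.frame(index = seq_len(D), reaction = strs,
                        median = med, q05 = q05, q95 = q95,
                        p_below = p_below,
                        fixed = seq_len(D) %in% post$fixed_idx,
                        retained = seq_len(D) %in% retained)
  structure(list(retained_idx = retained, pruned_idx = sort(pruned_free),
                 p_below = p_below, summary = summary, config = config,
                 posterior = post),
            class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  s <- x$summary[x$summary$retained, ]
  if (nrow(s) == 0L) {
    cat("Recovered network: empty (all candidate reactions pruned)\n")
    return(invisible(x))
  }
  cat("Recovered network (", nrow(s), " reactions, delta = ",
      x$config$delta, ", p0 = ", x$config$p0, "):\n", sep = "")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s  k = %.4g  [%.4g, %.4g]%s\n", s$reaction[i],
                s$median[i], s$q05[i], s$q95[i],
                if (s$fixed[i]) "  (fixed)" else ""))
  }
  invisible(x)
}

#' Rate vector of the pruned network at the posterior median
#'
#' Retained reactions carry their posterior median (or fixed) rate; pruned
#' reactions are set to zero.
#'
#' @param network a `crn_network`.
#' @return numeric rate vector of length D.
#' @export
network_rates <- function(network) {
  k <- numeric(nrow(network$summary))
  k[network$retained_idx] <- network$summary$median[network$retained_idx]
  fixed <- network$posterior$fixed_idx
  if (length(fixed)) k[fixed] <- network$posterior$model$fixed_k
  k
}

#' Posterior-predictive trajectory bands
#'
#' Simulates the ODE forward for a subsample of posterior rate draws and
#' returns pointwise quantile bands per observable. With
#' `include_noise = TRUE` the sampled measurement noise is applied, giving
#' predictive bands for new observations rather than for the latent
#' trajectory.
#'
#' @param post a `crn_posterior`, `crn_mode_group` or `crn_network`.
#' @param times output time grid; defaults to the model's observation times.
#' @param x0 initial state; defaults to the model's.
#' @param n_draws number of posterior draws to simulate.
#' @param seed integer seed (draw subsampling and predictive noise).
#' @param include_noise apply log-normal observation noise per draw.
#' @param probs quantiles for the bands.
#' @return an object of class `crn_predictive`: `times`, `labels`, `bands`
#'   (array time x observable x quantile), `n_failed` (excluded solver
#'   failures), and the median-rate trajectory.
#' @export
posterior_predictive <- function(post, times = NULL, x0 = NULL,
                                 n_draws = 200L, seed = 1L,
                                 include_noise = FALSE,
                                 probs = c(0.05, 0.5, 0.95)) {
  if (inherits(post, "crn_network")) post <- post$posterior
  if (inherits(post, "crn_mode_group")) post <- post$posterior
  model <- post$model
  lib <- model$library
  if (is.null(times)) {
    if (length(model$datasets) == 0L) stop("times must be given for a model with no data")
    times <- model$datasets[[1]]$times
  }
  if (is.null(x0)) x0 <- model$x0
  map <- if (length(model$datasets) > 0L) model$datasets[[1]]$map else
    observation_map("full", lib$species)
  k_draws <- do.call(rbind, lapply(post$chains, function(ch) ch$k))
  sig_draws <- unlist(lapply(post$chains, function(ch) ch$sigma))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  idx <- if (nrow(k_draws) <= n_draws) seq_len(nrow(k_draws)) else
    sample.int(nrow(k_draws), n_draws)
  sims <- array(NA_real_, c(length(times), length(map$labels), length(idx)))
  n_failed <- 0L
  for (j in seq_along(idx)) {
    tr <- tryCatch(
      simulate_network(lib, k_draws[idx[j], ], x0, times),
      error = function(e) NULL)
    if (is.null(tr)) { n_failed <- n_failed + 1L; next }
    obs <- apply_observation_map(map, tr$states)
    if (include_noise) {
      obs <- obs * exp(matrix(rnorm(length(obs), 0, sig_draws[idx[j]]),
                              nrow(obs)))
    }
    sims[, , j] <- obs
  }
  if (n_failed == length(idx)) stop("all posterior-predictive solves failed")
  bands <- apply(sims, c(1, 2), quantile, probs = probs, na.rm = TRUE)
  bands <- aperm(bands, c(2, 3, 1))
  dimnames(bands) <- list(NULL, map$labels, paste0("q", probs * 100))
  med_traj <- tryCatch(
    simulate_network(lib, apply(k_draws, 2, median), x0, times),
    error = function(e) NULL)
  structure(list(times = times, labels = map$labels, bands = bands,
                 probs = probs, n_failed = n_failed,
                 median_trajectory = med_traj),
            class = "crn_predictive")
}

#' @export
print.crn_predictive <- function(x, ...) {
  cat("Posterior-predictive bands over ", length(x$times), " times, ",
      length(x$labels), " observable(s); ", x$n_failed,
      " failed draw(s) excluded\n", sep = "")
  invisible(x)
}

#' Sensitivity of the pruning decision to (delta, p0)
#'
#' For every pair on the grid, reports the retained-set size and a
#' predictive-fit score: the data log-likelihood under the median retained
#' network (pruned rates set to zero, sigma at its posterior median).
#'
#' @param post a `crn_posterior` or `crn_mode_group`.
#' @param delta_grid,p0_grid numeric grids.
#' @return data frame with columns `delta`, `p0`, `n_retained`, `fit_score`.
#' @export
sensitivity_sweep <- function(post,
                              delta_grid = 10^seq(-5, -1, by = 1),
                              p0_grid = c(0.5, 0.75, 0.9, 0.99)) {
  if (inherits(post, "crn_mode_group")) post <- post$posterior
  model <- post$model
  obj <- .model_objective(model)
  sig_med <- median(unlist(lapply(post$chains, function(ch) ch$sigma)))
  out <- expand.grid(delta = delta_grid, p0 = p0_grid)
  out$n_retained <- NA_integer_
  out$fit_score <- NA_real_
  cache <- new.env()
  for (i in seq_len(nrow(out))) {
    net <- prune_network(post, prune_config(out$delta[i], out$p0[i]))
    out$n_retained[i] <- length(net$retained_idx)
    key <- paste(net$retained_idx, collapse = ",")
    if (is.null(cache[[paste0("k", key)]])) {
      k <- network_rates(net)
      params <- list(k_free = k[model$free_idx], lambda = NULL,
                     c = NULL, sigma = sig_med)
      cache[[paste0("k", key)]] <- obj$loglik_params(params)
    }
    out$fit_score[i] <- cache[[paste0("k", key)]]
  }
  out
}

#' Write a human-readable report of recovered networks
#'
#' Produces, per mode group: `network.txt` (reaction strings with posterior
#' median rates), `pruning.csv` (per-reaction exceedance probability, median
#' and credible interval), `predictive.csv` (time, observable, quantile
#' bands), and a top-level `modes.json` describing the groups. Pairwise
#' posterior summaries (correlations between retained log-rates) are written
#' to `pairs.csv` per mode.
#'
#' @param post a `crn_posterior`.
#' @param output_dir directory to create.
#' @param config a [prune_config()].
#' @param predictive_draws draws for the predictive bands (0 skips them).
#' @param seed integer seed for predictive subsampling.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(post, output_dir, config = prune_config(),
                         predictive_draws = 200L, seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  modes <- group_chains_by_mode(post, config)
  strs <- reaction_strings(post$model$library)
  modes_meta <- list()
  for (mi in seq_along(modes)) {
    g <- modes[[mi]]
    mdir <- file.path(output_dir, names(modes)[mi])
    dir.create(mdir, showWarnings = FALSE)
    net <- prune_network(g, config)
    s <- net$summary[net$summary$retained, ]
    lines <- if (nrow(s) == 0L) {
      "(null network: every candidate reaction was pruned)"
    } else {
      sprintf("%-24s k = %.6g  [%.6g, %.6g]%s", s$reaction, s$median,
              s$q05, s$q95, ifelse(s$fixed, "  (fixed)", ""))
    }
    writeLines(c(sprintf("# mode %d: chains [%s], mean log-posterior %.2f",
                         mi, paste(g$chains, collapse = ", "), g$mean_lp),
                 lines), file.path(mdir, "network.txt"))
    write.csv(net$summary, file.path(mdir, "pruning.csv"), row.names = FALSE)
    # pairwise posterior correlations of retained free log-rates
    ret_free <- intersect(net$retained_idx, post$free_idx)
    if (length(ret_free) >= 2L) {
      kd <- do.call(rbind, lapply(g$posterior$chains, function(ch)
        log(pmax(ch$k[, ret_free, drop = FALSE], 1e-300))))
      cm <- stats::cor(kd)
      dimnames(cm) <- list(strs[ret_free], strs[ret_free])
      write.csv(round(cm, 4), file.path(mdir, "pairs.csv"))
    }
    if (predictive_draws > 0L) {
      pred <- posterior_predictive(g, n_draws = predictive_draws, seed = seed)
      pd <- do.call(rbind, lapply(seq_along(pred$labels), function(m) {
        data.frame(time = pred$times, observable = pred$labels[m],
                   q05 = pred$bands[, m, 1], q50 = pred$bands[, m, 2],
                   q95 = pred$bands[, m, 3])
      }))
      write.csv(pd, file.path(mdir, "predictive.csv"), row.names = FALSE)
    }
    modes_meta[[mi]] <- list(mode = mi, chains = g$chains,
                             mean_log_posterior = g$mean_lp,
                             retained = strs[net$retained_idx])
  }
  jsonlite::write_json(list(delta = config$delta, p0 = config$p0,
                            modes = modes_meta),
                       file.path(output_dir, "modes.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
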