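# The joint probability model: regularized-horseshoe prior over candidate
# reaction rates combined with either the latent-ODE observational likelihood
# (log-normal or Poisson measurement noise through an observation map) or the
# derivative-based likelihood on finite-difference derivative estimates.
#
# The sampler works on an unconstrained parameter vector
#   theta = [u, eta, gamma, s, (w)]
# with k_i = tau * lambda_tilde_i * exp(u_i)   (non-centered, rates >= 0),
#      lambda_i = exp(eta_i), c = exp(gamma), sigma = exp(s),
#      Z0 = exp(w) when the initial latent state is inferred.
# All gradients are analytic; the ODE part comes from forward sensitivities.

#' Regularized-horseshoe prior configuration
#'
#' @param tau global shrinkage scale (> 0): the scale at which a reaction
#'   rate counts as negligible. Smaller values give sparser networks.
#' @param slab_a,slab_b shape and scale of the Inverse-Gamma hyper-prior on
#'   the slab scale `c`, which bounds non-negligible rates.
#' @param sigma_prior_scale scale of the half-normal prior on the observation
#'   noise scale `sigma`.
#' @return an object of class `crn_hs_config`.
#' @export
horseshoe_config <- function(tau = 1e-8, slab_a = 4, slab_b = 4,
                             sigma_prior_scale = 1) {
  stopifnot(tau > 0, slab_a > 0, slab_b > 0, sigma_prior_scale > 0)
  structure(list(tau = tau, slab_a = slab_a, slab_b = slab_b,
                 sigma_prior_scale = sigma_prior_scale),
            class = "crn_hs_config")
}

#' Slab-regularized local scale
#'
#' Computes the effective prior scale `tau * lambda_tilde` of a rate, where
#' `lambda_tilde^2 = c^2 lambda^2 / (c^2 + tau^2 lambda^2)`. The scale is
#' strictly increasing in `lambda`, bounded above by `c` (the slab), and
#' reduces to `tau * lambda` when `c -> Inf` (the plain horseshoe).
#'
#' @param lambda local scale(s), > 0 (vectorized).
#' @param tau global shrinkage scale, > 0.
#' @param c slab scale, > 0.
#' @return `tau * lambda_tilde`, same length as `lambda`.
#' @export
regularized_scale <- function(lambda, tau, c) {
  stopifnot(all(lambda > 0), tau > 0, c > 0)
  tau * c * lambda / sqrt(c^2 + tau^2 * lambda^2)
}

#' Specify a sparse Bayesian reaction-network model
#'
#' Binds a candidate library, one or more datasets, the horseshoe
#' configuration and the observational-model choices into the model object
#' consumed by [run_mcmc()], [run_vi()] and [log_posterior()].
#'
#' @param library a `crn_library` of candidate reactions.
#' @param datasets a `crn_dataset` or list of them (replicate trajectories
#'   inside one dataset share the latent trajectory). `NULL` gives a
#'   prior-only model (zero likelihood), useful for prior-predictive and
#'   sampler-correctness checks.
#' @param config a [horseshoe_config()].
#' @param fixed_reactions reactions known with confidence: a named numeric
#'   vector mapping reaction strings (as in [reaction_strings()]) to their
#'   known rates. Fixed reactions enter the dynamics at their given rate and
#'   receive no shrinkage prior.
#' @param noise_model `"lognormal"` (latent trajectory is the median) or
#'   `"poisson"` (latent trajectory is the mean; observations must be
#'   counts).
#' @param variant `"latent_ode"` (likelihood on the ODE solution; no
#'   derivative estimation) or `"derivative"` (likelihood on second-order
#'   finite-difference derivative estimates; requires a full observation
#'   map).
#' @param init_state `"fixed_to_first_observation"` (default; requires a
#'   full observation map or explicit `x0`) or `"inferred"` (log-normal
#'   prior centered at `x0`).
#' @param x0 optional latent initial state; defaults to the first observation
#'   row when the map is full.
#' @param derivative_scale for the derivative variant: `"fixed"` uses unit
#'   observation scale; `"estimated"` gives the scale a half-normal prior and
#'   infers it.
#' @param solver latent-ODE solver options: `rtol` (default 1e-6), `atol`
#'   (default 1e-8), `max_steps`, and `err_z_only` (control the adaptive step
#'   error on the latent state only, letting the sensitivity components
#'   follow; cheaper, at slight cost in gradient accuracy).
#' @return an object of class `crn_hs_model`.
#' @export
horseshoe_model <- function(library, datasets, config = horseshoe_config(),
                            fixed_reactions = NULL,
                            noise_model = c("lognormal", "poisson"),
                            variant = c("latent_ode", "derivative"),
                            init_state = c("fixed_to_first_observation",
                                           "inferred"),
                            x0 = NULL,
                            derivative_scale = c("fixed", "estimated"),
                            solver = list()) {
  noise_model <- match.arg(noise_model)
  variant <- match.arg(variant)
  init_state <- match.arg(init_state)
  derivative_scale <- match.arg(derivative_scale)
  if (is.null(datasets)) datasets <- list()
  if (inherits(datasets, "crn_dataset")) datasets <- list(datasets)
  for (d in datasets) {
    if (!identical(d$map$species$names, library$species$names)) {
      stop("dataset species do not match the library species")
    }
  }
  D <- n_reactions(library)
  fixed_idx <- integer(0)
  fixed_k <- numeric(0)
  if (!is.null(fixed_reactions) && length(fixed_reactions) > 0L) {
    strs <- reaction_strings(library)
    fixed_idx <- match(names(fixed_reactions), strs)
    if (anyNA(fixed_idx)) {
      stop("fixed reaction(s) not in library: ",
           paste(names(fixed_reactions)[is.na(fixed_idx)], collapse = "; "))
    }
    if (anyDuplicated(fixed_idx)) stop("duplicate fixed reactions")
    fixed_k <- as.numeric(fixed_reactions)
    if (any(fixed_k < 0)) stop("fixed rates must be nonnegative")
  }
  free_idx <- setdiff(seq_len(D), fixed_idx)
  if (length(free_idx) == 0L) stop("model must have at least one free reaction")
  if (variant == "derivative") {
    for (d in datasets) {
      if (d$map$kind != "full") {
        stop("the derivative variant requires complete observations of all species")
      }
    }
  }
  if (is.null(x0)) {
    if (length(datasets) == 0L) {
      x0 <- rep(1, length(library$species$names))
    } else {
      d1 <- datasets[[1]]
      if (d1$map$kind != "full") {
        stop("x0 must be given explicitly unless the first dataset observes ",
             "all species")
      }
      x0 <- as.numeric(d1$observations[1, ])
    }
  } else {
    x0 <- .check_state(library, x0)
  }
  solver <- modifyList(list(rtol = 1e-6, atol = 1e-8, max_steps = 100000L,
                            err_z_only = FALSE), solver)
  structure(list(library = library, datasets = datasets, config = config,
                 fixed_idx = fixed_idx, fixed_k = fixed_k,
                 free_idx = free_idx, noise_model = noise_model,
                 variant = variant, init_state = init_state, x0 = x0,
                 derivative_scale = derivative_scale, solver = solver),
            class = "crn_hs_model")
}

#' @export
print.crn_hs_model <- function(x, ...) {
  cat("Horseshoe reaction-network model\n")
  cat("  candidate reactions:", n_reactions(x$library),
      sprintf("(%d free, %d fixed)\n", length(x$free_idx), length(x$fixed_idx)))
  cat("  variant:", x$variant, "| noise:", x$noise_model,
      "| init state:", x$init_state, "\n")
  cat(sprintf("  tau = %g, c ~ Inv-Gamma(%g, %g)\n", x$config$tau,
              x$config$slab_a, x$config$slab_b))
  invisible(x)
}

# assemble full rate vector from free rates
.full_k <- function(model, k_free) {
  k <- numeric(n_reactions(model$library))
  k[model$free_idx] <- k_free
  if (length(model$fixed_idx)) k[model$fixed_idx] <- model$fixed_k
  k
}

#' Second-order finite-difference derivative estimates
#'
#' Central differences at interior points and one-sided three-point stencils
#' at both ends, exact for quadratics; handles non-uniform grids.
#'
#' @param times strictly increasing times (>= 3 points).
#' @param values matrix (times x variables) or a `crn_dataset` (full map),
#'   in which case its first replicate is differentiated.
#' @return matrix of the same shape with derivative estimates.
#' @export
estimate_derivatives <- function(times, values = NULL) {
  if (inherits(times, "crn_dataset")) {
    if (times$map$kind != "full") {
      stop("derivative estimation requires complete observations of all species")
    }
    values <- times$observations
    times <- times$times
  }
  values <- as.matrix(values)
  T1 <- length(times)
  if (T1 < 3L) stop("at least 3 time points are required")
  if (nrow(values) != T1) stop("values rows must match times")
  out <- matrix(0, T1, ncol(values), dimnames = dimnames(values))
  for (j in seq_len(T1)) {
    if (j == 1L) {
      h1 <- times[2] - times[1]; h2 <- times[3] - times[2]
      w <- c(-(2 * h1 + h2) / (h1 * (h1 + h2)), (h1 + h2) / (h1 * h2),
             -h1 / (h2 * (h1 + h2)))
      idx <- 1:3
    } else if (j == T1) {
      h1 <- times[T1 - 1] - times[T1 - 2]; h2 <- times[T1] - times[T1 - 1]
      w <- c(h2 / (h1 * (h1 + h2)), -(h1 + h2) / (h1 * h2),
             (h1 + 2 * h2) / (h2 * (h1 + h2)))
      idx <- (T1 - 2):T1
    } else {
      h1 <- times[j] - times[j - 1]; h2 <- times[j + 1] - times[j]
      w <- c(-h2 / (h1 * (h1 + h2)), (h2 - h1) / (h1 * h2),
             h1 / (h2 * (h1 + h2)))
      idx <- (j - 1):(j + 1)
    }
    out[j, ] <- w %*% values[idx, , drop = FALSE]
  }
  out
}

# ---- densities on the natural scale ----------------------------------------

.log_halfcauchy <- function(x) log(2 / pi) - log1p(x^2)
.log_halfnormal <- function(x, scale) {
  log(2) - 0.5 * log(2 * pi) - log(scale) - x^2 / (2 * scale^2)
}
.log_invgamma <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Log prior density of the model parameters
#'
#' Sum of half-Cauchy(0,1) terms for the local scales, zero-truncated
#' Normal(0, tau*lambda_tilde) terms for the free rates, the Inverse-Gamma
#' slab prior on `c`, the half-normal prior on `sigma`, and (when the initial
#' state is inferred) a log-normal prior on `Z0`. Fixed reactions contribute
#' no terms.
#'
#' @param params list with elements `k_free`, `lambda`, `c`, `sigma` and
#'   optionally `z0`.
#' @param model a `crn_hs_model`.
#' @return log density (scalar).
#' @export
log_prior <- function(params, model) {
  cfg <- model$config
  k <- params$k_free; lam <- params$lambda
  if (any(!is.finite(c(k, lam, params$c, params$sigma)))) {
    stop("non-finite parameter values")
  }
  if (any(k < 0) || any(lam <= 0) || params$c <= 0 || params$sigma <= 0) {
    return(-Inf)
  }
  q <- regularized_scale(lam, cfg$tau, params$c)
  lp <- sum(.log_halfcauchy(lam)) +
    sum(.log_halfnormal(k, q)) +
    .log_invgamma(params$c, cfg$slab_a, cfg$slab_b) +
    .log_halfnormal(params$sigma, cfg$sigma_prior_scale)
  if (model$init_state == "inferred") {
    z0 <- params$z0
    if (is.null(z0) || any(z0 <= 0)) return(-Inf)
    lp <- lp + sum(stats::dlnorm(z0, log(model$x0), 0.5, log = TRUE))
  }
  lp
}

#' Log likelihood of the data under the model
#'
#' For the `latent_ode` variant, solves the latent trajectory
#' `Z(t)` from the full rate vector, maps it through each dataset's
#' observation map, and accumulates log-normal (or Poisson) observation terms
#' over all times, observables and replicate trajectories. For the
#' `derivative` variant, accumulates Normal terms for the finite-difference
#' derivative estimates against `t(S) %*% (k * f(Xhat))`.
#'
#' A failed ODE solve yields `-Inf` (the proposal is rejected, the chain is
#' not aborted).
#'
#' @inheritParams log_prior
#' @return log density (scalar).
#' @export
log_likelihood <- function(params, model) {
  obj <- .model_objective(model)
  obj$loglik_params(params)
}

#' Log posterior density with gradient
#'
#' `log_prior + log_likelihood`, differentiable with respect to all
#' continuous parameters (gradients propagate through the ODE solution via
#' forward sensitivities). The returned value carries a `"gradient"`
#' attribute: a list with components `k_free`, `lambda`, `c`, `sigma` (and
#' `z0` when inferred) on the natural scale.
#'
#' @inheritParams log_prior
#' @param gradient if `FALSE`, skip gradient computation.
#' @return log density with attribute `"gradient"`.
#' @export
log_posterior <- function(params, model, gradient = TRUE) {
  obj <- .model_objective(model)
  res <- obj$natural(params)
  out <- res$lp
  if (gradient) attr(out, "gradient") <- res$grad
  out
}

# ---- internal objective on the unconstrained scale --------------------------

# Builds closures for the unconstrained-scale objective used by the samplers.
# Returns list(dim, names, fn(theta) -> list(lp, grad), unpack(theta) -> params,
#              natural(params) -> list(lp, grad-list), loglik_natural(theta)).
.model_objective <- function(model) {
  cfg <- model$config
  lib <- model$library
  Df <- length(model$free_idx)
  N <- length(lib$species$names)
  a <- cfg$slab_a; b <- cfg$slab_b; s0 <- cfg$sigma_prior_scale
  tau <- cfg$tau          # target shrinkage scale (used by natural-scale ops)
  tau_s <- cfg$tau        # sampler-path scale; run_mcmc may anneal it during
  set_tau <- function(x) tau_s <<- x  # warmup, ending exactly at cfg$tau
  infer_z0 <- model$init_state == "inferred"
  latent <- model$variant == "latent_ode" || length(model$datasets) == 0L
  noise <- if (model$noise_model == "lognormal") 0L else 1L
  free0 <- as.integer(model$free_idx - 1L)
  dim <- 2L * Df + 2L + if (infer_z0) N else 0L
  names <- c(paste0("u", seq_len(Df)), paste0("eta", seq_len(Df)),
             "log_c", "log_sigma",
             if (infer_z0) paste0("w", seq_len(N)))

  if (!latent) {
    # precompute the regression structure of the derivative variant
    ds <- model$datasets
    Phi_all <- list(); y_all <- list()
    for (d in ds) {
      for (rep_obs in d$replicates) {
        dhat <- estimate_derivatives(d$times, rep_obs)
        Tn <- length(d$times)
        Phi <- matrix(0, Tn * N, n_reactions(lib))
        for (j in seq_len(Tn)) {
          f <- propensity(lib, rep_obs[j, ])
          Phi[(j - 1L) * N + seq_len(N), ] <- t(lib$stoich * f)
        }
        Phi_all[[length(Phi_all) + 1L]] <- Phi
        y_all[[length(y_all) + 1L]] <- as.numeric(t(dhat))
      }
    }
    Phi <- do.call(rbind, Phi_all)
    yv <- unlist(y_all)
    offset <- if (length(model$fixed_idx)) {
      drop(Phi[, model$fixed_idx, drop = FALSE] %*% model$fixed_k)
    } else 0
    Phi_free <- Phi[, model$free_idx, drop = FALSE]
    resid_target <- yv - offset
    n_obs <- length(yv)
    est_scale <- model$derivative_scale == "estimated"
    loglik_k <- function(k_free, sig) {
      r <- resid_target - drop(Phi_free %*% k_free)
      sc <- if (est_scale) sig else 1
      ll <- -n_obs * log(sc) - 0.5 * n_obs * log(2 * pi) -
        0.5 * sum(r^2) / sc^2
      gk <- drop(crossprod(Phi_free, r)) / sc^2
      gs <- if (est_scale) -n_obs / sc + sum(r^2) / sc^3 else 0
      list(loglik = ll, grad_k = gk, grad_sigma = gs, grad_x0 = numeric(0),
           ok = is.finite(ll))
    }
  }

  eval_loglik <- function(k_free, sig, z0) {
    if (!latent) return(loglik_k(k_free, sig))
    k_full <- .full_k(model, k_free)
    ll <- 0; gk <- numeric(Df); gs <- 0; gx0 <- numeric(if (infer_z0) N else 0)
    for (d in model$datasets) {
      res <- crn_loglik_grad_cpp(lib$stoich, lib$rcount, k_full, free0,
                                 z0, infer_z0, d$times, d$replicates,
                                 d$map$A, sig, noise,
                                 model$solver$rtol, model$solver$atol,
                                 as.integer(model$solver$max_steps),
                                 isTRUE(model$solver$err_z_only))
      if (!res$ok) return(list(ok = FALSE))
      ll <- ll + res$loglik
      gk <- gk + res$grad_k
      gs <- gs + res$grad_sigma
      if (infer_z0) gx0 <- gx0 + res$grad_x0
    }
    list(loglik = ll, grad_k = gk, grad_sigma = gs, grad_x0 = gx0, ok = TRUE)
  }

  unpack <- function(theta) {
    u <- theta[seq_len(Df)]
    eta <- theta[Df + seq_len(Df)]
    gamma <- theta[2 * Df + 1]
    s <- theta[2 * Df + 2]
    lam <- exp(eta); cc <- exp(gamma); sig <- exp(s); z <- exp(u)
    q <- tau_s * cc * lam / sqrt(cc^2 + tau_s^2 * lam^2)
    k_free <- q * z
    z0 <- if (infer_z0) exp(theta[2 * Df + 2 + seq_len(N)]) else model$x0
    list(k_free = k_free, lambda = lam, c = cc, sigma = sig,
         z0 = if (infer_z0) z0 else NULL,
         .z = z, .q = q, .u = u, .eta = eta, .gamma = gamma, .s = s)
  }

  fn <- function(theta) {
    p <- unpack(theta)
    z <- p$.z; lam <- p$lambda; cc <- p$c; sig <- p$sigma; q <- p$.q
    z0 <- if (infer_z0) p$z0 else model$x0
    den <- cc^2 + tau_s^2 * lam^2
    lik <- eval_loglik(p$k_free, sig, z0)
    if (!isTRUE(lik$ok)) {
      return(list(lp = -Inf, grad = rep(0, dim)))
    }
    # unconstrained-scale prior (Jacobians included)
    lp_prior <- sum(log(2) - 0.5 * log(2 * pi) - z^2 / 2 + p$.u) +
      sum(log(2 / pi) - log1p(lam^2) + p$.eta) +
      (a * log(b) - lgamma(a) - a * p$.gamma - b / cc) +
      (log(2) - 0.5 * log(2 * pi) - log(s0) - sig^2 / (2 * s0^2) + p$.s)
    g_u <- lik$grad_k * p$k_free + (1 - z^2)
    dq_dlam <- tau_s * cc^3 / den^1.5
    g_eta <- lik$grad_k * z * dq_dlam * lam + (1 - 2 * lam^2 / (1 + lam^2))
    dq_dc <- tau_s^3 * lam^3 / den^1.5
    g_gamma <- sum(lik$grad_k * z * dq_dc * cc) + (-a + b / cc)
    g_s <- lik$grad_sigma * sig + (1 - sig^2 / s0^2)
    grad <- c(g_u, g_eta, g_gamma, g_s)
    lp <- lp_prior + lik$loglik
    if (infer_z0) {
      w <- log(z0); mu0 <- log(model$x0); sd0 <- 0.5
      lp <- lp + sum(-log(sd0) - 0.5 * log(2 * pi) - (w - mu0)^2 / (2 * sd0^2))
      g_w <- lik$grad_x0 * z0 - (w - mu0) / sd0^2
      grad <- c(grad, g_w)
    }
    if (!is.finite(lp)) return(list(lp = -Inf, grad = rep(0, dim)))
    list(lp = lp, grad = grad)
  }

  loglik_params <- function(params) {
    z0 <- if (infer_z0) params$z0 else model$x0
    lik <- eval_loglik(params$k_free, params$sigma, z0)
    if (!isTRUE(lik$ok)) return(-Inf)
    lik$loglik
  }

  natural <- function(params) {
    k <- params$k_free; lam <- params$lambda; cc <- params$c
    sig <- params$sigma
    z0 <- if (infer_z0) params$z0 else model$x0
    lp_prior <- log_prior(params, model)
    if (!is.finite(lp_prior)) {
      return(list(lp = -Inf, grad = NULL))
    }
    lik <- eval_loglik(k, sig, z0)
    if (!isTRUE(lik$ok)) return(list(lp = -Inf, grad = NULL))
    q <- regularized_scale(lam, tau, cc)
    den <- cc^2 + tau^2 * lam^2
    dq_dlam <- tau * cc^3 / den^1.5
    dq_dc <- tau^3 * lam^3 / den^1.5
    # d/dk of log prior: -k/q^2 ; d/dlam adds the scale dependence of q
    g_k <- lik$grad_k - k / q^2
    g_lam <- -2 * lam / (1 + lam^2) + (-1 / q + k^2 / q^3) * dq_dlam
    g_c <- sum((-1 / q + k^2 / q^3) * dq_dc) +
      (-(a + 1) / cc + b / cc^2)
    g_sig <- lik$grad_sigma - sig / s0^2
    grad <- list(k_free = g_k, lambda = g_lam, c = g_c, sigma = g_sig)
    lp <- lp_prior + lik$loglik
    if (infer_z0) {
      grad$z0 <- lik$grad_x0 +
        (-1 / z0 - (log(z0) - log(model$x0)) / (0.25 * z0))
    }
    list(lp = lp, grad = grad)
  }

  list(dim = dim, names = names, fn = fn, unpack = unpack,
       natural = natural, loglik_params = loglik_params,
       n_free = Df, infer_z0 = infer_z0, set_tau = set_tau)
}
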