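# Mean-field automatic-differentiation variational inference on the
# unconstrained scale: a diagonal Gaussian q(theta) = N(m, diag(exp(2*omega)))
# fitted by stochastic maximization of the ELBO with the reparameterization
# trick and Adam updates.

.advi_fit <- function(obj, init, iterations = 3000L, n_mc = 4L,
                      lr = 0.02, seed_offset = 0L) {
  dim <- length(init)
  m <- init
  omega <- rep(-2, dim)
  # Adam state
  am <- rep(0, 2 * dim); av <- rep(0, 2 * dim)
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  best_elbo <- -Inf; best_m <- m; best_omega <- omega
  elbo_trace <- numeric(0)
  window <- max(50L, iterations %/% 20L)
  acc <- 0; acc_n <- 0L
  for (it in seq_len(iterations)) {
    gm <- rep(0, dim); go <- rep(0, dim); elbo <- 0
    for (s in seq_len(n_mc)) {
      epsv <- rnorm(dim)
      th <- m + exp(omega) * epsv
      o <- obj(th)
      if (!is.finite(o$lp)) next
      elbo <- elbo + o$lp / n_mc
      gm <- gm + o$grad / n_mc
      go <- go + o$grad * epsv * exp(omega) / n_mc
    }
    # entropy of q: sum(omega) + const; d/domega = 1
    elbo <- elbo + sum(omega)
    go <- go + 1
    g <- c(gm, go)
    am <- b1 * am + (1 - b1) * g
    av <- b2 * av + (1 - b2) * g^2
    mhat <- am / (1 - b1^it); vhat <- av / (1 - b2^it)
    step <- lr * mhat / (sqrt(vhat) + eps_adam)
    m <- m + step[seq_len(dim)]
    omega <- omega + step[dim + seq_len(dim)]
    acc <- acc + elbo; acc_n <- acc_n + 1L
    if (acc_n == window) {
      mean_elbo <- acc / acc_n
      elbo_trace <- c(elbo_trace, mean_elbo)
      if (mean_elbo > best_elbo) {
        best_elbo <- mean_elbo; best_m <- m; best_omega <- omega
      }
      acc <- 0; acc_n <- 0L
    }
  }
  if (!is.finite(best_elbo)) {
    stop("variational optimization diverged (ELBO never finite)")
  }
  list(m = best_m, omega = best_omega, elbo = best_elbo,
       elbo_trace = elbo_trace)
}
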