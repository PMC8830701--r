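# No-U-Turn sampler with multinomial trajectory sampling, dual-averaging step
# size adaptation and windowed diagonal mass-matrix estimation. The target is
# supplied as a closure returning the log density and its gradient on an
# unconstrained parameter vector.

.logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

# one leapfrog step; obj(theta) -> list(lp, grad)
.leapfrog <- function(obj, th, p, grad, eps, inv_mass) {
  p1 <- p + 0.5 * eps * grad
  th2 <- th + eps * inv_mass * p1
  o2 <- obj(th2)
  p2 <- p1 + 0.5 * eps * o2$grad
  list(th = th2, p = p2, lp = o2$lp, grad = o2$grad)
}

.kinetic <- function(p, inv_mass) 0.5 * sum(p^2 * inv_mass)

# Recursive doubling; returns the subtree summary.
.build_tree <- function(obj, th, p, grad, dir, depth, eps, H0, inv_mass,
                        max_delta = 1000) {
  if (depth == 0L) {
    lf <- .leapfrog(obj, th, p, grad, dir * eps, inv_mass)
    H <- if (is.finite(lf$lp)) -lf$lp + .kinetic(lf$p, inv_mass) else Inf
    dH <- H - H0
    div <- !is.finite(dH) || dH > max_delta
    logw <- if (div) -Inf else -dH
    alpha <- if (!is.finite(dH)) 0 else min(1, exp(-dH))
    return(list(th_m = lf$th, p_m = lf$p, g_m = lf$grad,
                th_p = lf$th, p_p = lf$p, g_p = lf$grad,
                th_prop = lf$th, lp_prop = lf$lp, g_prop = lf$grad,
                logw = logw, sum_alpha = alpha, n_alpha = 1L,
                cont = !div, div = div, n_leap = 1L))
  }
  t1 <- .build_tree(obj, th, p, grad, dir, depth - 1L, eps, H0, inv_mass,
                    max_delta)
  if (!t1$cont) return(t1)
  t2 <- if (dir == 1L) {
    .build_tree(obj, t1$th_p, t1$p_p, t1$g_p, dir, depth - 1L, eps, H0,
                inv_mass, max_delta)
  } else {
    .build_tree(obj, t1$th_m, t1$p_m, t1$g_m, dir, depth - 1L, eps, H0,
                inv_mass, max_delta)
  }
  out <- t1
  if (dir == 1L) {
    out$th_p <- t2$th_p; out$p_p <- t2$p_p; out$g_p <- t2$g_p
  } else {
    out$th_m <- t2$th_m; out$p_m <- t2$p_m; out$g_m <- t2$g_m
  }
  logw <- .logsumexp2(t1$logw, t2$logw)
  if (is.finite(t2$logw) && runif(1) < exp(t2$logw - logw)) {
    out$th_prop <- t2$th_prop
    out$lp_prop <- t2$lp_prop
    out$g_prop <- t2$g_prop
  }
  out$logw <- logw
  out$sum_alpha <- t1$sum_alpha + t2$sum_alpha
  out$n_alpha <- t1$n_alpha + t2$n_alpha
  out$n_leap <- t1$n_leap + t2$n_leap
  dth <- out$th_p - out$th_m
  uturn <- sum(dth * (inv_mass * out$p_m)) < 0 ||
    sum(dth * (inv_mass * out$p_p)) < 0
  out$cont <- t2$cont && !uturn
  out$div <- t1$div || t2$div
  out
}

.find_epsilon <- function(obj, th, lp, grad, inv_mass) {
  eps <- 1
  p <- rnorm(length(th)) / sqrt(inv_mass)
  H0 <- -lp + .kinetic(p, inv_mass)
  lf <- .leapfrog(obj, th, p, grad, eps, inv_mass)
  H1 <- if (is.finite(lf$lp)) -lf$lp + .kinetic(lf$p, inv_mass) else Inf
  a <- if (is.finite(H1) && exp(H0 - H1) > 0.5) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    lf <- .leapfrog(obj, th, p, grad, eps, inv_mass)
    H1 <- if (is.finite(lf$lp)) -lf$lp + .kinetic(lf$p, inv_mass) else Inf
    ratio <- exp(H0 - H1)
    if (a == 1 && !(is.finite(H1) && ratio > 0.5)) break
    if (a == -1 && !(!is.finite(H1) || ratio < 0.5)) break
  }
  max(eps, 1e-10)
}

# Samples one chain. Returns draws (iterations x dim), lp vector, and sampler
# diagnostics. Warmup is discarded.
.nuts_chain <- function(obj, init, n_warmup, n_draws, control = list(),
                        hook = NULL) {
  ctl <- modifyList(list(max_treedepth = 10L, adapt_delta = 0.9,
                         max_delta = 1000, init_buffer = 75L,
                         term_buffer = 50L, base_window = 25L), control)
  dim <- length(init)
  th <- init
  o <- obj(th)
  if (!is.finite(o$lp)) stop("initial point has non-finite log density")
  inv_mass <- rep(1, dim)
  eps <- .find_epsilon(obj, th, o$lp, o$grad, inv_mass)
  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75
  # mass adaptation windows (Stan-like schedule)
  W <- n_warmup
  init_buf <- min(ctl$init_buffer, max(0L, floor(W * 0.15)))
  term_buf <- min(ctl$term_buffer, max(0L, floor(W * 0.1)))
  win_start <- init_buf + 1L
  win_size <- ctl$base_window
  win_end <- if (W > init_buf + term_buf) {
    min(win_start + win_size - 1L, W - term_buf)
  } else 0L
  acc_mean <- rep(0, dim); acc_m2 <- rep(0, dim); acc_n <- 0L

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, dim)
  lps <- numeric(n_draws)
  n_div <- 0L; n_maxdepth <- 0L; leapfrogs <- 0L
  accept_sum <- 0; accept_n <- 0L

  for (it in seq_len(total)) {
    if (!is.null(hook) && isTRUE(hook(it))) {
      o <- obj(th)  # the target changed under us; refresh lp and gradient
    }
    p0 <- rnorm(dim) / sqrt(inv_mass)
    H0 <- -o$lp + .kinetic(p0, inv_mass)
    tree <- list(th_m = th, p_m = p0, g_m = o$grad,
                 th_p = th, p_p = p0, g_p = o$grad,
                 th_prop = th, lp_prop = o$lp, g_prop = o$grad, logw = 0)
    sum_alpha <- 0; n_alpha <- 0L
    divergent <- FALSE
    depth <- 0L
    while (depth < ctl$max_treedepth) {
      dir <- if (runif(1) < 0.5) -1L else 1L
      sub <- if (dir == 1L) {
        .build_tree(obj, tree$th_p, tree$p_p, tree$g_p, dir, depth, eps, H0,
                    inv_mass, ctl$max_delta)
      } else {
        .build_tree(obj, tree$th_m, tree$p_m, tree$g_m, dir, depth, eps, H0,
                    inv_mass, ctl$max_delta)
      }
      leapfrogs <- leapfrogs + sub$n_leap
      sum_alpha <- sum_alpha + sub$sum_alpha
      n_alpha <- n_alpha + sub$n_alpha
      if (sub$div) divergent <- TRUE
      if (!sub$cont) break
      # multinomial: take the new subtree's proposal with prob w_new / w_total
      logw_tot <- .logsumexp2(tree$logw, sub$logw)
      if (is.finite(sub$logw) && runif(1) < exp(sub$logw - logw_tot)) {
        tree$th_prop <- sub$th_prop
        tree$lp_prop <- sub$lp_prop
        tree$g_prop <- sub$g_prop
      }
      tree$logw <- logw_tot
      if (dir == 1L) {
        tree$th_p <- sub$th_p; tree$p_p <- sub$p_p; tree$g_p <- sub$g_p
      } else {
        tree$th_m <- sub$th_m; tree$p_m <- sub$p_m; tree$g_m <- sub$g_m
      }
      dth <- tree$th_p - tree$th_m
      if (sum(dth * (inv_mass * tree$p_m)) < 0 ||
          sum(dth * (inv_mass * tree$p_p)) < 0) break
      depth <- depth + 1L
    }
    if (depth == ctl$max_treedepth) n_maxdepth <- n_maxdepth + 1L
    if (!identical(tree$th_prop, th)) {
      th <- tree$th_prop
      o <- list(lp = tree$lp_prop, grad = tree$g_prop)
    }
    alpha_mean <- if (n_alpha > 0L) sum_alpha / n_alpha else 0

    if (it <= n_warmup) {
      # dual averaging
      m <- it
      H_bar <- (1 - 1 / (m + t0)) * H_bar +
        (ctl$adapt_delta - alpha_mean) / (m + t0)
      log_eps <- mu - sqrt(m) / gamma_da * H_bar
      w <- m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      # mass window accumulation
      if (win_end > 0L && it >= win_start && it <= win_end) {
        acc_n <- acc_n + 1L
        delta <- th - acc_mean
        acc_mean <- acc_mean + delta / acc_n
        acc_m2 <- acc_m2 + delta * (th - acc_mean)
        if (it == win_end) {
          if (acc_n >= 5L) {
            v <- acc_m2 / (acc_n - 1L)
            inv_mass <- (acc_n / (acc_n + 5)) * v +
              1e-3 * (5 / (acc_n + 5))
            # re-initialize step size for the new metric
            eps <- .find_epsilon(obj, th, o$lp, o$grad, inv_mass)
            mu <- log(10 * eps); H_bar <- 0; log_eps_bar <- log(eps)
          }
          acc_mean[] <- 0; acc_m2[] <- 0; acc_n <- 0L
          win_size <- win_size * 2L
          win_start <- it + 1L
          win_end <- min(win_start + win_size - 1L, W - term_buf)
          if (W - term_buf - win_end < win_size) win_end <- W - term_buf
          if (win_end <= win_start) win_end <- 0L
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      j <- it - n_warmup
      draws[j, ] <- th
      lps[j] <- o$lp
      if (divergent) n_div <- n_div + 1L
      accept_sum <- accept_sum + alpha_mean
      accept_n <- accept_n + 1L
    }
  }
  list(draws = draws, lp = lps,
       diagnostics = list(divergences = n_div, max_treedepth_hits = n_maxdepth,
                          step_size = eps, mean_accept = accept_sum /
                            max(1L, accept_n), leapfrogs = leapfrogs,
                          inv_mass = inv_mass))
}
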