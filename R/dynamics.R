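# Mass-action dynamics: rate basis evaluation, the reaction-rate ODE
# right-hand side, and deterministic simulation.

#' Mass-action rate basis f(X)
#'
#' `f[d]` is the product of reactant concentrations of reaction `d`
#' (a doubled reactant contributes its square; an empty reactant side
#' contributes 1). The rate of reaction `d` is `k[d] * f[d]`: combinatorial
#' factors are absorbed into the rate constant.
#'
#' @param library a `crn_library`.
#' @param x nonnegative state vector of length N (species order of the
#'   library).
#' @return numeric vector of length D.
#' @export
propensity <- function(library, x) {
  x <- .check_state(library, x)
  rc <- library$rcount
  f <- rep(1, nrow(rc))
  for (n in seq_len(ncol(rc))) {
    cn <- rc[, n]
    pos <- cn > 0L
    if (any(pos)) f[pos] <- f[pos] * x[n]^cn[pos]
  }
  f
}

.check_state <- function(library, x) {
  x <- as.numeric(x)
  if (length(x) != length(library$species$names)) {
    stop("state vector length ", length(x), " does not match the ",
         length(library$species$names), " library species")
  }
  x
}

.check_rates <- function(library, k) {
  k <- as.numeric(k)
  if (length(k) != n_reactions(library)) {
    stop("rate vector length ", length(k), " does not match the ",
         n_reactions(library), " library reactions")
  }
  if (any(k < 0)) stop("rate constants must be nonnegative")
  k
}

#' Reaction-rate ODE right-hand side
#'
#' Evaluates `dX/dt = t(S) %*% (k * f(X))` for the given library, rate vector
#' and state; exactly linear in `k` for fixed `X`.
#'
#' @param library a `crn_library`.
#' @param k nonnegative rate vector of length D (zero encodes an absent
#'   reaction).
#' @param x state vector of length N.
#' @return named numeric vector of length N.
#' @export
reaction_rhs <- function(library, k, x) {
  k <- .check_rates(library, k)
  x <- .check_state(library, x)
  drop(t(library$stoich) %*% (k * propensity(library, x)))
}

#' Simulate the reaction-rate ODE
#'
#' Solves the deterministic mass-action initial-value problem at the requested
#' times. The default engine is an adaptive Dormand-Prince Runge-Kutta 4(5)
#' solver with forward-sensitivity support (the same integrator used inside
#' the latent-ODE likelihood); `engine = "lsoda"` switches to the implicit
#' stiff solver from deSolve for stiff rate combinations.
#'
#' @param library a `crn_library`.
#' @param k nonnegative rate vector of length D.
#' @param x0 nonnegative initial state of length N.
#' @param times strictly increasing output times; `times[1]` is the initial
#'   time.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param max_steps step cap before the solve is declared failed.
#' @param engine `"rk45"` (default) or `"lsoda"`.
#' @return an object of class `crn_trajectory`: list with `times` and
#'   `states` (length(times) x N matrix, columns named by species).
#' @export
simulate_network <- function(library, k, x0, times, rtol = 1e-6, atol = 1e-8,
                             max_steps = 100000L,
                             engine = c("rk45", "lsoda")) {
  engine <- match.arg(engine)
  k <- .check_rates(library, k)
  x0 <- .check_state(library, x0)
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (engine == "rk45") {
    res <- crn_simulate_cpp(library$stoich, library$rcount, k, x0, times,
                            rtol, atol, as.integer(max_steps))
    if (!res$ok) {
      stop("ODE solve failed (non-finite state or step-size collapse) at k = ",
           paste(signif(k, 4), collapse = ", "))
    }
    states <- res$states
  } else {
    rhs_fn <- function(t, y, parms) list(reaction_rhs(library, parms, y))
    sol <- deSolve::lsoda(y = x0, times = times, func = rhs_fn, parms = k,
                          rtol = rtol, atol = atol)
    states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  }
  if (any(!is.finite(states))) {
    stop("ODE solve produced non-finite states at k = ",
         paste(signif(k, 4), collapse = ", "))
  }
  colnames(states) <- library$species$names
  structure(list(times = times, states = states, species = library$species),
            class = "crn_trajectory")
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("Trajectory: ", length(x$times), " time points over [",
      x$times[1], ", ", x$times[length(x$times)], "], species: ",
      paste(colnames(x$states), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' First column `time`, one column per species.
#'
#' @param traj a `crn_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path file as written by [write_trajectory()].
#' @return a `crn_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  states <- as.matrix(df[, -1, drop = FALSE])
  structure(list(times = df$time, states = states,
                 species = species_set(colnames(states))),
            class = "crn_trajectory")
}
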