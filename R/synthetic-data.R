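# Synthetic measurement generation: observation maps, multiplicative
# log-normal noise, the two canonical benchmark fixtures, and dataset IO.

#' Create an observation map
#'
#' Links the latent species trajectory to what is measured: all species
#' (`"full"`), a subset of species (`"subset"`), or a single weighted sum
#' (`"linear_sum"`).
#'
#' @param kind `"full"`, `"subset"` or `"linear_sum"`.
#' @param species the [species_set()] the map refers to.
#' @param indices for `"subset"`: distinct species indices (or names) to
#'   observe.
#' @param weights for `"linear_sum"`: nonnegative weight per species with at
#'   least one positive entry.
#' @return an object of class `crn_obsmap` with the observable `labels` and
#'   the matrix representation `A` (observables x species) used by the
#'   likelihood: observed mean = `A %*% Z`.
#' @export
observation_map <- function(kind = c("full", "subset", "linear_sum"),
                            species, indices = NULL, weights = NULL) {
  kind <- match.arg(kind)
  N <- length(species$names)
  if (kind == "full") {
    A <- diag(1, N)
    labels <- species$names
  } else if (kind == "subset") {
    if (is.character(indices)) indices <- match(indices, species$names)
    indices <- as.integer(indices)
    if (length(indices) < 1L || anyNA(indices) || anyDuplicated(indices) ||
        any(indices < 1L | indices > N)) {
      stop("subset indices must be distinct valid species indices")
    }
    A <- matrix(0, length(indices), N)
    A[cbind(seq_along(indices), indices)] <- 1
    labels <- species$names[indices]
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != N || any(weights < 0) || !any(weights > 0)) {
      stop("linear_sum weights must be length-N, nonnegative, not all zero")
    }
    A <- matrix(weights, 1, N)
    labels <- paste(species$names[weights > 0], collapse = "+")
  }
  colnames(A) <- species$names
  rownames(A) <- labels
  structure(list(kind = kind, species = species, A = A, labels = labels,
                 indices = if (kind == "subset") indices else NULL,
                 weights = if (kind == "linear_sum") weights else NULL),
            class = "crn_obsmap")
}

#' Apply an observation map to a latent state matrix
#' @param map a `crn_obsmap`.
#' @param states matrix (times x N).
#' @return matrix (times x observables).
#' @export
apply_observation_map <- function(map, states) {
  out <- states %*% t(map$A)
  colnames(out) <- map$labels
  out
}

#' Perturb a trajectory with multiplicative log-normal noise
#'
#' Each observation is `state * exp(e)` with `e ~ Normal(0, sigma^2)`
#' independently, so `sigma` is the log-scale standard deviation and the
#' noise is median-unbiased.
#'
#' @param traj a `crn_trajectory` (or a positive matrix).
#' @param sigma log-scale standard deviation (> 0).
#' @param seed integer seed for reproducibility.
#' @return observation matrix of the same shape as the trajectory states.
#' @export
apply_lognormal_noise <- function(traj, sigma, seed) {
  states <- if (inherits(traj, "crn_trajectory")) traj$states else as.matrix(traj)
  if (sigma <= 0) stop("sigma must be positive")
  if (any(states <= 0)) {
    stop("all states must be strictly positive to apply log-normal noise")
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  states * exp(matrix(rnorm(length(states), 0, sigma), nrow(states)))
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Create a time-series dataset
#'
#' @param times strictly increasing observation times.
#' @param observations positive matrix (times x observables), or a list of
#'   `L` such matrices for replicate trajectories sharing the time grid.
#' @param map a `crn_obsmap` describing what the columns measure.
#' @return an object of class `crn_dataset` with `times`, `observations`
#'   (first replicate), `replicates` (list of all replicates) and `map`.
#' @export
time_series_dataset <- function(times, observations, map) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("observation times must be strictly increasing")
  }
  reps <- if (is.list(observations)) observations else list(observations)
  reps <- lapply(reps, as.matrix)
  shapes <- vapply(reps, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) stop("replicates must share one shape")
  for (m in reps) {
    if (nrow(m) != length(times)) {
      stop("observation rows (", nrow(m), ") must match times (",
           length(times), ")")
    }
    if (ncol(m) != length(map$labels)) {
      stop("observation columns must match the observation map")
    }
    if (any(m <= 0)) {
      bad <- which(m <= 0, arr.ind = TRUE)[1, ]
      stop("observations must be strictly positive (row ", bad[1],
           ", column ", bad[2], " is not)")
    }
  }
  reps <- lapply(reps, function(m) { colnames(m) <- map$labels; m })
  structure(list(times = times, observations = reps[[1]], replicates = reps,
                 map = map),
            class = "crn_dataset")
}

#' @export
print.crn_dataset <- function(x, ...) {
  cat("Time-series dataset: ", length(x$times), " times in [", x$times[1],
      ", ", x$times[length(x$times)], "], ", length(x$map$labels),
      " observable(s) [", paste(x$map$labels, collapse = ", "), "], ",
      length(x$replicates), " replicate(s)\n", sep = "")
  invisible(x)
}

#' Lotka-Volterra benchmark dataset
#'
#' Simulates the 3-reaction predator-prey system (prey birth `Y -> 2 Y` at
#' rate 1, predation `P + Y -> 2 P` at rate 0.01, predator death `P -> 0` at
#' rate 0.3) from initial state `(P, Y) = (50, 100)` over `[0, 15]`, samples
#' it every `dt` time units and perturbs with multiplicative log-normal
#' noise. The returned ground truth embeds the generating rates in the
#' 16-reaction `"lv-table1"` candidate library.
#'
#' @param dt observation interval (the benchmark uses 0.2, 1 and 2).
#' @param sigma log-normal noise scale (benchmark value 0.2); `sigma = 0`
#'   returns noiseless observations.
#' @param seed integer seed.
#' @param map optional `crn_obsmap` over species `(P, Y)`; default observes
#'   both species.
#' @return a list with `dataset` (`crn_dataset`), `library` (the 16-reaction
#'   candidate library), `true_k` (length-16 rate vector), `true_index`
#'   (indices of the generating reactions), `x0` and `trajectory` (the
#'   noiseless latent trajectory).
#' @export
make_lotka_volterra_dataset <- function(dt = 0.2, sigma = 0.2, seed = 1,
                                        map = NULL) {
  lib <- library_preset("lv-table1")
  true_k <- numeric(n_reactions(lib))
  true_index <- match(c("Y -> 2 Y", "P + Y -> 2 P", "P -> 0"),
                      reaction_strings(lib))
  true_k[true_index] <- c(1, 0.01, 0.3)
  x0 <- c(P = 50, Y = 100)
  times <- seq(0, 15, by = dt)
  traj <- simulate_network(lib, true_k, x0, times)
  if (is.null(map)) map <- observation_map("full", lib$species)
  latent_obs <- apply_observation_map(map, traj$states)
  obs <- if (sigma > 0) apply_lognormal_noise(latent_obs, sigma, seed) else latent_obs
  list(dataset = time_series_dataset(times, obs, map),
       library = lib, true_k = true_k, true_index = true_index, x0 = x0,
       trajectory = traj)
}

#' Prokaryotic auto-regulation benchmark dataset
#'
#' Simulates the 8-reaction gene auto-regulation network over species
#' `(g, P2, gP2, r, P)` with rates `(0.5, 1, 0.15, 1, 0.5, 0.5, 1.5, 0.3)`
#' from initial concentration 20 per species, sampled every `dt = 0.05` over
#' `[0, 0.5]`, with log-normal noise of scale 0.07. At these parameters `g`
#' and `P` decay rapidly, so the short, densely sampled window carries the
#' identifiable signal.
#'
#' @param seed integer seed.
#' @param dt observation interval (default 0.05).
#' @param sigma log-normal noise scale (default 0.07; 0 for noiseless).
#' @param map optional `crn_obsmap`; default observes all five species.
#' @return a list shaped like [make_lotka_volterra_dataset()]'s return value,
#'   with `library` the 8-reaction true network (use
#'   `library_preset("autoreg-reduced")` for a candidate set).
#' @export
make_autoregulation_dataset <- function(seed = 1, dt = 0.05, sigma = 0.07,
                                        map = NULL) {
  lib <- library_preset("autoreg-true")
  true_k <- c(0.5, 1, 0.15, 1, 0.5, 0.5, 1.5, 0.3)
  x0 <- setNames(rep(20, 5), lib$species$names)
  times <- seq(0, 0.5, by = dt)
  traj <- simulate_network(lib, true_k, x0, times)
  if (is.null(map)) map <- observation_map("full", lib$species)
  latent_obs <- apply_observation_map(map, traj$states)
  obs <- if (sigma > 0) apply_lognormal_noise(latent_obs, sigma, seed) else latent_obs
  list(dataset = time_series_dataset(times, obs, map),
       library = lib, true_k = true_k,
       true_index = seq_len(n_reactions(lib)), x0 = x0, trajectory = traj)
}

#' Write a dataset to CSV
#'
#' Columns: `time`, one column per observable; a `replicate` column is added
#' when the dataset holds more than one replicate.
#'
#' @param dataset a `crn_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  L <- length(dataset$replicates)
  dfs <- lapply(seq_len(L), function(l) {
    df <- data.frame(time = dataset$times, dataset$replicates[[l]],
                     check.names = FALSE)
    if (L > 1L) df$replicate <- l
    df
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' @param path file as written by [write_dataset()].
#' @param map a `crn_obsmap` whose labels match the observable columns.
#' @return a `crn_dataset`.
#' @export
read_dataset <- function(path, map) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  has_rep <- "replicate" %in% names(df)
  obs_cols <- setdiff(names(df), c("time", "replicate"))
  if (!identical(obs_cols, unname(map$labels))) {
    stop("observable columns (", paste(obs_cols, collapse = ", "),
         ") do not match the observation map labels (",
         paste(map$labels, collapse = ", "), ")")
  }
  if (has_rep) {
    reps <- split(df, df$replicate)
    times <- reps[[1]]$time
    if (!all(vapply(reps, function(d) identical(d$time, times), logical(1)))) {
      stop("replicates must share the same time grid")
    }
    mats <- lapply(reps, function(d) {
      m <- as.matrix(d[, obs_cols, drop = FALSE])
      rownames(m) <- NULL
      m
    })
    time_series_dataset(times, mats, map)
  } else {
    time_series_dataset(df$time, as.matrix(df[, obs_cols, drop = FALSE]), map)
  }
}
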