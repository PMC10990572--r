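#' Tracking accuracy
#'
#' `k / n`: the fraction of the `n` targets that appear among the
#' reported objects. Missing reports (e.g. dropped attended locations)
#' count against `k`.
#'
#' @param reported_objects integer indices of reported objects (may
#'   contain `NA` for missing reports).
#' @param target_set integer indices of the true targets.
#' @return a fraction in `[0, 1]`.
#' @export
tracking_accuracy <- function(reported_objects, target_set) {
  n <- length(target_set)
  if (n < 1) stop("need at least one target")
  k <- length(intersect(reported_objects[!is.na(reported_objects)],
                        target_set))
  k / n
}

#' Convert an empirical object speed to a simulation sigma
#'
#' Equates the average time an object takes to cross the MOT window in
#' the experiment and in the simulation. For constant-speed dynamics
#' `sigma = s * d / (eta * theta)`; for OU dynamics one simulation
#' update covers on average 1.8 sigma pixels along an axis, so
#' `sigma = 0.555 * s * d / (eta * theta)`.
#'
#' @param theta visual angle of the MOT window, degrees.
#' @param d empirical object speed, degrees per second.
#' @param s grid side, pixels (cells).
#' @param eta simulation update rate, Hz.
#' @param dynamics `"constant_speed"` or `"ou"`.
#' @return sigma in pixels per update.
#' @export
sim_sigma <- function(theta, d, s, eta,
                      dynamics = c("constant_speed", "ou")) {
  dynamics <- match.arg(dynamics)
  if (any(c(theta, d, s, eta) <= 0))
    stop("all conversion inputs must be positive")
  base <- s * d / (eta * theta)
  if (dynamics == "ou") 0.555 * base else base
}

#' Mean per-update displacement of unconstrained OU motion
#'
#' Calibration behind the OU speed conversion: simulates the
#' unconstrained OU recurrence from zero initial velocity and returns
#' the mean absolute per-axis displacement in units of sigma. For
#' `k = 0.0005`, `lambda = 0.9` the stationary velocity is normal with
#' sd close to `sigma / sqrt(1 - lambda^2)`, so the factor approaches
#' `sqrt(2 / (pi * (1 - lambda^2)))` (about 1.83): one update covers on
#' average about 1.8 sigma pixels along an axis, the factor inverted in
#' the OU speed conversion (0.555 = 1/1.8).
#'
#' @param sigma velocity-noise sd, pixels per update.
#' @param k,lambda OU parameters.
#' @param n_runs independent runs (objects).
#' @param n_updates updates per run; total sampled updates is
#'   `n_runs * n_updates`.
#' @param seed RNG seed.
#' @param euclidean also return the mean 2-D Euclidean step length
#'   (`pi / 2` times the per-axis mean for isotropic normal velocities).
#' @return the displacement factor (mean per-axis `|dx| / sigma`), with
#'   the Euclidean factor in attribute `"euclidean"` if requested.
#' @export
ou_displacement_factor <- function(sigma = 1, k = 5e-4, lambda = 0.9,
                                   n_runs = 100, n_updates = 1000,
                                   seed = 1L, euclidean = FALSE) {
  set.seed(seed)
  ax <- 0; eu <- 0
  arena <- c(4000, 4000)   # large enough that walls are never touched
  cfg <- mot_env("ou", sigma = sigma, k = k, lambda = lambda,
                 arena = arena, eta = 1, n_updates = 2,
                 n_targets = 1, n_objects = n_runs)
  pos <- matrix(stats::runif(2 * n_runs, 1900, 2100), n_runs, 2)
  state <- mot_state(pos, cfg)
  for (t in seq_len(n_updates)) {
    state <- ou_step(state, cfg)
    ax <- ax + mean(abs(state$velocities))
    eu <- eu + mean(sqrt(rowSums(state$velocities^2)))
  }
  out <- ax / n_updates / sigma
  if (euclidean) attr(out, "euclidean") <- eu / n_updates / sigma
  out
}

#' Experiment presets
#'
#' Tabulated environment and model configurations for the reproduced
#' experiments and for the package's two in-house designs. Object
#' counts that the source experiments leave open are recorded in
#' `meta$assumptions` and can be overridden via `n_targets` /
#' `n_objects`.
#'
#' @param name one of `"PS1988"`, `"AF2007"`, `"SV2016"`,
#'   `"FR2008-small"`, `"FR2008-large"`, `"Exp1"`, `"Exp2"`.
#' @param n_targets override the default target count.
#' @param n_objects override the default object count.
#' @param sigma override the default speed parameter.
#' @return `list(env = mot_env, params = mot_params, meta = list)`.
#' @export
mot_preset <- function(name, n_targets = NULL, n_objects = NULL,
                       sigma = NULL) {
  presets <- list(
    PS1988 = list(
      env = list(dynamics = "constrained_ou", sigma = 18, min_distance = 15,
                 arena = c(360, 360), eta = 2.5, n_updates = 25,
                 n_targets = 4, n_objects = 10),
      params = list(f_loc = 28, f_u = 10, c_e = Inf, nob = Inf),
      meta = list(sigma_range = c(18, 18),
                  assumptions = "n_targets 1..5 among 10 objects")),
    AF2007 = list(
      env = list(dynamics = "constant_speed", sigma = 3, min_distance = 80,
                 arena = c(720, 720), eta = 60, n_updates = 300,
                 n_targets = 4, n_objects = 8),
      params = list(f_loc = 30, f_u = 3, c_e = Inf, nob = 24),
      meta = list(sigma_range = c(0.1, 6),
                  assumptions = "equal targets and distractors (2n objects)")),
    SV2016 = list(
      env = list(dynamics = "ou", sigma = 3, min_distance = 0,
                 arena = c(720, 720), eta = 30, n_updates = 150,
                 n_targets = 4, n_objects = 12),
      params = list(f_loc = 30, f_u = 10, c_e = Inf, nob = 60),
      meta = list(sigma_range = c(1.3, 5.4),
                  assumptions = "n_targets 1..6 among 12 objects")),
    `FR2008-small` = list(
      env = list(dynamics = "constant_speed", sigma = 1.35,
                 min_distance = 24, arena = c(180, 180), eta = 90,
                 n_updates = 540, n_targets = 3, n_objects = 8),
      params = list(f_loc = 17, f_u = 10, c_e = Inf, nob = Inf),
      meta = list(sigma_range = c(0.45, 2.25),
                  assumptions = "n_targets 1..4 among 8 objects")),
    `FR2008-large` = list(
      env = list(dynamics = "constant_speed", sigma = 5.4,
                 min_distance = 96, arena = c(720, 720), eta = 90,
                 n_updates = 540, n_targets = 3, n_objects = 8),
      params = list(f_loc = 16, f_u = 10, c_e = Inf, nob = Inf),
      meta = list(sigma_range = c(1.8, 9),
                  assumptions = "n_targets 1..4 among 8 objects")),
    Exp1 = list(
      env = list(dynamics = "ou", sigma = 2, min_distance = 0,
                 arena = c(720, 720), eta = 60, n_updates = 300,
                 n_targets = 4, n_objects = 14),
      params = list(f_loc = 30, f_u = 10, c_e = Inf, nob = 52),
      meta = list(sigma_range = c(0.5, 6),
                  assumptions = paste(
                    "14 objects, n_targets 1..8, 5 s trials;",
                    "stimulus sigma 2.0 assumed (not reported)"))),
    Exp2 = list(
      env = list(dynamics = "shell_game", sigma = 3, min_distance = 120,
                 arena = c(1080, 720), eta = 60, n_updates = 300,
                 n_targets = 2, n_objects = 3),
      params = list(f_loc = 30, f_u = 10, c_e = Inf, nob = Inf),
      meta = list(sigma_range = c(0.5, 6),
                  assumptions = paste(
                    "object diameter 30 px; n_objects = n_targets + 1,",
                    "n_targets in 2..4"))))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  if (!is.null(n_targets)) p$env$n_targets <- n_targets
  if (!is.null(n_objects)) p$env$n_objects <- n_objects
  if (name == "AF2007" && is.null(n_objects) && !is.null(n_targets))
    p$env$n_objects <- 2L * n_targets
  if (name == "Exp2" && is.null(n_objects) && !is.null(n_targets))
    p$env$n_objects <- n_targets + 1L
  if (!is.null(sigma)) p$env$sigma <- sigma
  env <- do.call(mot_env, p$env)
  params <- do.call(mot_params, c(p$params,
                                  list(capacity = max(8L, env$n_targets))))
  list(env = env, params = params, meta = c(list(name = name), p$meta))
}

#' Run a block of independent trials
#'
#' Simulates `n_trials` seeded trials under one environment/parameter
#' configuration and summarises tracking and ID accuracy.
#'
#' @param env a [mot_env()].
#' @param params a [mot_params()].
#' @param n_trials number of trials.
#' @param seed base seed; trial seeds are derived deterministically.
#' @return an object of class `mot_block`: `summary` (a data frame of
#'   mean and SEM per metric) plus the raw `trials` list.
#' @export
run_block <- function(env, params, n_trials = 100, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    s_env <- derive_seed(seed, 2L * i)
    s_mod <- derive_seed(seed, 2L * i + 1L)
    traj <- simulate_trajectory(env, seed = s_env)
    if (is_rejected(traj))
      stop("trial generation rejected: ", traj$reason)
    trials[[i]] <- run_tracker(traj, params, seed = s_mod)
  }
  tr <- vapply(trials, `[[`, numeric(1), "tracking_accuracy")
  id <- vapply(trials, `[[`, numeric(1), "id_accuracy")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  structure(list(
    summary = data.frame(
      metric = c("tracking_accuracy", "id_accuracy"),
      mean = c(mean(tr), mean(id)),
      sem = c(sem(tr), sem(id)),
      n_trials = n_trials),
    trials = trials, env = env, params = params, seed = seed),
    class = "mot_block")
}

#' @export
print.mot_block <- function(x, ...) {
  cat(sprintf("MOT block: %d trials\n", x$summary$n_trials[1]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Accuracy as a function of target count
#'
#' Runs one [run_block()] per target count, everything else fixed.
#'
#' @inheritParams run_block
#' @param target_counts integer vector of target counts.
#' @param n_objects_fn function mapping a target count to the object
#'   count (default: keep `env$n_objects`).
#' @return a data frame with one row per target count: mean and SEM of
#'   tracking and ID accuracy.
#' @export
accuracy_by_targets <- function(env, params, target_counts,
                                n_trials = 100, seed = 1L,
                                n_objects_fn = NULL) {
  if (any(target_counts < 1)) stop("target counts must be >= 1")
  rows <- lapply(seq_along(target_counts), function(ti) {
    nt <- target_counts[ti]
    e <- env
    e$n_targets <- as.integer(nt)
    if (!is.null(n_objects_fn)) e$n_objects <- as.integer(n_objects_fn(nt))
    if (e$n_objects < e$n_targets) e$n_objects <- e$n_targets
    p <- params
    p$capacity <- max(p$capacity, e$n_targets)
    b <- run_block(validate_mot_env(e), p, n_trials,
                   seed = derive_seed(seed, ti))
    data.frame(n_targets = nt,
               tracking_mean = b$summary$mean[1],
               tracking_sem = b$summary$sem[1],
               id_mean = b$summary$mean[2],
               id_sem = b$summary$sem[2],
               n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' Maximum speed reaching a target accuracy
#'
#' Bisects over sigma for the largest speed at which mean tracking
#' accuracy still reaches `accuracy_target`, assuming accuracy is
#' non-increasing in sigma.
#'
#' @inheritParams run_block
#' @param accuracy_target required mean tracking accuracy.
#' @param bracket `c(lo, hi)` sigma search bracket.
#' @param tolerance stop when the bracket is narrower than this.
#' @param accuracy_fn optional `function(sigma) -> accuracy` standing in
#'   for the simulated observer (used for calibration checks).
#' @return `list(sigma =, accuracy =, status =)`; `status` is
#'   `"ok"`, `"at_upper_bracket"`, or `"below_bracket"` when even the
#'   slowest speed misses the target.
#' @export
speed_threshold <- function(env, params, accuracy_target = 0.94,
                            bracket = c(0.1, 6), n_trials = 100,
                            tolerance = 0.1, seed = 1L,
                            accuracy_fn = NULL) {
  if (is.null(accuracy_fn)) {
    accuracy_fn <- function(sig) {
      e <- env; e$sigma <- sig
      b <- run_block(e, params, n_trials, seed = seed)
      b$summary$mean[1]
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  acc_hi <- accuracy_fn(hi)
  if (acc_hi >= accuracy_target)
    return(list(sigma = hi, accuracy = acc_hi, status = "at_upper_bracket"))
  acc_lo <- accuracy_fn(lo)
  if (acc_lo < accuracy_target)
    return(list(sigma = lo, accuracy = acc_lo, status = "below_bracket"))
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    acc_mid <- accuracy_fn(mid)
    if (acc_mid >= accuracy_target) {
      lo <- mid; acc_lo <- acc_mid
    } else {
      hi <- mid
    }
  }
  list(sigma = lo, accuracy = acc_lo, status = "ok")
}

#' Adaptive staircase for speed calibration
#'
#' The calibration rule: sigma starts at 1.0 and lives on a 0.5 lattice
#' in `[0.5, 6.0]`. After a fully correct trial the next sigma is the
#' same, one step up, or one step down with probability 1/3 each
#' (clamped at the bounds); after any error sigma resets to 1.0.
#' Calibration converges once the last five trials are all correct with
#' a sigma range of at most 0.5.
#'
#' @return `staircase_state()`: an empty state with the standard bounds.
#' @export
staircase_state <- function() {
  structure(list(sigma_history = numeric(0), correct_history = logical(0),
                 sigma_0 = 1.0, sigma_min = 0.5, sigma_max = 6.0,
                 step = 0.5),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state a `staircase_state`.
#' @param last_trial_correct was the most recent trial fully correct?
#' @return `staircase_next()`: the sigma for the next trial.
#' @export
staircase_next <- function(state, last_trial_correct) {
  if (!last_trial_correct) return(state$sigma_0)
  cur <- if (length(state$sigma_history) == 0) state$sigma_0 else
    state$sigma_history[length(state$sigma_history)]
  prop <- cur + sample(c(-state$step, 0, state$step), 1L)
  min(max(prop, state$sigma_min), state$sigma_max)
}

#' @rdname staircase_state
#' @param sigma the sigma used on the trial being recorded.
#' @param correct whether that trial was fully correct.
#' @return `staircase_push()`: the updated state.
#' @export
staircase_push <- function(state, sigma, correct) {
  if (sigma < state$sigma_min || sigma > state$sigma_max ||
      abs(sigma / state$step - round(sigma / state$step)) > 1e-9)
    stop("sigma off the staircase lattice")
  state$sigma_history <- c(state$sigma_history, sigma)
  state$correct_history <- c(state$correct_history, correct)
  state
}

#' @rdname staircase_state
#' @return `staircase_converged()`: `TRUE` once the last 5 trials are
#'   all correct and their sigma values span at most 0.5.
#' @export
staircase_converged <- function(state) {
  h <- length(state$correct_history)
  if (h < 5) return(FALSE)
  last5 <- seq(h - 4, h)
  all(state$correct_history[last5]) &&
    diff(range(state$sigma_history[last5])) <= state$step + 1e-9
}

#' @rdname staircase_state
#' @param env a [mot_env()]; its sigma is driven by the staircase.
#' @param params a [mot_params()].
#' @param seed base seed.
#' @param max_trials give up after this many trials.
#' @return `run_staircase()`: the final state, with attribute
#'   `"converged"` and the calibrated sigma (mean of the last five) in
#'   attribute `"sigma_calibrated"` when converged.
#' @export
run_staircase <- function(env, params, seed = 1L, max_trials = 60L) {
  set.seed(derive_seed(seed, 0L))
  state <- staircase_state()
  sigma <- state$sigma_0
  for (t in seq_len(max_trials)) {
    e <- env; e$sigma <- sigma
    traj <- simulate_trajectory(e, seed = derive_seed(seed, 2L * t))
    if (is_rejected(traj)) stop("trial generation rejected: ", traj$reason)
    res <- run_tracker(traj, params, seed = derive_seed(seed, 2L * t + 1L))
    correct <- res$k == res$n
    state <- staircase_push(state, sigma, correct)
    if (staircase_converged(state)) break
    sigma <- staircase_next(state, correct)
  }
  conv <- staircase_converged(state)
  attr(state, "converged") <- conv
  if (conv) {
    h <- length(state$sigma_history)
    attr(state, "sigma_calibrated") <- mean(state$sigma_history[(h - 4):h])
  }
  state
}

#' Grid-search parameter fit
#'
#' Exhaustive search over `f_loc` and `nob` (and optionally `f_corr`)
#' minimising the mean squared error between the model's
#' accuracy-vs-target-count curve and a reference curve. Ties break to
#' the smaller `f_loc`, then the smaller `nob`. `r2` is
#' `1 - SS_res / SS_tot` about the reference mean (it can be negative,
#' and is reported as computed).
#'
#' @inheritParams run_block
#' @param reference data frame with columns `n_targets` and `accuracy`.
#' @param f_loc_values,nob_values,f_corr_values grids to search;
#'   `f_corr_values = NULL` fits tracking accuracy only.
#' @param metric which model curve to compare: `"tracking"` or `"id"`.
#' @return an object of class `mot_fit`: `best_params`, `mse`, `r2`,
#'   and the full search `table`.
#' @export
grid_fit <- function(reference, env, params, f_loc_values, nob_values,
                     f_corr_values = NULL, n_trials = 50, seed = 1L,
                     metric = c("tracking", "id")) {
  metric <- match.arg(metric)
  if (length(f_loc_values) == 0 || length(nob_values) == 0)
    stop("empty parameter grid")
  if (!all(c("n_targets", "accuracy") %in% names(reference)))
    stop("reference must have columns n_targets and accuracy")
  fc <- if (is.null(f_corr_values)) NA else f_corr_values
  grid <- expand.grid(f_loc = f_loc_values, nob = nob_values, f_corr = fc)
  grid <- grid[order(grid$f_loc, grid$nob, grid$f_corr), , drop = FALSE]
  ref <- reference[order(reference$n_targets), ]
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- params
    p$f_loc <- grid$f_loc[g]
    p$nob <- grid$nob[g]
    if (!is.na(grid$f_corr[g])) p$f_corr <- grid$f_corr[g]
    curve <- accuracy_by_targets(env, p, ref$n_targets,
                                 n_trials = n_trials, seed = seed)
    model <- if (metric == "tracking") curve$tracking_mean else
      curve$id_mean
    data.frame(f_loc = grid$f_loc[g], nob = grid$nob[g],
               f_corr = grid$f_corr[g],
               mse = mean((model - ref$accuracy)^2),
               ss_res = sum((model - ref$accuracy)^2))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$mse)   # grid pre-sorted: ties go to smaller f_loc
  ss_tot <- sum((ref$accuracy - mean(ref$accuracy))^2)
  r2 <- if (ss_tot == 0) -Inf else 1 - tab$ss_res[best] / ss_tot
  structure(list(
    best_params = list(f_loc = tab$f_loc[best], nob = tab$nob[best],
                       f_corr = tab$f_corr[best]),
    mse = tab$mse[best], r2 = r2, table = tab),
    class = "mot_fit")
}

#' @export
print.mot_fit <- function(x, ...) {
  cat(sprintf("MOT grid fit: f_loc = %g, nob = %g%s; MSE = %.3g, r2 = %.3f\n",
              x$best_params$f_loc, x$best_params$nob,
              if (is.na(x$best_params$f_corr)) "" else
                sprintf(", f_corr = %g", x$best_params$f_corr),
              x$mse, x$r2))
  invisible(x)
}
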