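#' Shell-game trial generator
#'
#' Generates a trial whose motion mimics a magician's shell game: the
#' objects sit on a ring of equally spaced stations about the arena
#' centre, and in each phase one randomly chosen pair of adjacent
#' stations exchanges its occupants along a half-circle arc about the
#' pair midpoint while the remaining objects hold still. The spatial
#' sort order of the objects therefore changes repeatedly while every
#' pairwise separation stays at or above `min_distance` by construction
#' (the ring radius solves the clearance inequality; the guarantee is
#' still audited frame by frame).
#'
#' A candidate trial is accepted only if (i) its minimum pairwise
#' distance over all frames is at least `min_distance`, and (ii) the
#' screening tracker -- the model with `f_corr = 0` -- labels it with
#' less than 100% ID accuracy, so the trial can actually dissociate
#' identification from tracking. Candidates are drawn until one passes
#' or the budget is exhausted.
#'
#' @param config a [mot_env()] with `dynamics = "shell_game"` and
#'   `n_objects = n_targets + 1`; a zero `min_distance` defaults to
#'   120 px. Arc speed is set so moving objects travel `sigma` pixels
#'   per update.
#' @param screening_params [mot_params()] for the screening tracker
#'   (default: `f_loc` 30 Hz, `f_u` 10 Hz, `c_e = Inf`, `nob = Inf`,
#'   `f_corr = 0`).
#' @param seed trial seed.
#' @param labels optional target labels.
#' @param budget candidate trajectories to try before giving up.
#' @return a `mot_trajectory`, or an object of class `mot_rejection`
#'   (with a `reason` field naming the binding constraint) if no
#'   candidate satisfies all constraints within the budget.
#' @export
shell_game_trial <- function(config, screening_params = NULL, seed = 1L,
                             labels = NULL, budget = 1000L) {
  validate_mot_env(config)
  if (config$dynamics != "shell_game")
    stop("invalid config: shell_game_trial requires shell_game dynamics")
  n <- config$n_objects
  if (n != config$n_targets + 1L)
    stop("invalid config: shell game uses n_objects = n_targets + 1")
  md <- if (config$min_distance > 0) config$min_distance else 120
  if (config$sigma <= 0)
    return(reject("zero motion: screening heuristic would label perfectly"))
  if (is.null(screening_params))
    screening_params <- mot_params(f_loc = 30, f_u = 10, c_e = Inf,
                                   nob = Inf, f_corr = 0,
                                   capacity = config$n_targets)

  geom <- shell_ring_geometry(n, md, config$arena)
  if (is.null(geom))
    return(reject(sprintf(
      "arena %g x %g too small for %d objects at separation %g",
      config$arena[1], config$arena[2], n, md)))

  last_reason <- "budget exhausted"
  for (cand in seq_len(budget)) {
    set.seed(derive_seed(seed, cand))
    frames <- shell_candidate_frames(config, geom)
    traj <- new_trajectory(frames, config, seed, labels)
    if (min_pairwise_distance(traj) < md) {
      last_reason <- "min_distance violated"   # should not occur
      next
    }
    if (screen_id_errors(traj, screening_params,
                         derive_seed(seed, budget + cand)))
      return(traj)
    last_reason <- "screening tracker labelled the trial perfectly"
  }
  reject(last_reason)
}

reject <- function(reason) {
  structure(list(reason = reason), class = "mot_rejection")
}

#' @export
print.mot_rejection <- function(x, ...) {
  cat("shell-game generation rejected:", x$reason, "\n")
  invisible(x)
}

#' @rdname shell_game_trial
#' @param x object to test.
#' @export
is_rejected <- function(x) inherits(x, "mot_rejection")

# TRUE when the screening tracker makes at least one ID error
screen_id_errors <- function(traj, screening_params, seed) {
  res <- run_tracker(traj, screening_params, seed = seed)
  res$id_accuracy < 1
}

# ring radius and station layout satisfying the clearance inequality:
# rotating an adjacent-station pair sweeps a circle of radius chord/2
# about the pair midpoint; every other station must stay min_distance
# clear of that circle, and the swept reach must fit inside the arena.
shell_ring_geometry <- function(n, md, arena, margin = 10) {
  half_ang <- pi / n
  chord_f <- 2 * sin(half_ang)              # chord / R
  if (n >= 3) {
    ang <- 2 * pi * (seq_len(n) - 1) / n    # stations; pair = (1, 2)
    mid_r <- cos(half_ang)                  # |midpoint| / R
    mid_a <- half_ang
    clear_f <- min(vapply(3:n, function(j) {
      sqrt(1 + mid_r^2 - 2 * mid_r * cos(ang[j] - mid_a))
    }, numeric(1))) - chord_f / 2
  } else {
    clear_f <- Inf                          # n = 2: no third object
  }
  R <- 1.1 * max(md / chord_f, md / clear_f)
  reach <- R * (cos(half_ang) + sin(half_ang))
  if (reach > min(arena) / 2 - margin) return(NULL)
  list(R = R, chord = R * chord_f, n = n)
}

shell_candidate_frames <- function(config, geom) {
  n <- config$n_objects
  nf <- config$n_updates
  centre <- config$arena / 2
  R <- geom$R
  ang0 <- stats::runif(1, 0, 2 * pi)
  station_ang <- ang0 + 2 * pi * (seq_len(n) - 1) / n
  station_pos <- cbind(centre[1] + R * cos(station_ang),
                       centre[2] + R * sin(station_ang))
  station_of <- sample.int(n)               # station index per object
  frames <- array(NA_real_, c(nf, n, 2))
  frames[1, , ] <- station_pos[station_of, ]
  omega <- 2 * config$sigma / geom$chord    # rad/update along the arc
  f <- 1L
  while (f < nf) {
    s1 <- sample.int(n, 1L)
    s2 <- if (s1 == n) 1L else s1 + 1L
    i <- which(station_of == s1)
    j <- which(station_of == s2)
    A <- station_pos[s1, ]; B <- station_pos[s2, ]
    mid <- (A + B) / 2
    rad <- sqrt(sum((A - mid)^2))
    a0 <- atan2(A[2] - mid[2], A[1] - mid[1])
    dir <- sample(c(-1, 1), 1L)
    n_steps <- ceiling(pi / omega)
    completed <- FALSE
    for (s in seq_len(n_steps)) {
      if (f >= nf) break
      f <- f + 1L
      a <- a0 + dir * min(s * omega, pi)
      frames[f, , ] <- frames[f - 1L, , ]
      frames[f, i, ] <- mid + rad * c(cos(a), sin(a))
      frames[f, j, ] <- mid - rad * c(cos(a), sin(a))
      if (s * omega >= pi) { completed <- TRUE; break }
    }
    if (completed) {
      station_of[i] <- s2
      station_of[j] <- s1
    }
  }
  frames
}
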