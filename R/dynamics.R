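#' World state for stepwise simulation
#'
#' Holds the instantaneous kinematic state of all objects. OU regimes use
#' `vel`; the constant-speed regime uses `theta` (heading, radians) and
#' the scalar speed in `config$sigma`.
#'
#' @param positions n x 2 matrix of (x, y) pixel positions.
#' @param config a [mot_env()].
#' @param velocities n x 2 matrix of per-update velocities (OU regimes).
#' @param theta length-n heading angles in radians (constant speed).
#' @param time_index frame counter.
#' @return an object of class `mot_state`.
#' @export
mot_state <- function(positions, config, velocities = NULL, theta = NULL,
                      time_index = 1L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 2)
  if (is.null(theta)) theta <- rep(0, n)
  if (any(positions[, 1] < 0 | positions[, 1] >= config$arena[1] |
          positions[, 2] < 0 | positions[, 2] >= config$arena[2]))
    stop("positions must lie within the arena")
  structure(list(time_index = as.integer(time_index), positions = positions,
                 velocities = as.matrix(velocities), theta = as.numeric(theta),
                 config = config),
            class = "mot_state")
}

# reflect positions (and negate the matching velocity component /
# mirror headings) at the arena walls; arena is [0, w) x [0, h)
reflect_walls <- function(pos, vel = NULL, theta = NULL, arena) {
  eps <- 1e-9
  for (ax in 1:2) {
    hi <- arena[ax]
    for (rep_i in 1:4) {       # a step never exceeds a few arena widths
      low <- pos[, ax] < 0
      if (any(low)) {
        pos[low, ax] <- -pos[low, ax]
        if (!is.null(vel)) vel[low, ax] <- -vel[low, ax]
        if (!is.null(theta))
          theta[low] <- if (ax == 1) pi - theta[low] else -theta[low]
      }
      high <- pos[, ax] >= hi
      if (any(high)) {
        pos[high, ax] <- 2 * hi - pos[high, ax] - eps
        if (!is.null(vel)) vel[high, ax] <- -vel[high, ax]
        if (!is.null(theta))
          theta[high] <- if (ax == 1) pi - theta[high] else -theta[high]
      }
      if (!any(pos[, ax] < 0 | pos[, ax] >= hi)) break
    }
    pos[, ax] <- pmin(pmax(pos[, ax], 0), hi - eps)
  }
  list(pos = pos, vel = vel, theta = theta)
}

#' One Ornstein-Uhlenbeck update
#'
#' Advances every object by the discrete OU recurrence
#' `v_t = lambda * v_{t-1} - k * (x_{t-1} - centre) + w_t`,
#' `x_t = x_{t-1} + v_t`, with `w_t ~ N(0, sigma)` (sigma a standard
#' deviation) drawn independently per axis and object. The spring term
#' acts on positions measured relative to the arena centre, which keeps
#' objects in-window; walls reflect both position and velocity.
#'
#' Uses the ambient RNG stream; seed upstream for reproducibility.
#'
#' @param state a [mot_state()].
#' @param config a [mot_env()] with `dynamics` `"ou"` or `"constrained_ou"`.
#' @return the updated `mot_state`.
#' @export
ou_step <- function(state, config = state$config) {
  if (!config$dynamics %in% c("ou", "constrained_ou"))
    stop("invalid config: ou_step requires ou or constrained_ou dynamics")
  validate_mot_env(config)
  n <- nrow(state$positions)
  centre <- matrix(config$arena / 2, n, 2, byrow = TRUE)
  w <- matrix(stats::rnorm(2 * n, 0, config$sigma), n, 2)
  vel <- config$lambda * state$velocities -
    config$k * (state$positions - centre) + w
  pos <- state$positions + vel
  rf <- reflect_walls(pos, vel = vel, arena = config$arena)
  state$positions <- rf$pos
  state$velocities <- rf$vel
  state$time_index <- state$time_index + 1L
  state
}

#' One constrained Ornstein-Uhlenbeck update
#'
#' Velocities always follow the OU recurrence, but an object's position
#' update is applied only if, after the move, it remains at least
#' `config$min_distance` pixels from every other object; otherwise its
#' position is held for this frame (the velocity update is kept).
#' Acceptance is evaluated object-by-object in index order.
#'
#' @inheritParams ou_step
#' @return the updated `mot_state`.
#' @export
constrained_ou_step <- function(state, config = state$config) {
  if (config$dynamics != "constrained_ou")
    stop("invalid config: constrained_ou_step requires constrained_ou dynamics")
  md <- config$min_distance
  if (md > 0 && min_pairwise_dist_frame(state$positions) < md)
    stop("invalid config: initial configuration violates min_distance")
  n <- nrow(state$positions)
  centre <- matrix(config$arena / 2, n, 2, byrow = TRUE)
  w <- matrix(stats::rnorm(2 * n, 0, config$sigma), n, 2)
  vel <- config$lambda * state$velocities -
    config$k * (state$positions - centre) + w
  pos <- state$positions
  for (i in seq_len(n)) {
    prop <- pos[i, ] + vel[i, ]
    rf <- reflect_walls(matrix(prop, 1, 2), vel = matrix(vel[i, ], 1, 2),
                        arena = config$arena)
    prop <- rf$pos[1, ]
    ok <- TRUE
    if (md > 0 && n > 1) {
      d <- sqrt((pos[-i, 1] - prop[1])^2 + (pos[-i, 2] - prop[2])^2)
      ok <- all(d >= md)
    }
    if (ok) {
      pos[i, ] <- prop
      vel[i, ] <- rf$vel[1, ]
    }
  }
  state$positions <- pos
  state$velocities <- vel
  state$time_index <- state$time_index + 1L
  state
}

#' Net repulsion heading for one object
#'
#' Sums, component-wise, inverse-square-distance repulsion from every
#' other object and every wall lying within `min_distance` of the object
#' (walls enter at their perpendicular foot), and returns the heading of
#' the net repulsion vector via the two-argument arctangent.
#'
#' @param state a [mot_state()].
#' @param object_index which object (1-based).
#' @param min_distance interaction radius in pixels.
#' @return the repulsion heading in radians, or `NA_real_` when the net
#'   vector is exactly zero (perfectly balanced: the caller should keep
#'   the current heading).
#' @export
repulsion_direction <- function(state, object_index,
                                min_distance = state$config$min_distance) {
  pos <- state$positions
  p <- pos[object_index, ]
  rx <- 0; ry <- 0
  if (nrow(pos) > 1) {
    q <- pos[-object_index, , drop = FALSE]
    dx <- p[1] - q[, 1]; dy <- p[2] - q[, 2]
    d2 <- dx^2 + dy^2
    keep <- sqrt(d2) < min_distance & d2 > 0
    rx <- sum(dx[keep] / d2[keep])
    ry <- sum(dy[keep] / d2[keep])
  }
  arena <- state$config$arena
  # walls: left, right, bottom (y = 0), top, via perpendicular distance
  wd <- c(p[1], arena[1] - p[1], p[2], arena[2] - p[2])
  wvec <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (wi in 1:4) {
    if (wd[wi] < min_distance && wd[wi] > 0) {
      rx <- rx + wvec[wi, 1] / wd[wi]
      ry <- ry + wvec[wi, 2] / wd[wi]
    }
  }
  if (rx == 0 && ry == 0) return(NA_real_)
  atan2(ry, rx)
}

#' One constant-speed update
#'
#' Every object within `min_distance` of a neighbour or wall adopts the
#' net repulsion heading from [repulsion_direction()]; all objects then
#' advance exactly `config$sigma` pixels along their headings. Speed is
#' preserved exactly; an object that would leave the arena has its
#' heading mirrored at the wall.
#'
#' @inheritParams ou_step
#' @return the updated `mot_state`.
#' @export
constant_speed_step <- function(state, config = state$config) {
  if (config$dynamics != "constant_speed")
    stop("invalid config: constant_speed_step requires constant_speed dynamics")
  pos <- state$positions
  n <- nrow(pos)
  theta <- state$theta
  md <- config$min_distance
  if (md > 0) {
    for (i in seq_len(n)) {
      near_obj <- FALSE
      if (n > 1) {
        d <- sqrt((pos[-i, 1] - pos[i, 1])^2 + (pos[-i, 2] - pos[i, 2])^2)
        near_obj <- any(d < md)
      }
      near_wall <- min(pos[i, 1], config$arena[1] - pos[i, 1],
                       pos[i, 2], config$arena[2] - pos[i, 2]) < md
      if (near_obj || near_wall) {
        th <- repulsion_direction(state, i, md)
        if (!is.na(th)) theta[i] <- th
      }
    }
  }
  step <- config$sigma * cbind(cos(theta), sin(theta))
  rf <- reflect_walls(pos + step, theta = theta, arena = config$arena)
  state$positions <- rf$pos
  state$theta <- rf$theta
  state$time_index <- state$time_index + 1L
  state
}

# min pairwise distance within a single frame of positions
min_pairwise_dist_frame <- function(pos) {
  if (nrow(pos) < 2) return(Inf)
  min(stats::dist(pos))
}

#' Minimum pairwise object distance of a trajectory
#'
#' @param traj a [mot_trajectory] (see [simulate_trajectory()]).
#' @return the minimum, over all frames and object pairs, of the
#'   Euclidean distance in pixels.
#' @export
min_pairwise_distance <- function(traj) {
  stopifnot(inherits(traj, "mot_trajectory"))
  if (dim(traj$frames)[2] < 2)
    stop("invalid input: need at least 2 objects")
  min(vapply(seq_len(dim(traj$frames)[1]),
             function(f) min_pairwise_dist_frame(traj$frames[f, , ]),
             numeric(1)))
}

# rejection-sample n positions with pairwise separation >= min_distance
# and a small wall margin
init_positions <- function(config, margin = 1) {
  n <- config$n_objects
  w <- config$arena[1]; h <- config$arena[2]
  md <- config$min_distance
  for (attempt in 1:200) {
    pos <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try_i in 1:500) {
        p <- c(stats::runif(1, margin, w - margin),
               stats::runif(1, margin, h - margin))
        if (i == 1 || md == 0 ||
            all(sqrt((pos[seq_len(i - 1), 1] - p[1])^2 +
                     (pos[seq_len(i - 1), 2] - p[2])^2) >= md)) {
          pos[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("could not place ", n, " objects at separation ", md,
       " in a ", w, " x ", h, " arena")
}

#' Simulate a full trajectory
#'
#' Generates a seeded, bit-reproducible trial under the configured motion
#' regime. The first frame is the initial configuration; targets are
#' objects `1..n_targets` and are labelled `"1".."n"` unless `labels` is
#' given. Shell-game configurations are delegated to [shell_game_trial()].
#'
#' @param config a [mot_env()].
#' @param seed integer RNG seed for this trial.
#' @param labels optional character labels for the targets.
#' @return an object of class `mot_trajectory`: a list with `frames`
#'   (`n_updates x n_objects x 2` array of (x, y) positions), logical
#'   `target_mask`, `labels`, `config` and `seed`.
#' @export
simulate_trajectory <- function(config, seed = 1L, labels = NULL) {
  validate_mot_env(config)
  if (config$dynamics == "shell_game")
    return(shell_game_trial(config, seed = seed, labels = labels))
  set.seed(seed)
  n <- config$n_objects
  pos <- init_positions(config)
  state <- mot_state(pos, config,
                     theta = stats::runif(n, 0, 2 * pi))
  frames <- array(NA_real_, c(config$n_updates, n, 2))
  frames[1, , ] <- state$positions
  stepper <- switch(config$dynamics,
                    ou = ou_step,
                    constrained_ou = constrained_ou_step,
                    constant_speed = constant_speed_step)
  if (config$n_updates > 1) {
    for (f in 2:config$n_updates) {
      state <- stepper(state, config)
      frames[f, , ] <- state$positions
    }
  }
  new_trajectory(frames, config, seed, labels)
}

new_trajectory <- function(frames, config, seed, labels = NULL) {
  mask <- seq_len(config$n_objects) <= config$n_targets
  if (is.null(labels)) labels <- as.character(seq_len(config$n_targets))
  if (length(labels) != config$n_targets)
    stop("invalid input: need one label per target")
  structure(list(frames = frames, target_mask = mask, labels = labels,
                 config = config, seed = as.integer(seed)),
            class = "mot_trajectory")
}

#' @export
print.mot_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("MOT trajectory: %d frames, %d objects (%d targets), seed %d\n",
              d[1], d[2], sum(x$target_mask), x$seed))
  print(x$config)
  invisible(x)
}
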