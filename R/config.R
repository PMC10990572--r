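#' Environment (stimulus) configuration
#'
#' Describes the motion regime and display geometry of a simulated MOT
#' trial. Positions are measured in pixels of the retinotopic grid, with
#' the origin at the top-left corner of the arena; one grid cell equals
#' one pixel.
#'
#' @param dynamics one of `"constant_speed"`, `"ou"`, `"constrained_ou"`,
#'   `"shell_game"`.
#' @param sigma speed parameter, pixels per update. For constant-speed
#'   dynamics this is the (exact) per-update displacement of every object;
#'   for Ornstein-Uhlenbeck (OU) dynamics it is the standard deviation of
#'   the per-update velocity noise.
#' @param k OU spring constant pulling positions back towards the arena
#'   centre (dimensionless, default 0.0005).
#' @param lambda OU velocity inertia in `[0, 1]` (default 0.9).
#' @param min_distance minimum pairwise object separation in pixels;
#'   0 disables the constraint. Constant-speed dynamics use it as the
#'   repulsion radius, constrained OU as a hard separation constraint,
#'   shell-game dynamics as the guaranteed clearance.
#' @param arena `c(width, height)` of the arena in pixels.
#' @param eta environment update rate, Hz (updates per second).
#' @param n_updates total number of frames in a trial (the first frame is
#'   the initial configuration), so trial duration is `n_updates / eta`
#'   seconds.
#' @param n_targets number of targets.
#' @param n_objects total number of objects (`>= n_targets`).
#'
#' @return an object of class `mot_env` (a validated list).
#' @export
mot_env <- function(dynamics = c("ou", "constant_speed", "constrained_ou",
                                 "shell_game"),
                    sigma = 1, k = 5e-4, lambda = 0.9, min_distance = 0,
                    arena = c(720, 720), eta = 30, n_updates = 150,
                    n_targets = 4, n_objects = 8) {
  dynamics <- match.arg(dynamics)
  env <- structure(
    list(dynamics = dynamics, sigma = sigma, k = k, lambda = lambda,
         min_distance = min_distance, arena = as.numeric(arena), eta = eta,
         n_updates = as.integer(n_updates), n_targets = as.integer(n_targets),
         n_objects = as.integer(n_objects)),
    class = "mot_env")
  validate_mot_env(env)
}

#' @rdname mot_env
#' @param env an object to validate.
#' @export
validate_mot_env <- function(env) {
  stopifnot(inherits(env, "mot_env"))
  with(env, {
    if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
      stop("invalid config: sigma must be a non-negative scalar")
    if (k < 0) stop("invalid config: k must be >= 0")
    if (lambda < 0 || lambda > 1)
      stop("invalid config: lambda must lie in [0, 1]")
    if (min_distance < 0) stop("invalid config: min_distance must be >= 0")
    if (length(arena) != 2 || any(arena <= 0))
      stop("invalid config: arena must be positive (width, height)")
    if (eta <= 0) stop("invalid config: eta must be > 0")
    if (n_updates < 1) stop("invalid config: n_updates must be >= 1")
    if (n_targets < 1) stop("invalid config: n_targets must be >= 1")
    if (n_objects < n_targets)
      stop("invalid config: n_objects must be >= n_targets")
  })
  env
}

#' @export
print.mot_env <- function(x, ...) {
  cat(sprintf("MOT environment: %s dynamics\n", x$dynamics))
  cat(sprintf("  arena %g x %g px, %d updates @ %g Hz (%.2f s)\n",
              x$arena[1], x$arena[2], x$n_updates, x$eta,
              x$n_updates / x$eta))
  cat(sprintf("  sigma = %g px/update, min separation = %g px\n",
              x$sigma, x$min_distance))
  if (x$dynamics %in% c("ou", "constrained_ou"))
    cat(sprintf("  k = %g, lambda = %g\n", x$k, x$lambda))
  cat(sprintf("  %d targets among %d objects\n", x$n_targets, x$n_objects))
  invisible(x)
}

#' Tracker (observer) parameters
#'
#' @param f_loc total attention-update frequency in Hz, shared across all
#'   attended locations: the more targets, the less often each one is
#'   refreshed.
#' @param f_u frequency (Hz) at which the unitary process may switch which
#'   attended location it serves; the literature-motivated range is
#'   3--10 Hz (a 100--300 ms dwell).
#' @param c_e confusion exponent (non-negative; `Inf` selects the most
#'   confusable location deterministically, ties to the lowest index).
#' @param nob nearest-object bound: maximum Euclidean search radius, in
#'   cells, for re-acquiring an object; a location whose search fails is
#'   dropped. `Inf` searches the whole grid.
#' @param f_corr probability, per relocating attention update, that the
#'   identity sequence is re-synchronised with the new spatial order
#'   (`0` = never, `1` = always).
#' @param scheduler `"round_robin"` (cyclic location updates, the default)
#'   or `"crowding_priority"` (locations drawn by confusion ratio).
#' @param capacity maximum number of attended locations.
#'
#' @return an object of class `mot_params`.
#' @export
mot_params <- function(f_loc = 30, f_u = 10, c_e = Inf, nob = Inf,
                       f_corr = 0, scheduler = c("round_robin",
                                                 "crowding_priority"),
                       capacity = 8) {
  scheduler <- match.arg(scheduler)
  if (f_loc <= 0) stop("invalid config: f_loc must be > 0")
  if (f_u <= 0) stop("invalid config: f_u must be > 0")
  if (is.na(c_e) || c_e < 0) stop("invalid config: c_e must be >= 0")
  if (is.na(nob) || nob <= 0) stop("invalid config: nob must be > 0")
  if (f_corr < 0 || f_corr > 1)
    stop("invalid config: f_corr must lie in [0, 1]")
  if (capacity < 1) stop("invalid config: capacity must be >= 1")
  structure(list(f_loc = f_loc, f_u = f_u, c_e = c_e, nob = nob,
                 f_corr = f_corr, scheduler = scheduler,
                 capacity = as.integer(capacity)),
            class = "mot_params")
}

#' @export
print.mot_params <- function(x, ...) {
  cat("MOT tracker parameters:\n")
  cat(sprintf("  f_loc = %g Hz, f_u = %g Hz, c_e = %s, nob = %s\n",
              x$f_loc, x$f_u, format(x$c_e), format(x$nob)))
  cat(sprintf("  f_corr = %g, scheduler = %s, capacity = %d\n",
              x$f_corr, x$scheduler, x$capacity))
  invisible(x)
}

# derive a reproducible 32-bit sub-seed from a base seed and an index
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 9973) %% 2147483647)
}
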