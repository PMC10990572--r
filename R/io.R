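#' Write / read a trajectory file
#'
#' Line-delimited text: a JSON header (config, seed, target mask,
#' labels) followed by one record per frame, `frame x1 y1 x2 y2 ...`,
#' serialised at full double precision so a round trip is bit-exact.
#' The reader re-validates the trajectory invariants (frame count,
#' in-bounds positions, and the minimum-separation constraint for the
#' constrained regimes) and raises typed parse errors naming the
#' offending line.
#'
#' @param traj a `mot_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the `mot_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mot_trajectory"))
  cfg <- traj$config
  header <- jsonlite::toJSON(list(
    format = "motrack-trajectory", version = 1L,
    config = unclass(cfg), seed = traj$seed,
    target_mask = traj$target_mask, labels = traj$labels),
    auto_unbox = TRUE, digits = NA)
  nf <- dim(traj$frames)[1]
  lines <- vapply(seq_len(nf), function(f) {
    paste(c(f, sprintf("%.17g", t(matrix(traj$frames[f, , ], ncol = 2)))),
          collapse = " ")
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

parse_error <- function(msg, line = NA) {
  stop(errorCondition(
    if (is.na(line)) msg else sprintf("%s (line %d)", msg, line),
    class = c("motrack_parse_error", "error", "condition")))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) parse_error("empty trajectory file")
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e)
                       parse_error("malformed JSON header", 1))
  if (is.null(header$format) || header$format != "motrack-trajectory")
    parse_error("not a motrack trajectory file", 1)
  cfg <- do.call(mot_env, header$config[names(header$config) %in%
                                          names(formals(mot_env))])
  n <- cfg$n_objects
  nf_expected <- cfg$n_updates
  body <- lines[-1]
  if (length(body) != nf_expected)
    parse_error(sprintf("frame count %d does not match n_updates %d",
                        length(body), nf_expected), length(lines))
  frames <- array(NA_real_, c(nf_expected, n, 2))
  for (f in seq_len(nf_expected)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[f]),
                                                 "\\s+")[[1]]))
    if (length(vals) != 1 + 2 * n || any(is.na(vals)))
      parse_error(sprintf("expected %d numbers per frame record",
                          1 + 2 * n), f + 1)
    frames[f, , ] <- matrix(vals[-1], n, 2, byrow = TRUE)
  }
  if (any(frames[, , 1] < 0 | frames[, , 1] >= cfg$arena[1] |
          frames[, , 2] < 0 | frames[, , 2] >= cfg$arena[2]))
    parse_error("position outside arena")
  traj <- new_trajectory(frames, cfg, header$seed,
                         labels = header$labels)
  traj$target_mask <- as.logical(header$target_mask)
  if (cfg$min_distance > 0 &&
      cfg$dynamics %in% c("constrained_ou", "shell_game") &&
      min_pairwise_distance(traj) < cfg$min_distance)
    parse_error("min_distance invariant violated")
  traj
}

#' Deterministic test fixtures
#'
#' Tiny hand-constructed trajectories with known ground truth:
#' * `static`: nothing moves;
#' * `constant_velocity`: all objects drift uniformly;
#' * `swap_pair`: two objects exchange their spatial (x) order along
#'   parallel lanes, never closing below the lane separation;
#' * `crossing_pair`: two orthogonal paths crossing within a cell at
#'   the midpoint.
#'
#' @param kind fixture kind.
#' @param n_updates number of frames.
#' @param arena `c(width, height)` pixels.
#' @param separation lane separation for `swap_pair`, pixels.
#' @param speed drift in pixels per update.
#' @return a `mot_trajectory` with both objects marked as targets
#'   (except `static`, which has 3 objects, 2 of them targets).
#' @export
make_fixture <- function(kind = c("static", "constant_velocity",
                                  "swap_pair", "crossing_pair"),
                         n_updates = 10, arena = c(100, 100),
                         separation = 20, speed = 2) {
  kind <- match.arg(kind)
  nf <- as.integer(n_updates)
  build <- function(start, vel, n_targets) {
    n <- nrow(start)
    frames <- array(NA_real_, c(nf, n, 2))
    for (f in seq_len(nf))
      frames[f, , ] <- start + (f - 1) * vel
    cfg <- mot_env("constant_speed", sigma = sqrt(max(rowSums(vel^2))),
                   min_distance = 0, arena = arena, eta = 10,
                   n_updates = nf, n_targets = n_targets, n_objects = n)
    new_trajectory(frames, cfg, seed = 0L)
  }
  w <- arena[1]; h <- arena[2]
  switch(kind,
    static = build(rbind(c(0.2 * w, 0.3 * h), c(0.6 * w, 0.7 * h),
                         c(0.8 * w, 0.2 * h)),
                   matrix(0, 3, 2), n_targets = 2L),
    constant_velocity = build(rbind(c(0.1 * w, 0.2 * h),
                                    c(0.2 * w, 0.6 * h)),
                              matrix(rep(c(speed, 0), each = 2), 2, 2),
                              n_targets = 2L),
    swap_pair = {
      span <- speed * (nf - 1)
      y0 <- h / 2 - separation / 2
      build(rbind(c(0.2 * w, y0), c(0.2 * w + span, y0 + separation)),
            rbind(c(speed, 0), c(-speed, 0)), n_targets = 2L)
    },
    crossing_pair = {
      span <- speed * (nf - 1)
      cx <- w / 2; cy <- h / 2
      build(rbind(c(cx - span / 2, cy), c(cx, cy - span / 2)),
            rbind(c(speed, 0), c(0, speed)), n_targets = 2L)
    })
}

#' Read a key-value configuration file
#'
#' Plain-text configs: one `key value` (or `key = value`) pair per
#' line, `#` comments, `inf` accepted as a sentinel for `Inf`, and
#' two-element values (e.g. `arena 720 720`) returned as vectors.
#'
#' @param path file path.
#' @return a named list with numeric values where possible.
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(gsub("=", " ", ln), "\\s+")[[1]]
    key <- parts[1]
    vals <- parts[-1]
    num <- suppressWarnings(as.numeric(ifelse(tolower(vals) == "inf",
                                              "Inf", vals)))
    out[[key]] <- if (any(is.na(num))) paste(vals, collapse = " ") else num
  }
  out
}
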