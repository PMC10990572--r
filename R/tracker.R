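#' Initialise a tracker state
#'
#' Sets up the attended-location list on the targets' cells (the model
#' starts a trial knowing exactly where the targets are), an empty
#' capacity-two unitary buffer, the round-robin pointer and the identity
#' state.
#'
#' @param target_positions n x 2 matrix of (x, y) pixel positions of the
#'   targets at frame 1.
#' @param params a [mot_params()].
#' @param grid_size `c(rows, cols)` of the retinotopic grid.
#' @param n_objects total number of objects on the map (used by the
#'   confusion-ratio machinery).
#' @param labels target labels (default `"1".."n"`).
#' @return an object of class `mot_tracker`.
#' @export
init_tracker <- function(target_positions, params, grid_size, n_objects,
                         labels = NULL) {
  target_positions <- as.matrix(target_positions)
  m <- nrow(target_positions)
  if (params$capacity < m)
    stop("invalid config: capacity (", params$capacity,
         ") below number of targets (", m, ")")
  if (is.null(labels)) labels <- as.character(seq_len(m))
  attended <- pos_to_cells(target_positions)
  structure(list(
    attended = attended,               # m x 2, 0-based (row, col)
    origin_target = seq_len(m),        # which target each thread started on
    rr = 1L,                           # round-robin pointer
    unitary = list(u = NULL, v = NULL, locked = NA_integer_,
                   lock_time = -Inf),
    id = init_id_state(cells_to_xy(attended), labels, params$f_corr),
    params = params,
    grid_size = as.integer(grid_size),
    n_objects = as.integer(n_objects),
    n_initial = m,
    n_dropped = 0L,
    last_event = NULL),
    class = "mot_tracker")
}

# attended cells are (row, col) = (y, x); identity sorting wants (x, y)
cells_to_xy <- function(cells) {
  cells <- matrix(cells, ncol = 2)
  cbind(cells[, 2], cells[, 1])
}

#' Attention map of a tracker
#'
#' @param tracker a [init_tracker()] state.
#' @return a list with integer matrix `grid` (multiplicity of each cell
#'   in the attended list) and the attended cell list; the grid total
#'   always equals the number of live attended locations.
#' @export
attention_map <- function(tracker) {
  grid <- matrix(0L, tracker$grid_size[1], tracker$grid_size[2])
  att <- tracker$attended
  for (i in seq_len(nrow(att)))
    grid[att[i, 1] + 1L, att[i, 2] + 1L] <-
      grid[att[i, 1] + 1L, att[i, 2] + 1L] + 1L
  structure(list(grid = grid, attended_list = att,
                 grid_size = tracker$grid_size),
            class = "attention_map")
}

#' @export
print.mot_tracker <- function(x, ...) {
  cat(sprintf("MOT tracker: %d/%d attended locations live, %d dropped\n",
              nrow(x$attended), x$n_initial, x$n_dropped))
  cat(sprintf("  unitary lock: %s\n",
              if (is.na(x$unitary$locked)) "none" else x$unitary$locked))
  invisible(x)
}

# base (unexponentiated) confusion ratios d1/d2 for all attended
# locations; returns zeros when the map holds fewer than 2 objects.
# Distances to occupied cells only are needed, so the ratios are
# computed directly from the object cell list (one row per object,
# multiplicity implicit) rather than by ring scan.
base_confusion_ratios <- function(tracker, object_cells) {
  m <- nrow(tracker$attended)
  r <- numeric(m)
  if (tracker$n_objects < 2) return(r)
  for (i in seq_len(m)) {
    d <- sqrt((object_cells[, 1] - tracker$attended[i, 1])^2 +
              (object_cells[, 2] - tracker$attended[i, 2])^2)
    d12 <- sort.int(d, partial = 2)[1:2]
    r[i] <- if (d12[1] == 0) 0 else d12[1] / d12[2]
  }
  r
}

# occupied cells of a grid, one row per object (multiplicity expanded)
grid_object_cells <- function(grid) {
  occ <- which(grid > 0L, arr.ind = TRUE)
  cells <- occ[rep(seq_len(nrow(occ)), grid[occ]), , drop = FALSE]
  cells - 1L
}

# draw an index from ratios under exponent c_e; c_e = Inf is a
# deterministic argmax with lowest-index tie-break
draw_by_confusion <- function(ratios, c_e) {
  if (is.infinite(c_e)) return(which.max(ratios))
  p <- unitary_selection_probs(ratios^c_e)
  sample.int(length(p), 1L, prob = p)
}

#' (Re-)select the unitary lock
#'
#' The unitary process serves one attended location at a time and may
#' only switch threads every `1 / f_u` seconds. When eligible, the lock
#' is drawn according to the confusion ratios (most-confusable-first for
#' `c_e = Inf`). Switching threads discards the buffered locations;
#' re-selecting the incumbent retains them.
#'
#' @param tracker a [init_tracker()] state.
#' @param o an `object_map` (or bare integer grid) of current object
#'   locations.
#' @param now simulated time in seconds.
#' @param object_cells optional pre-computed m x 2 matrix of occupied
#'   cells (one row per object); derived from `o` when missing.
#' @return the updated tracker.
#' @export
select_unitary_lock <- function(tracker, o, now, object_cells = NULL) {
  u <- tracker$unitary
  m <- nrow(tracker$attended)
  if (m == 0) {
    tracker$unitary <- list(u = NULL, v = NULL, locked = NA_integer_,
                            lock_time = u$lock_time)
    return(tracker)
  }
  if (now - u$lock_time < 1 / tracker$params$f_u) return(tracker)
  if (is.null(object_cells))
    object_cells <- grid_object_cells(
      if (inherits(o, "object_map")) o$grid else o)
  ratios <- base_confusion_ratios(tracker, object_cells)
  pick <- draw_by_confusion(ratios, tracker$params$c_e)
  if (is.na(u$locked) || pick != u$locked) {
    tracker$unitary <- list(u = NULL, v = NULL, locked = pick,
                            lock_time = now)
  }
  tracker
}

#' Velocity extrapolation from the unitary buffer
#'
#' With the two most recent locations `u` (latest) and `v` (previous) of
#' the locked thread, the search for that thread starts at
#' `a_i + (u - v)`, clipped to the grid.
#'
#' @param u_buf list with components `u` and `v` (0-based cells).
#' @param a_i 0-based `c(row, col)` attended cell.
#' @param grid_size `c(rows, cols)`.
#' @return the extrapolated 0-based cell.
#' @export
unitary_extrapolate <- function(u_buf, a_i, grid_size) {
  if (is.null(u_buf$u) || is.null(u_buf$v))
    stop("unitary buffer incomplete: fall back to plain search")
  cell <- a_i + (u_buf$u - u_buf$v)
  c(min(max(cell[1], 0L), grid_size[1] - 1L),
    min(max(cell[2], 0L), grid_size[2] - 1L))
}

# remove thread i from the tracker (search failure beyond nob)
drop_thread <- function(tracker, i) {
  tracker$attended <- tracker$attended[-i, , drop = FALSE]
  tracker$origin_target <- tracker$origin_target[-i]
  tracker$id <- id_drop_thread(tracker$id, i)
  un <- tracker$unitary
  if (!is.na(un$locked)) {
    if (un$locked == i) {
      un$u <- NULL; un$v <- NULL; un$locked <- NA_integer_
    } else if (un$locked > i) {
      un$locked <- un$locked - 1L
    }
  }
  tracker$unitary <- un
  m <- nrow(tracker$attended)
  if (tracker$rr > i) tracker$rr <- tracker$rr - 1L
  if (m == 0 || tracker$rr > m) tracker$rr <- 1L
  tracker$n_dropped <- tracker$n_dropped + 1L
  tracker
}

#' One attention tick
#'
#' Exactly one attended location is chosen (round-robin by default, or
#' drawn by confusion ratio under the crowding-priority scheduler) and
#' refreshed against the current object map:
#' * if its cell is still occupied it is confirmed in place;
#' * otherwise a bounded nearest-object search relocates it, starting
#'   from the velocity-extrapolated cell when the location is the one
#'   served by the unitary process (full buffer), else from the stale
#'   location itself;
#' * if no object lies within `nob` of the search origin the location is
#'   dropped.
#'
#' A relocating tick shifts the unitary buffer when it serves the locked
#' thread, and triggers a correspondence update of the identity sequence
#' with probability `f_corr`.
#'
#' @inheritParams select_unitary_lock
#' @return the updated tracker; `tracker$last_event` records
#'   `list(type = "confirmed"|"relocated"|"dropped", index =)`.
#' @export
attention_tick <- function(tracker, o, now = 0, object_cells = NULL) {
  grid <- if (inherits(o, "object_map")) o$grid else o
  m <- nrow(tracker$attended)
  if (m == 0) stop("attended list is empty")
  i <- if (tracker$params$scheduler == "round_robin") {
    tracker$rr
  } else {
    if (is.null(object_cells)) object_cells <- grid_object_cells(grid)
    draw_by_confusion(base_confusion_ratios(tracker, object_cells),
                      tracker$params$c_e)
  }
  cell <- tracker$attended[i, ]
  un <- tracker$unitary
  is_lock <- !is.na(un$locked) && un$locked == i
  if (grid[cell[1] + 1L, cell[2] + 1L] > 0L) {
    tracker$last_event <- list(type = "confirmed", index = i)
  } else {
    start <- cell
    if (is_lock && !is.null(un$u) && !is.null(un$v))
      start <- unitary_extrapolate(un, cell, tracker$grid_size)
    res <- cpp_nearest_cells(grid, start[1], start[2], 1L,
                             tracker$params$nob)
    if (nrow(res$cells) == 0) {
      tracker <- drop_thread(tracker, i)
      tracker$last_event <- list(type = "dropped", index = i)
      return(tracker)
    }
    newc <- res$cells[1, ]
    tracker$attended[i, ] <- newc
    if (is_lock) {
      if (is.null(un$u)) un$u <- newc else { un$v <- un$u; un$u <- newc }
      tracker$unitary <- un
    }
    tracker$id <- correspondence_update(tracker$id, i,
                                        cells_to_xy(tracker$attended))
    tracker$last_event <- list(type = "relocated", index = i)
  }
  if (tracker$params$scheduler == "round_robin")
    tracker$rr <- i %% nrow(tracker$attended) + 1L
  tracker
}

# greedy ascending-distance matching of live threads to final objects;
# ties by thread index then object index; each object claimable once
claim_objects <- function(attended, object_cells) {
  m <- nrow(attended); n <- nrow(object_cells)
  if (m == 0) return(integer(0))
  pairs <- expand.grid(thread = seq_len(m), object = seq_len(n))
  d <- sqrt((attended[pairs$thread, 1] - object_cells[pairs$object, 1])^2 +
            (attended[pairs$thread, 2] - object_cells[pairs$object, 2])^2)
  ord <- order(d, pairs$thread, pairs$object)
  claimed <- rep(NA_integer_, m)
  taken <- logical(n)
  for (idx in ord) {
    t_i <- pairs$thread[idx]; o_i <- pairs$object[idx]
    if (is.na(claimed[t_i]) && !taken[o_i]) {
      claimed[t_i] <- o_i
      taken[o_i] <- TRUE
    }
  }
  claimed
}

#' Run the tracker over a full trajectory
#'
#' Advances the stimulus at `eta` Hz while dispensing attention ticks at
#' `f_loc` Hz through a fractional-tick accumulator (ticks are spread
#' evenly within each frame) and offering unitary re-locks at `f_u` Hz.
#' At the last frame each surviving attended location claims the nearest
#' object (greedy, ascending distance, each object once); `k` counts the
#' distinct targets claimed and `p` the claims that carry the correct
#' label under the sorted-sequence assignment.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param params a [mot_params()].
#' @param seed RNG seed for the model's stochastic choices.
#' @return an object of class `mot_trial_result` with `n`, `k`, `p`,
#'   `tracking_accuracy = k/n`, `id_accuracy = p/n`, `n_dropped`, the
#'   per-thread `claims` data frame, `seed` and a `params` echo.
#' @export
run_tracker <- function(traj, params, seed = 1L) {
  stopifnot(inherits(traj, "mot_trajectory"))
  cfg <- traj$config
  set.seed(seed)
  grid_size <- c(as.integer(ceiling(cfg$arena[2])),
                 as.integer(ceiling(cfg$arena[1])))
  frame_at <- function(f) matrix(traj$frames[f, , ], ncol = 2)
  tracker <- init_tracker(
    matrix(frame_at(1)[traj$target_mask, ], ncol = 2),
    params, grid_size, cfg$n_objects, labels = traj$labels)
  grid <- matrix(0L, grid_size[1], grid_size[2])
  cells_prev <- pos_to_cells(frame_at(1))
  cpp_shift_cells(grid, matrix(0L, 0, 2), cells_prev)
  eta <- cfg$eta
  acc <- 0
  for (f in seq_len(cfg$n_updates)) {
    if (f > 1) {
      cells_now <- pos_to_cells(frame_at(f))
      cpp_shift_cells(grid, cells_prev, cells_now)
      cells_prev <- cells_now
    }
    acc <- acc + params$f_loc / eta
    nticks <- floor(acc)
    acc <- acc - nticks
    if (nticks > 0 && nrow(tracker$attended) > 0) {
      t0 <- (f - 1) / eta
      for (j in seq_len(nticks)) {
        now <- t0 + (j - 1) / (nticks * eta)
        tracker <- select_unitary_lock(tracker, grid, now,
                                       object_cells = cells_prev)
        tracker <- attention_tick(tracker, grid, now,
                                  object_cells = cells_prev)
        if (nrow(tracker$attended) == 0) break
      }
    }
  }
  score_trial(tracker, traj, cells_prev, seed)
}

score_trial <- function(tracker, traj, final_cells, seed) {
  cfg <- traj$config
  n <- sum(traj$target_mask)
  m <- nrow(tracker$attended)
  claimed <- claim_objects(tracker$attended, final_cells)
  assigned <- if (m > 0) {
    final_id_assignment(tracker$id, cells_to_xy(tracker$attended))
  } else character(0)
  target_idx <- which(traj$target_mask)
  true_label_of <- function(obj) {
    pos <- match(obj, target_idx)
    if (is.na(pos)) NA_character_ else traj$labels[pos]
  }
  claims <- data.frame(
    thread = seq_len(m),
    origin_target = tracker$origin_target,
    claimed_object = claimed,
    assigned_label = assigned,
    true_label = vapply(claimed, function(o)
      if (is.na(o)) NA_character_ else
        (if (is.na(true_label_of(o))) NA_character_ else true_label_of(o)),
      character(1)),
    stringsAsFactors = FALSE)
  claims$tracked <- !is.na(claims$claimed_object) &
    claims$claimed_object %in% target_idx
  claims$labelled <- claims$tracked & !is.na(claims$true_label) &
    claims$assigned_label == claims$true_label
  k <- sum(claims$tracked)
  p <- sum(claims$labelled)
  structure(list(n = n, k = k, p = p,
                 tracking_accuracy = k / n, id_accuracy = p / n,
                 n_dropped = tracker$n_dropped, claims = claims,
                 seed = as.integer(seed), params = tracker$params),
            class = "mot_trial_result")
}

#' @export
print.mot_trial_result <- function(x, ...) {
  cat(sprintf(
    "MOT trial: %d/%d targets tracked (%.0f%%), %d/%d labelled (%.0f%%), %d dropped\n",
    x$k, x$n, 100 * x$tracking_accuracy, x$p, x$n, 100 * x$id_accuracy,
    x$n_dropped))
  invisible(x)
}
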