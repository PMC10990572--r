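#' Spatial sort order of locations
#'
#' The identity-maintenance sort rule: locations ordered by x ascending,
#' ties by y ascending, remaining ties by input index (stable).
#'
#' @param locations m x 2 matrix of (x, y) coordinates.
#' @return an integer permutation: `locations[sorted_order(locations), ]`
#'   is sorted.
#' @export
sorted_order <- function(locations) {
  locations <- matrix(locations, ncol = 2)
  order(locations[, 1], locations[, 2])
}

#' Initialise an identity-maintenance state
#'
#' Holds the explicitly recited sequence of target labels and the rank of
#' each attended thread within it. At trial start the attended locations
#' are the targets themselves, so the sequence is their labels in spatial
#' sort order.
#'
#' @param locations m x 2 matrix of (x, y) initial target locations.
#' @param labels character labels, one per target, in thread order.
#' @param f_corr probability in `[0, 1]` that a relocating attention
#'   update is followed by a correspondence update.
#' @return an object of class `id_state`: `id_sequence` (labels in
#'   believed spatial order), `ranks` (per-thread rank, a permutation),
#'   `f_corr`.
#' @export
init_id_state <- function(locations, labels, f_corr = 0) {
  locations <- matrix(locations, ncol = 2)
  if (nrow(locations) != length(labels))
    stop("invalid input: need one label per location")
  if (f_corr < 0 || f_corr > 1) stop("f_corr must lie in [0, 1]")
  perm <- sorted_order(locations)
  ranks <- integer(length(labels))
  ranks[perm] <- seq_along(labels)
  structure(list(id_sequence = as.character(labels)[perm], ranks = ranks,
                 f_corr = f_corr),
            class = "id_state")
}

# rank of thread i among all threads under the total order
# (x, y, thread index); locations are (x, y)
id_rank_of <- function(locations, i) {
  x <- locations[, 1]; y <- locations[, 2]
  before <- (x < x[i]) | (x == x[i] & y < y[i]) |
    (x == x[i] & y == y[i] & seq_along(x) < i)
  sum(before) + 1L
}

#' Correspondence update after a location update
#'
#' Called once per attention tick that relocated a thread. With
#' probability `f_corr` the moved thread's label is re-inserted at its
#' new sorted rank among the current attended locations (all ranks
#' recomputed); otherwise the mapping is left stale. The extremes
#' consume no randomness: `f_corr = 0` never updates, `f_corr = 1`
#' always does.
#'
#' @param state an [init_id_state()] object.
#' @param thread_index index of the thread that moved.
#' @param all_locations m x 2 matrix of (x, y) current attended
#'   locations, including the moved thread's new location.
#' @return the updated `id_state`.
#' @export
correspondence_update <- function(state, thread_index, all_locations) {
  m <- length(state$ranks)
  if (thread_index < 1 || thread_index > m)
    stop("thread_index out of range")
  do_update <- state$f_corr >= 1 ||
    (state$f_corr > 0 && stats::runif(1) < state$f_corr)
  if (!do_update) return(state)
  all_locations <- matrix(all_locations, ncol = 2)
  r_old <- state$ranks[thread_index]
  r_new <- id_rank_of(all_locations, thread_index)
  seq_wo <- state$id_sequence[-r_old]
  ranks <- state$ranks - (state$ranks > r_old)
  state$id_sequence <- append(seq_wo, state$id_sequence[r_old],
                              after = r_new - 1L)
  ranks <- ranks + (ranks >= r_new)
  ranks[thread_index] <- r_new
  state$ranks <- ranks
  state
}

# remove a dropped thread's label from the sequence and renumber ranks
id_drop_thread <- function(state, thread_index) {
  r <- state$ranks[thread_index]
  state$id_sequence <- state$id_sequence[-r]
  state$ranks <- state$ranks[-thread_index]
  state$ranks <- state$ranks - (state$ranks > r)
  state
}

#' Final label assignment
#'
#' At trial end the system sorts the surviving attended locations by the
#' maintenance sort rule and attaches the k-th label of the maintained
#' sequence to the k-th location in sorted order.
#'
#' @param state an `id_state` (already shrunk to surviving threads).
#' @param final_locations m x 2 matrix of (x, y) surviving attended
#'   locations, in thread order.
#' @return character vector of assigned labels, in thread order.
#' @export
final_id_assignment <- function(state, final_locations) {
  final_locations <- matrix(final_locations, ncol = 2)
  m <- nrow(final_locations)
  if (length(state$id_sequence) != m)
    stop("id sequence and locations disagree in length")
  if (m == 0) return(character(0))
  perm <- order(final_locations[, 1], final_locations[, 2], seq_len(m))
  assigned <- character(m)
  assigned[perm] <- state$id_sequence
  assigned
}

#' Identification accuracy
#'
#' `p / n`: the fraction of the `n` responses whose reported object is
#' the true bearer of the assigned label. Unassigned responses
#' (`NA`, e.g. a dropped thread) score incorrect.
#'
#' @param assigned character vector of assigned labels (may contain
#'   `NA`).
#' @param truth character vector of true labels, same length.
#' @return a fraction in `[0, 1]`.
#' @export
id_accuracy <- function(assigned, truth) {
  n <- length(truth)
  if (n < 1) stop("need n >= 1")
  sum(!is.na(assigned) & assigned == truth) / n
}
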