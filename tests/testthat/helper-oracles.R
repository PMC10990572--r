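# brute-force oracle for the expanding-ring grid search: scan every
# occupied cell, order by (Euclidean distance, Chebyshev shell, row,
# col) -- the documented tie-break -- and return the k-th entry with
# multiplicity
brute_nearest <- function(grid, origin, k = 1, nob = Inf) {
  occ <- which(grid > 0L, arr.ind = TRUE) - 1L
  if (nrow(occ) == 0) return(NULL)
  counts <- grid[occ + 1L]
  d <- sqrt((occ[, 1] - origin[1])^2 + (occ[, 2] - origin[2])^2)
  cheb <- pmax(abs(occ[, 1] - origin[1]), abs(occ[, 2] - origin[2]))
  keep <- d <= nob
  if (!any(keep)) return(NULL)
  occ <- occ[keep, , drop = FALSE]
  counts <- counts[keep]; d <- d[keep]; cheb <- cheb[keep]
  ord <- order(d, cheb, occ[, 1], occ[, 2])
  d <- rep(d[ord], counts[ord])
  rows <- rep(occ[ord, 1], counts[ord])
  cols <- rep(occ[ord, 2], counts[ord])
  if (length(d) < k) return(NULL)
  list(cell = unname(c(rows[k], cols[k])), dist = unname(d[k]))
}

# random sparse occupancy map plus a random origin
random_map <- function(nr = 30, nc = 30, n_objects = 6) {
  pos <- cbind(runif(n_objects, 0, nc), runif(n_objects, 0, nr))
  list(map = rasterize(pos, c(nr, nc)),
       origin = c(sample.int(nr, 1) - 1L, sample.int(nc, 1) - 1L))
}

# brute-force net inverse-square repulsion over objects and walls
brute_repulsion <- function(pos, i, min_distance, arena) {
  rx <- 0; ry <- 0
  for (j in seq_len(nrow(pos))) {
    if (j == i) next
    dx <- pos[i, 1] - pos[j, 1]; dy <- pos[i, 2] - pos[j, 2]
    d2 <- dx^2 + dy^2
    if (sqrt(d2) < min_distance && d2 > 0) {
      rx <- rx + dx / d2; ry <- ry + dy / d2
    }
  }
  wd <- c(pos[i, 1], arena[1] - pos[i, 1], pos[i, 2], arena[2] - pos[i, 2])
  wv <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (w in 1:4) if (wd[w] < min_distance && wd[w] > 0) {
    rx <- rx + wv[w, 1] / wd[w]; ry <- ry + wv[w, 2] / wd[w]
  }
  if (rx == 0 && ry == 0) return(NA_real_)
  atan2(ry, rx)
}

# small fast configurations used across tests
tiny_ou_env <- function(sigma = 2, n_targets = 3, n_objects = 8,
                        min_distance = 0,
                        dynamics = if (min_distance > 0) "constrained_ou"
                                   else "ou") {
  mot_env(dynamics, sigma = sigma, min_distance = min_distance,
          arena = c(200, 200), eta = 20, n_updates = 60,
          n_targets = n_targets, n_objects = n_objects)
}

tiny_params <- function(...) {
  defaults <- list(f_loc = 20, f_u = 10, c_e = Inf, nob = Inf,
                   f_corr = 0, capacity = 8)
  args <- utils::modifyList(defaults, list(...))
  do.call(mot_params, args)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) atan2(sin(a), cos(a))
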