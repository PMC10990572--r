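test_that("OU recurrence has the stated degenerate behaviours", {
  cfg <- mot_env("ou", sigma = 0, k = 0, lambda = 1, arena = c(100, 100),
                 eta = 10, n_updates = 10, n_targets = 1, n_objects = 2)
  st <- mot_state(rbind(c(20, 20), c(60, 60)), cfg,
                  velocities = rbind(c(1, 0), c(0, 0)))
  for (i in 1:10) st <- ou_step(st, cfg)
  # noise-free uniform motion: position advances (1, 0) per step
  expect_equal(st$positions[1, ], c(30, 20))
  expect_equal(st$velocities[1, ], c(1, 0))
  # zero noise, zero velocity, k = 0 is a fixed point
  expect_equal(st$positions[2, ], c(60, 60))

  expect_error(mot_env("ou", sigma = -1), "sigma")
})

test_that("OU velocity noise is N(0, sigma) with sigma a standard deviation", {
  set.seed(42)
  cfg <- mot_env("ou", sigma = 1.7, k = 0, lambda = 0, arena = c(4000, 4000),
                 eta = 10, n_updates = 2, n_targets = 1, n_objects = 50)
  st <- mot_state(matrix(runif(100, 1900, 2100), 50, 2), cfg)
  draws <- c()
  for (i in 1:200) {
    st <- ou_step(st, cfg)   # lambda = k = 0: velocity IS the draw
    draws <- c(draws, st$velocities)
  }
  gof <- ks.test(draws, "pnorm", 0, 1.7)
  expect_gt(gof$p.value, 0.001)
})

test_that("mean per-axis OU displacement approaches 1.8 sigma", {
  f <- ou_displacement_factor(sigma = 2, n_runs = 50, n_updates = 500,
                              seed = 3, euclidean = TRUE)
  expect_lt(abs(as.numeric(f) - 1.8), 0.1)
  # the 2-D Euclidean step is pi/2 times the mean per-axis one
  expect_lt(abs(attr(f, "euclidean") - (pi / 2) * as.numeric(f)), 0.05)
})

test_that("repulsion direction matches symmetry cases and the brute-force sum", {
  cfg <- mot_env("constant_speed", sigma = 1, min_distance = 30,
                 arena = c(200, 200), eta = 10, n_updates = 2,
                 n_targets = 1, n_objects = 3)
  # single neighbour along +x: repelled along -x
  st <- mot_state(rbind(c(100, 100), c(110, 100), c(100, 170)), cfg)
  expect_equal(repulsion_direction(st, 1, 30), pi)
  # mirror-symmetric neighbours: y components cancel
  st2 <- mot_state(rbind(c(100, 100), c(110, 105), c(110, 95)), cfg)
  expect_equal(abs(wrap_angle(repulsion_direction(st2, 1, 30))), pi)
  # random instances against an independent re-evaluation of the sum
  set.seed(7)
  for (rep_i in 1:50) {
    pos <- cbind(runif(4, 60, 140), runif(4, 60, 140))
    st3 <- mot_state(pos, cfg)
    got <- repulsion_direction(st3, 1, 40)
    want <- brute_repulsion(pos, 1, 40, cfg$arena)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(wrap_angle(got - want), 0, tolerance = 1e-12)
  }
})

test_that("repulsion direction is rotation-equivariant", {
  cfg <- mot_env("constant_speed", sigma = 1, min_distance = 25,
                 arena = c(400, 400), eta = 10, n_updates = 2,
                 n_targets = 1, n_objects = 4)
  centre <- cfg$arena / 2
  set.seed(11)
  for (rep_i in 1:30) {
    pos <- cbind(runif(4, 180, 220), runif(4, 180, 220))  # walls out of range
    phi <- runif(1, 0, 2 * pi)
    rot <- function(p) {
      sweep(sweep(p, 2, centre) %*%
              rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi))),
            2, centre, `+`)
    }
    a <- repulsion_direction(mot_state(pos, cfg), 1, 25)
    b <- repulsion_direction(mot_state(rot(pos), cfg), 1, 25)
    if (!is.na(a))
      expect_equal(wrap_angle(b - a - phi), 0, tolerance = 1e-9)
  }
})

test_that("constant-speed dynamics preserve speed exactly and repel head-on pairs", {
  cfg <- mot_env("constant_speed", sigma = 0.5, min_distance = 0,
                 arena = c(200, 200), eta = 10, n_updates = 2,
                 n_targets = 1, n_objects = 1)
  st <- mot_state(matrix(c(100, 100), 1), cfg, theta = 0.3)
  for (i in 1:100) {
    old <- st$positions
    st <- constant_speed_step(st, cfg)
    expect_equal(sqrt(sum((st$positions - old)^2)), cfg$sigma)
    expect_equal(st$theta, 0.3)  # isolated object: heading unchanged
  }

  cfg2 <- mot_env("constant_speed", sigma = 1, min_distance = 10,
                  arena = c(200, 200), eta = 10, n_updates = 2,
                  n_targets = 1, n_objects = 2)
  st2 <- mot_state(rbind(c(98, 100), c(102, 100)), cfg2,
                   theta = c(0, pi))  # approaching head-on, within range
  st2 <- constant_speed_step(st2, cfg2)
  expect_equal(wrap_angle(st2$theta[1] - pi), 0)
  expect_equal(wrap_angle(st2$theta[2]), 0)
})

test_that("constrained OU reduces to OU when the constraint is vacuous", {
  cfg <- mot_env("constrained_ou", sigma = 2, min_distance = 0,
                 arena = c(200, 200), eta = 10, n_updates = 2,
                 n_targets = 2, n_objects = 5)
  st <- mot_state(cbind(runif(5, 50, 150), runif(5, 50, 150)), cfg)
  set.seed(99); a <- ou_step(st, cfg)
  set.seed(99); b <- constrained_ou_step(st, cfg)
  expect_equal(a$positions, b$positions)
  expect_equal(a$velocities, b$velocities)
})

test_that("constrained OU holds positions but updates velocities on conflict", {
  cfg <- mot_env("constrained_ou", sigma = 0, min_distance = 50,
                 arena = c(400, 400), eta = 10, n_updates = 2,
                 n_targets = 1, n_objects = 2)
  st <- mot_state(rbind(c(100, 100), c(160, 100)), cfg,
                  velocities = rbind(c(50, 0), c(0, 0)))
  out <- constrained_ou_step(st, cfg)
  expect_equal(out$positions[1, ], c(100, 100))    # move rejected
  # velocity still follows the recurrence (sigma = 0 so no noise)
  expect_equal(out$velocities[1, 1],
               cfg$lambda * 50 - cfg$k * (100 - 200))
  # starting in violation is an invalid configuration
  st_bad <- mot_state(rbind(c(100, 100), c(120, 100)), cfg)
  expect_error(constrained_ou_step(st_bad, cfg), "min_distance")
})

test_that("constrained OU trajectories never violate the separation constraint", {
  cfg <- mot_env("constrained_ou", sigma = 3, min_distance = 15,
                 arena = c(360, 360), eta = 10, n_updates = 200,
                 n_targets = 4, n_objects = 10)
  traj <- simulate_trajectory(cfg, seed = 5)
  expect_gte(min_pairwise_distance(traj), 15)
})

test_that("min pairwise distance matches hand values and a brute-force loop", {
  frames <- array(0, c(1, 2, 2))
  frames[1, , ] <- rbind(c(0, 0), c(3, 4))
  cfg <- mot_env("ou", arena = c(10, 10), n_updates = 1, n_targets = 1,
                 n_objects = 2)
  traj <- structure(list(frames = frames, target_mask = c(TRUE, FALSE),
                         labels = "1", config = cfg, seed = 0L),
                    class = "mot_trajectory")
  expect_equal(min_pairwise_distance(traj), 5)

  traj2 <- simulate_trajectory(tiny_ou_env(), seed = 8)
  brute <- min(apply(traj2$frames, 1, function(fr) min(dist(fr))))
  expect_equal(min_pairwise_distance(traj2), brute)

  traj1 <- traj; traj1$frames <- traj1$frames[, 1, , drop = FALSE]
  expect_error(min_pairwise_distance(traj1), "2 objects")
})

test_that("seeded generation is bit-reproducible", {
  cfg <- tiny_ou_env()
  a <- simulate_trajectory(cfg, seed = 123)
  b <- simulate_trajectory(cfg, seed = 123)
  expect_identical(a$frames, b$frames)
  c <- simulate_trajectory(cfg, seed = 124)
  expect_false(identical(a$frames, c$frames))
})
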