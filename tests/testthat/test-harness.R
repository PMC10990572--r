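test_that("tracking accuracy is k over n with missing reports penalised", {
  expect_equal(tracking_accuracy(c(1, 2, 3, 9), 1:4), 0.75)
  expect_equal(tracking_accuracy(1:4, 1:4), 1)
  expect_equal(tracking_accuracy(rep(NA, 4), 1:4), 0)
  expect_equal(tracking_accuracy(integer(0), 1:4), 0)
  expect_error(tracking_accuracy(1, integer(0)), "target")
})

test_that("speed conversions follow the crossing-time equations", {
  expect_equal(sim_sigma(30, 15, 720, 60, "constant_speed"), 6)
  expect_equal(sim_sigma(30, 15, 720, 60, "ou"), 0.555 * 6)
  # linear in s and d, inverse in eta and theta
  set.seed(2)
  for (i in 1:20) {
    th <- runif(1, 5, 80); d <- runif(1, 0.5, 20)
    s <- runif(1, 100, 1000); eta <- runif(1, 10, 90)
    base <- sim_sigma(th, d, s, eta, "constant_speed")
    expect_equal(sim_sigma(th, d, 2 * s, eta, "constant_speed"), 2 * base)
    expect_equal(sim_sigma(th, 2 * d, s, eta, "constant_speed"), 2 * base)
    expect_equal(sim_sigma(th, d, s, 2 * eta, "constant_speed"), base / 2)
    expect_equal(sim_sigma(2 * th, d, s, eta, "constant_speed"), base / 2)
  }
  expect_error(sim_sigma(0, 1, 1, 1), "positive")
})

test_that("presets return the tabulated configurations", {
  af <- mot_preset("AF2007")
  expect_equal(af$env$dynamics, "constant_speed")
  expect_equal(af$env$arena, c(720, 720))
  expect_equal(af$env$n_updates, 300L)
  expect_equal(af$env$eta, 60)
  expect_equal(af$env$min_distance, 80)
  expect_equal(af$params$f_u, 3)
  expect_equal(af$params$f_loc, 30)
  expect_equal(af$params$nob, 24)

  sv <- mot_preset("SV2016")
  expect_equal(sv$env$dynamics, "ou")
  expect_equal(sv$env$k, 5e-4)
  expect_equal(sv$env$lambda, 0.9)
  expect_equal(sv$env$min_distance, 0)
  expect_equal(sv$params$nob, 60)
  expect_equal(sv$params$f_u, 10)

  ps <- mot_preset("PS1988")
  expect_equal(ps$env$arena, c(360, 360))
  expect_equal(ps$env$sigma, 18)
  expect_equal(ps$env$n_updates, 25L)
  expect_equal(ps$env$min_distance, 15)
  expect_equal(ps$params$f_loc, 28)
  expect_true(is.infinite(ps$params$nob))

  e2 <- mot_preset("Exp2", n_targets = 3)
  expect_equal(e2$env$arena, c(1080, 720))
  expect_equal(e2$env$min_distance, 120)
  expect_equal(e2$env$n_objects, 4L)     # one distractor

  expect_error(mot_preset("nope"), "valid presets")
})

test_that("trial blocks aggregate correctly and reproduce under a seed", {
  env <- tiny_ou_env(sigma = 0)          # nothing moves
  b <- run_block(env, tiny_params(), n_trials = 5, seed = 1)
  expect_equal(b$summary$mean, c(1, 1))
  expect_equal(b$summary$sem, c(0, 0))

  env2 <- tiny_ou_env(sigma = 3)
  b1 <- run_block(env2, tiny_params(), n_trials = 8, seed = 4)
  b2 <- run_block(env2, tiny_params(), n_trials = 8, seed = 4)
  expect_identical(b1$summary, b2$summary)
})

test_that("speed threshold search recovers a known synthetic observer", {
  # steep logistic observer: threshold for 50% accuracy sits at 3
  obs <- function(sig) 1 / (1 + exp((sig - 3) / 0.05))
  th <- speed_threshold(NULL, NULL, accuracy_target = 0.5,
                        bracket = c(0.5, 6), tolerance = 0.01,
                        accuracy_fn = obs)
  expect_equal(th$status, "ok")
  expect_lt(abs(th$sigma - 3), 0.02)

  perfect <- speed_threshold(NULL, NULL, accuracy_target = 0.9,
                             bracket = c(0.5, 6),
                             accuracy_fn = function(s) 1)
  expect_equal(perfect$status, "at_upper_bracket")
  expect_equal(perfect$sigma, 6)

  chance <- speed_threshold(NULL, NULL, accuracy_target = 0.9,
                            bracket = c(0.5, 6),
                            accuracy_fn = function(s) 0.5)
  expect_equal(chance$status, "below_bracket")
})

test_that("staircase obeys the reset, randomisation, bound and lattice rules", {
  st <- staircase_state()
  # an error resets to sigma_0 regardless of the current level
  st2 <- staircase_push(st, 4.5, FALSE)
  expect_equal(staircase_next(st2, FALSE), 1.0)

  # success branches with probability 1/3 each, clamped at the bounds
  set.seed(9)
  st3 <- staircase_push(st, 2.0, TRUE)
  draws <- replicate(10000, staircase_next(st3, TRUE))
  expect_setequal(unique(draws), c(1.5, 2.0, 2.5))
  freqs <- table(draws) / length(draws)
  expect_true(all(abs(freqs - 1 / 3) < 0.02))

  st6 <- staircase_push(st, 6.0, TRUE)
  top <- replicate(2000, staircase_next(st6, TRUE))
  expect_setequal(unique(top), c(5.5, 6.0))     # +0.5 branch clamps

  stmin <- staircase_push(st, 0.5, TRUE)
  bottom <- replicate(2000, staircase_next(stmin, TRUE))
  expect_setequal(unique(bottom), c(0.5, 1.0))

  # a long simulated run never leaves the lattice or the bounds
  set.seed(10)
  s <- staircase_state(); sigma <- 1.0
  for (i in 1:500) {
    ok <- runif(1) < 0.7
    s <- staircase_push(s, sigma, ok)
    sigma <- staircase_next(s, ok)
  }
  expect_true(all(s$sigma_history >= 0.5 & s$sigma_history <= 6))
  expect_true(all(abs(s$sigma_history * 2 - round(s$sigma_history * 2))
                  < 1e-9))
  expect_error(staircase_push(s, 1.25, TRUE), "lattice")
})

test_that("staircase convergence needs 5 consecutive hits within half a step", {
  load_history <- function(sig, ok) {
    s <- staircase_state()
    for (i in seq_along(sig)) s <- staircase_push(s, sig[i], ok[i])
    s
  }
  expect_true(staircase_converged(
    load_history(c(3, 3, 3.5, 3.5, 3), rep(TRUE, 5))))
  expect_false(staircase_converged(
    load_history(c(3, 3, 3.5, 3.5), rep(TRUE, 4))))      # only 4 trials
  expect_false(staircase_converged(
    load_history(c(3, 3, 3, 3, 3), c(TRUE, TRUE, FALSE, TRUE, TRUE))))
  expect_false(staircase_converged(
    load_history(c(2.5, 3, 3.5, 3, 3.5), rep(TRUE, 5)))) # range 1.0
  # convergence looks only at the last five trials
  expect_true(staircase_converged(
    load_history(c(5, 1, 1, 1, 1.5, 1, 1), c(FALSE, rep(TRUE, 6)))))
})

test_that("a full staircase run converges on an easy configuration", {
  env <- tiny_ou_env(sigma = 1, n_targets = 2, n_objects = 4)
  st <- run_staircase(env, tiny_params(), seed = 7, max_trials = 40)
  expect_true(attr(st, "converged"))
  expect_gte(attr(st, "sigma_calibrated"), 0.5)
})

test_that("accuracy-vs-targets curves are flat at zero speed and decline with load", {
  env <- tiny_ou_env(sigma = 0)
  curve <- accuracy_by_targets(env, tiny_params(), c(1, 3, 5),
                               n_trials = 5, seed = 1)
  expect_equal(curve$tracking_mean, rep(1, 3))

  env2 <- tiny_ou_env(sigma = 3)
  curve2 <- accuracy_by_targets(env2, tiny_params(nob = 20), c(1, 4, 7),
                                n_trials = 40, seed = 2)
  # statistical monotonicity within 2 SEM
  for (i in 1:2) {
    slack <- 2 * sqrt(curve2$tracking_sem[i]^2 + curve2$tracking_sem[i + 1]^2)
    expect_lte(curve2$tracking_mean[i + 1], curve2$tracking_mean[i] + slack)
  }
})

test_that("grid fit recovers itself and reports degenerate references", {
  env <- tiny_ou_env(sigma = 3)
  pp <- tiny_params()
  truth <- list(f_loc = 24, nob = 12)
  p_true <- pp; p_true$f_loc <- truth$f_loc; p_true$nob <- truth$nob
  ref_curve <- accuracy_by_targets(env, p_true, c(2, 4), n_trials = 15,
                                   seed = 77)
  ref <- data.frame(n_targets = ref_curve$n_targets,
                    accuracy = ref_curve$tracking_mean)
  fit <- grid_fit(ref, env, pp, f_loc_values = c(8, 24),
                  nob_values = c(6, 12), n_trials = 15, seed = 77)
  expect_equal(fit$best_params$f_loc, 24)
  expect_equal(fit$best_params$nob, 12)
  expect_equal(fit$mse, 0)
  expect_equal(fit$r2, 1)

  # constant reference: r2 is degenerate and must be reported <= 0
  flat <- data.frame(n_targets = c(2, 4), accuracy = c(0.8, 0.8))
  fit2 <- grid_fit(flat, env, pp, f_loc_values = 24, nob_values = 12,
                   n_trials = 5, seed = 3)
  expect_lte(fit2$r2, 0)

  expect_error(grid_fit(ref, env, pp, numeric(0), 1), "empty")
})

test_that("the OU displacement factor matches its closed-form limit", {
  f <- ou_displacement_factor(sigma = 3, n_runs = 40, n_updates = 300,
                              seed = 12)
  expect_lt(abs(f - sqrt(2 / (pi * (1 - 0.9^2)))), 0.12)
})
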