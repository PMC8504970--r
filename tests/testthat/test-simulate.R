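# Time-stepping engine, steady-state summaries, ratio sweeps, staircase.

test_that("trajectories have the right shape and determinism", {
  q <- aniso_quad(10, seed = 1)
  comp <- compensation_config("exact_gradient")
  t1 <- run_maintenance(q, comp, eps_magnitude = 0.2, c_magnitude = 0.1,
                        n_steps = 50, seed = 5)
  expect_length(t1$errors, 51)
  expect_equal(t1$errors[1], 0) # starts at the minimiser: maintenance
  t2 <- run_maintenance(q, comp, eps_magnitude = 0.2, c_magnitude = 0.1,
                        n_steps = 50, seed = 5)
  expect_identical(t1$errors, t2$errors)
  t3 <- run_maintenance(q, comp, eps_magnitude = 0.2, c_magnitude = 0.1,
                        n_steps = 50, seed = 6)
  expect_false(identical(t1$errors, t3$errors))
})

test_that("no plasticity means a constant error sequence", {
  q <- aniso_quad(8, seed = 2)
  set.seed(1)
  start <- q$w_star + rnorm(8, 0, 0.5)
  comp <- compensation_config("exact_gradient")
  traj <- run_maintenance(q, comp, eps_magnitude = 0, c_magnitude = 0,
                          n_steps = 20, seed = 1, start = start)
  expect_equal(traj$errors, rep(quadratic_value(q, start), 21))
})

test_that("noise-free gradient descent is non-increasing until overshoot range", {
  q <- aniso_quad(10, lo = 0.5, hi = 2, seed = 3)
  set.seed(2)
  start <- q$w_star + rnorm(10, 0, 2)
  comp <- compensation_config("exact_gradient")
  m <- 0.05
  traj <- run_maintenance(q, comp, eps_magnitude = 0, c_magnitude = m,
                          n_steps = 200, seed = 1, start = start)
  # non-increasing while clearly outside overshoot range: with eigenvalues
  # in [0.5, 2], ||grad|| >= sqrt(F) and dF <= -m ||g|| + m^2 q/2 <= 0
  # whenever sqrt(F) >= 2m
  drops <- diff(traj$errors)
  far <- traj$errors[-length(traj$errors)] > (2 * m)^2
  expect_true(all(drops[far] <= 1e-12))
  # with overshoot clamping the noise-free run converges to the minimum
  trajc <- run_maintenance(q, compensation_config("exact_gradient",
                                                  clamp_overshoot = TRUE),
                           eps_magnitude = 0, c_magnitude = m,
                           n_steps = 2000, seed = 1, start = start)
  expect_lt(trajc$errors[length(trajc$errors)], 1e-10)
})

test_that("steady_state_error averages exactly the trailing window", {
  q <- aniso_quad(6, seed = 4)
  traj <- run_maintenance(q, compensation_config("exact_gradient"),
                          eps_magnitude = 0.3, c_magnitude = 0.2,
                          n_steps = 120, seed = 9)
  w <- 40
  tail_vals <- traj$errors[(length(traj$errors) - w + 1):length(traj$errors)]
  expect_equal(steady_state_error(traj, w), sum(tail_vals) / w,
               tolerance = 1e-15)
  const <- traj
  const$errors <- rep(3.5, 100)
  expect_equal(steady_state_error(const, 10), 3.5)
  expect_error(steady_state_error(traj, 1000), "window")
})

test_that("isotropic steady distance matches the closed-form fixed point", {
  q <- make_quadratic(rep(1, 100), numeric(100), seed = 5)
  comp <- compensation_config("exact_gradient")
  for (p in list(c(0.5, 0.5), c(0.5, 1))) {
    m <- p[1]; e <- p[2]
    traj <- run_maintenance(q, comp, eps_magnitude = e, c_magnitude = m,
                            n_steps = 10000, seed = 31)
    d_sim <- sqrt(2 * steady_state_error(traj, 5000))
    d_th <- isotropic_steady_state(m, e)$distance
    expect_close(d_sim, d_th, tol = 0.05 * d_th)
  }
})

test_that("zero compensation degrades a partially trained state", {
  # E[F(t+1) - F(t)] = e^2 Tr(H) / (2N) > 0 with Tr > 0
  q <- make_quadratic(c(rep(2, 15), rep(-0.5, 5)), numeric(20), seed = 6)
  expect_equal(classify_trained_state(q, numeric(20))$label,
               "partially_trained")
  comp <- compensation_config("exact_gradient")
  set.seed(7)
  w0 <- q$w_star + rnorm(20, 0, 0.3)
  e <- 0.2
  f0 <- quadratic_value(q, w0)
  d <- replicate(3000, {
    quadratic_value(q, w0 + fluctuation_step(20, e)) - f0
  })
  se <- sd(d) / sqrt(length(d))
  expect_close(mean(d), e^2 * sum(q$eigenvalues) / (2 * 20), tol = 3 * se)
  expect_gt(mean(d), 0)
})

test_that("single-ratio sweeps reduce to repeated maintenance runs", {
  q <- aniso_quad(10, seed = 8)
  comp <- compensation_config("exact_gradient")
  sw <- ratio_sweep(q, comp, eps_magnitude = 0.3, ratios = 0.8,
                    n_steps = 200, repeats = 3, seed = 11, window = 50)
  expect_equal(sw$argmin_ratio, 0.8)
  expect_equal(dim(sw$cells), c(1L, 3L))
  # cell reproduces a direct run with the same derived seed
  direct <- run_maintenance(q, comp, 0.3, 0.8 * 0.3, n_steps = 200,
                            seed = mix_seed(11, "cell", 1, 2))
  expect_equal(sw$cells[1, 2], steady_state_error(direct, 50))
})

test_that("isotropic ratio sweep puts the optimum at ratio 1", {
  q <- make_quadratic(rep(1, 60), numeric(60), seed = 9)
  comp <- compensation_config("exact_gradient")
  sw <- ratio_sweep(q, comp, eps_magnitude = 0.5,
                    ratios = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2),
                    n_steps = 3000, repeats = 3, seed = 13, window = 500)
  expect_close(sw$argmin_ratio, 1.0, tol = 0.25 + 1e-12)
  # U-shape: both grid ends sit clearly above the minimum and the curve
  # decreases from the left end and increases to the right end
  err <- sw$steady_errors
  expect_gt(err[1], min(err) * 1.1)
  expect_gt(err[length(err)], min(err) * 1.1)
  expect_lt(err[2], err[1])
  expect_gt(err[length(err)], err[length(err) - 1])
})

test_that("anisotropic gradient sweep optimum is below 1 and matches theory", {
  lam <- exp(seq(log(0.1), log(10), length.out = 60))
  q <- make_quadratic(lam, numeric(60), seed = 10)
  comp <- compensation_config("exact_gradient")
  ratios <- seq(0.25, 1.5, by = 0.25)
  sw <- ratio_sweep(q, comp, eps_magnitude = 0.5, ratios = ratios,
                    n_steps = 3000, repeats = 3, seed = 17, window = 500)
  expect_lt(sw$argmin_ratio, 1.0)
  traj <- run_maintenance(q, comp, 0.5, sw$argmin_ratio * 0.5,
                          n_steps = 3000, seed = 18,
                          record_weights_every = 20)
  pred <- predicted_ratio_steady(q, traj)
  expect_close(sw$argmin_ratio, pred, tol = 0.25 + 1e-12)
})

test_that("weights drift while error stays bounded at the sweet spot", {
  q <- aniso_quad(30, lo = 0.5, hi = 2, seed = 12)
  comp <- compensation_config("exact_gradient")
  traj <- run_maintenance(q, comp, eps_magnitude = 0.3, c_magnitude = 0.25,
                          n_steps = 4000, seed = 19,
                          record_weights_every = 200)
  drift <- vapply(traj$snapshots, function(w) sqrt(sum((w - q$w_star)^2)), 1)
  # error is bounded (no blow-up) ...
  expect_lt(max(traj$errors), 50 * steady_state_error(traj, 500) + 1)
  # ... while cumulative weight movement keeps growing: compare total path
  # length in the first vs second half (movement does not stall)
  times <- as.integer(names(traj$snapshots))
  path <- vapply(seq_len(length(times) - 1), function(i) {
    sqrt(sum((traj$snapshots[[i + 1]] - traj$snapshots[[i]])^2))
  }, 1)
  expect_gt(sum(path[times[-1] > 2000]), 0.5 * sum(path[times[-1] <= 2000]))
})

test_that("staircase finds a sweet spot below the fluctuation magnitude", {
  q <- aniso_quad(40, seed = 13)
  comp <- compensation_config("exact_gradient")
  e <- 0.5
  stages <- e * 0.25 * (2 / 0.25)^(seq(0, 1, length.out = 6))
  st <- staircase(q, comp, eps_magnitude = e, stage_magnitudes = stages,
                  stage_length = 1500, settle_discard = 900, seed = 23)
  expect_length(st$errors, 6 * 1500 + 1)
  expect_true(st$sweet_spot_magnitude %in% stages)
  expect_lt(st$sweet_spot_magnitude, e)
  # one stage == run_maintenance + steady_state_error
  st1 <- staircase(q, comp, eps_magnitude = e, stage_magnitudes = stages[2],
                   stage_length = 400, settle_discard = 100, seed = 29)
  direct <- run_maintenance(q, comp, e, stages[2], n_steps = 400,
                            seed = mix_seed(29, "stage", 1))
  expect_equal(st1$stage_steady_errors[1],
               mean(direct$errors[-1][101:400]), tolerance = 1e-12)
})

test_that("sweeps and staircases export tidy data frames", {
  q <- aniso_quad(8, seed = 14)
  comp <- compensation_config("exact_gradient")
  sw <- ratio_sweep(q, comp, 0.3, c(0.5, 1), n_steps = 100, repeats = 2,
                    seed = 1, window = 20)
  df <- as.data.frame(sw)
  expect_equal(nrow(df), 4)
  expect_named(df, c("ratio", "repeat_", "steady_error", "seed"))
  st <- staircase(q, comp, 0.3, c(0.1, 0.2), stage_length = 50,
                  settle_discard = 10, seed = 2)
  expect_equal(nrow(as.data.frame(st)), 2)
})
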