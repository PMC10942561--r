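test_that("sign-crossing counts match printed cases", {
  expect_equal(count_sign_crossings(c(1, -1, 1, -1)), 3L)
  expect_equal(count_sign_crossings(rep(2, 50)), 0L)
  expect_equal(count_sign_crossings(numeric(0)), 0L)
  expect_equal(count_sign_crossings(rep(0, 10)), 0L)
})

test_that("zero-hysteresis counting equals the brute-force sign scan", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:1000, 1)
    x <- stats::rnorm(n, sd = 1e-3)
    expect_identical(count_sign_crossings(x, 0), brute_sign_changes(x))
  }
})

test_that("hysteresis suppresses zero-lingering chatter", {
  # one genuine down-up excursion with chatter around zero in between
  x <- c(1, 0.01, -0.01, 0.02, -0.02, -1, 1)
  expect_equal(count_sign_crossings(x, 0.05), 2L)
  expect_gt(count_sign_crossings(x, 0), 2L)
})

test_that("movement-unit RMS follows the per-axis count formula", {
  t <- seq(0, 1, by = 0.01)
  mk <- function(nx, ny, nz) {
    sig <- function(k) if (k == 0) rep(1, length(t)) else
      sin(pi * t * (k + 0.5) / max(t))  # k interior zero crossings
    cbind(sig(nx), sig(ny), sig(nz))
  }
  mu <- movement_units(mk(3, 0, 0), mk(2, 2, 2), mk(0, 0, 0),
                       movement_unit_config(hysteresis_frac = 0))
  expect_equal(mu$mu_type1_rms, sqrt(3))        # (3,0,0) -> sqrt(9/3)
  expect_equal(mu$mu_type2_rms, 2)              # (2,2,2) -> 2
  expect_equal(mu$mu_type3_rms, 0)
  # root-sum-square mode
  mu2 <- movement_units(mk(3, 0, 0), mk(2, 2, 2), mk(0, 0, 0),
                        movement_unit_config(hysteresis_frac = 0,
                                             rms_divisor = "sum"))
  expect_equal(mu2$mu_type1_rms, 3)
})

test_that("a single min-jerk reach yields per-axis unit counts (0, 1, 2)", {
  # velocity 30 tau^2 (1-tau)^2 has no interior zeros; acceleration one
  # (tau = 1/2); jerk two (tau = (3 +/- sqrt(3))/6)
  at <- analytic_trial()
  sig <- prepare_signals(at$rec)
  w <- sig$t >= 0.5 & sig$t <= 1.5
  mu <- movement_units(sig$vel[w, ], sig$acc[w, ], sig$jerk[w, ],
                       movement_unit_config(hysteresis_frac = 0))
  counts <- attr(mu, "counts")
  expect_equal(unname(counts[, "type1"]), c(0L, 0L, 0L))
  expect_equal(unname(counts[1, "type2"]), 1L)
  expect_equal(unname(counts[1, "type3"]), 2L)
  expect_equal(mu$mu_type2_rms, sqrt(1 / 3))
  expect_equal(mu$mu_type3_rms, sqrt(4 / 3))
})

test_that("magnitude parameters recover the analytic reach", {
  at <- analytic_trial()
  sig <- prepare_signals(at$rec)
  mg <- compute_magnitude_params(sig$vel_mag, sig$acc_mag, sig$pos, sig$t,
                                 0.5, 1.5)
  expect_equal(mg$total_distance, 0.3, tolerance = 0.01)
  expect_equal(mg$time_to_peak_velocity, 0.5, tolerance = 0.011)
  expect_equal(mg$max_velocity / mg$avg_velocity, 1.875, tolerance = 0.02)
})

test_that("an out-and-back reach doubles path length at near-zero displacement", {
  t <- seq(0, 3, by = 0.01)
  ks <- list(submovement_kernel(0.3, 1, c(0.3, 0, 0)),
             submovement_kernel(1.5, 1, c(-0.3, 0, 0)))
  tr <- render_submovements(ks, t)
  rec <- trial_recording("S", "TD", 1L, 100, t, pos = tr$pos, acc = tr$acc,
                         trigger_time = 0, end_time = 3)
  sig <- prepare_signals(rec)
  mg <- compute_magnitude_params(sig$vel_mag, sig$acc_mag, sig$pos, sig$t,
                                 0.3, 2.5)
  expect_equal(mg$total_distance, 0.6, tolerance = 0.01)
  expect_lt(sqrt(sum((sig$pos[t == 2.5, ] - sig$pos[t == 0.3, ])^2)), 0.01)
})

test_that("constant-velocity motion satisfies the window identities", {
  t <- seq(0, 2, by = 0.01)
  v <- 0.4
  pos <- cbind(v * t, 0 * t, 0 * t)
  vel_mag <- rep(v, length(t))
  acc_mag <- rep(0, length(t))
  mg <- compute_magnitude_params(vel_mag, acc_mag, pos, t, 0, 2)
  expect_equal(mg$avg_velocity, v)
  expect_equal(mg$max_velocity, v)
  expect_equal(mg$total_distance, 2 * v, tolerance = 1e-9)
})

test_that("magnitude parameters ignore samples outside the window", {
  at <- analytic_trial()
  sig <- prepare_signals(at$rec)
  mg1 <- compute_magnitude_params(sig$vel_mag, sig$acc_mag, sig$pos, sig$t,
                                  0.5, 1.5)
  # corrupt everything outside [0.5, 1.5]
  out <- sig$t < 0.5 | sig$t > 1.5
  vm <- sig$vel_mag; vm[out] <- 99
  am <- sig$acc_mag; am[out] <- 99
  pos <- sig$pos; pos[out, ] <- 99
  mg2 <- compute_magnitude_params(vm, am, pos, sig$t, 0.5, 1.5)
  expect_equal(mg1, mg2)
})

test_that("full extraction composes the stages on a clean one-block trial", {
  p <- default_group_params("TD")
  p$corrective_rate <- 0
  p$overshoot_frac <- 0
  p$noise_sd_acc <- 0
  rec <- simulate_trial(p, blocks_per_trial = 1L, seed = 21)
  ft <- extract_features(rec)
  expect_equal(nrow(ft), 1L)
  expect_true(all(ft[kinematic_feature_names()] >= 0))
  expect_lte(ft$avg_velocity, ft$max_velocity)
  expect_lte(ft$time_to_peak_velocity, ft$movement_time)
  # 2 primaries: acceleration of each crosses zero once per active axis;
  # counts stay small on a clean trial
  expect_lte(ft$mu_type1_rms, 6)
})

test_that("extraction errors carry the trial identity", {
  t <- seq(0, 1, by = 0.01)
  flat <- trial_recording("CHILD07", "ASD", 3L, 100, t,
                          pos = matrix(0, length(t), 3),
                          acc = matrix(0, length(t), 3),
                          trigger_time = 0, end_time = 1)
  expect_error(extract_features(flat), "CHILD07.*3")
  expect_warning(
    ft <- extract_cohort_features(list(flat,
                                       simulate_trial(default_group_params("TD"),
                                                      1L, seed = 4)),
                                  on_error = "skip"),
    "CHILD07")
  expect_equal(nrow(ft), 1L)
})

test_that("sensor noise does not move detected onsets (position channel clean)", {
  p <- default_group_params("TD")
  p$noise_sd_acc <- 0
  set.seed(31)
  base <- simulate_trial(p, 1L, seed = 61)
  p$noise_sd_acc <- 0.2
  noisy <- simulate_trial(p, 1L, seed = 61)
  rt0 <- extract_features(base)$reaction_time
  rt1 <- extract_features(noisy)$reaction_time
  expect_equal(rt0, rt1, tolerance = 0.021)
})

test_that("scaling position scales magnitudes and preserves unit counts", {
  p <- default_group_params("TD")
  p$noise_sd_acc <- 0
  rec <- simulate_trial(p, 1L, seed = 8)
  ft1 <- extract_features(rec)
  rec2 <- rec
  rec2$pos <- rec$pos * 3
  rec2$acc <- rec$acc * 3
  ft2 <- extract_features(rec2)
  for (col in c("total_distance", "avg_velocity", "max_velocity",
                "avg_acceleration", "max_acceleration"))
    expect_equal(ft2[[col]], 3 * ft1[[col]], tolerance = 1e-6, info = col)
  for (col in c("mu_type1_rms", "mu_type2_rms", "mu_type3_rms",
                "reaction_time", "movement_time"))
    expect_equal(ft2[[col]], ft1[[col]], info = col)
})

test_that("adding a corrective submovement never decreases Type-2 units", {
  t <- seq(0, 3, by = 0.01)
  base_k <- list(submovement_kernel(0.4, 1, c(0.3, 0, 0)))
  extra_k <- c(base_k, list(submovement_kernel(1.0, 0.35, c(0.05, 0.02, 0))))
  mu_of <- function(ks) {
    tr <- render_submovements(ks, t)
    rec <- trial_recording("S", "TD", 1L, 100, t, pos = tr$pos, acc = tr$acc,
                           trigger_time = 0, end_time = 3)
    sig <- prepare_signals(rec)
    w <- sig$t >= 0.4 & sig$t <= 2
    movement_units(sig$vel[w, ], sig$acc[w, ], sig$jerk[w, ])$mu_type2_rms
  }
  expect_gte(mu_of(extra_k), mu_of(base_k))
})
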