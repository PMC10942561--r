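test_that("a single kernel reproduces the closed-form minimum-jerk profile", {
  t <- seq(0, 1, by = 0.001)
  tr <- render_submovements(list(submovement_kernel(0, 1, c(0.3, 0, 0))), t)
  # endpoint displacement and the analytic peak speed 1.875 * D / T at t = T/2
  expect_equal(tr$pos[length(t), ], c(x = 0.3, y = 0, z = 0))
  expect_equal(max(tr$vel[, 1]), 1.875 * 0.3, tolerance = 1e-9)
  expect_equal(t[which.max(tr$vel[, 1])], 0.5)
  # velocity is exactly the analytic derivative on the open interval
  inside <- t > 0 & t < 1
  expect_equal(tr$vel[inside, 1], 30 * t[inside]^2 * (1 - t[inside])^2 * 0.3,
               tolerance = 1e-12)
})

test_that("kernel contributions clamp outside the active window", {
  t <- seq(0, 1, by = 0.01)
  tr <- render_submovements(list(submovement_kernel(5, 1, c(0.2, 0.1, 0))), t)
  expect_true(all(tr$pos == 0))
  expect_true(all(tr$acc == 0))
  # after the window the position holds the full displacement, derivatives zero
  t2 <- seq(0, 3, by = 0.01)
  tr2 <- render_submovements(list(submovement_kernel(0.5, 1, c(0.2, 0.1, 0))), t2)
  after <- t2 >= 1.5 + 0.01
  expect_true(all(abs(tr2$pos[after, 1] - 0.2) < 1e-12))
  expect_true(all(tr2$vel[after, ] == 0))
  expect_true(all(tr2$jerk[after, ] == 0))
})

test_that("rendering is linear in the kernel set", {
  t <- seq(0, 2, by = 0.01)
  k <- submovement_kernel(0.3, 1.2, c(0.25, -0.1, 0.05))
  one <- render_submovements(list(k), t)
  two <- render_submovements(list(k, k), t)
  expect_equal(two$pos, 2 * one$pos)
  expect_equal(two$acc, 2 * one$acc)
})

test_that("rendering rejects bad inputs", {
  expect_error(render_submovements(list(), seq(0, 1, 0.1)), "at least one")
  expect_error(render_submovements(list(submovement_kernel(0, 1, c(1, 0, 0))),
                                   c(0, 0.1, 0.15)), "uniform")
  expect_error(submovement_kernel(0, -1, c(1, 0, 0)), "duration")
})

test_that("twice-differenced position recovers acceleration to truncation order", {
  # two passes of the central difference span 2*dt, so away from the kernel
  # boundaries (where the jerk jumps) the error is bounded by
  # (2*dt)^2 / 12 * max |d4 pos / dt4|, with d4 max = 360 * D / T^4 per axis
  at <- analytic_trial(sample_rate = 100)
  dt <- 1 / 100
  num_acc <- reachkin:::central_diff(reachkin:::central_diff(at$traj$pos, dt),
                                     dt)
  interior <- at$t > 0.5 + 2 * dt & at$t < 1.5 - 2 * dt
  bound <- 2 * (2 * dt)^2 / 12 * 360 * 0.3
  expect_lt(max(abs(num_acc[interior, ] - at$traj$acc[interior, ])), bound)
})
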