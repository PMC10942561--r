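test_that("a noise-free single-block trial contains exactly the primary kernels", {
  p <- default_group_params("TD")
  p$corrective_rate <- 0
  p$overshoot_frac <- 0
  p$noise_sd_acc <- 0
  rec <- simulate_trial(p, blocks_per_trial = 1L, seed = 11)
  # one reach + one place primary, no correctives
  expect_identical(rec$ground_truth$submovement_counts, c(1L, 1L))
  expect_equal(sum(rec$ground_truth$submovement_counts), 2L)
  expect_gte(rec$ground_truth$onset_time, rec$trigger_time)
})

test_that("the same seed reproduces a trial exactly", {
  p <- default_group_params("ASD")
  a <- simulate_trial(p, seed = 99)
  b <- simulate_trial(p, seed = 99)
  expect_identical(a, b)
})

test_that("corrective submovement counts follow the configured Poisson rate", {
  p <- default_group_params("TD")
  p$corrective_rate <- 3
  p$overshoot_frac <- 0
  set.seed(1234)
  total <- replicate(1000, {
    plan <- reachkin:::plan_trial(p, blocks_per_trial = 5L)
    sum(plan$submovement_counts) - 10L  # 10 primaries
  })
  # mean corrective count over 10 primaries is Poisson(30); 99% MC band
  expect_lt(abs(mean(total) - 30), 3 * sqrt(30) / sqrt(1000) * 3)
})

test_that("cohort size and class share match the configured child cohort", {
  co <- simulate_cohort(child_cohort_spec(seed = 5))
  expect_equal(nrow(co$manifest), (15 + 26) * 6)  # 246 trials
  expect_equal(mean(co$manifest$group == "ASD"), 26 / 41, tolerance = 1e-12)
  expect_equal(length(co$trials), nrow(co$manifest))
  # scores constant within subject, present for children
  s1 <- co$manifest[co$manifest$subject_id == "TD01", ]
  expect_equal(length(unique(s1$vabs_soc)), 1L)
  expect_false(any(is.na(co$manifest$vabs_com)))
})

test_that("a noiseless single-latent score model gives perfect correlation", {
  sm <- default_score_model(noise_sd = 0)
  sm$coef$TD <- rbind(com = c(vel = 0, mu = 0), dl = c(vel = 0, mu = 0),
                      soc = c(vel = 5, mu = 0))
  spec <- cohort_spec(groups = list(list(params = default_group_params("TD"),
                                         n_subjects = 12L)),
                      trials_per_subject = 1L, seed = 3, score_model = sm)
  co <- simulate_cohort(spec)
  expect_equal(stats::cor(co$subjects$z_vel, co$subjects$vabs_soc), 1)
})

test_that("cohort specification preconditions are enforced", {
  expect_error(cohort_spec(groups = list()), "at least one group")
  expect_error(cohort_spec(groups = list(list(params = default_group_params("TD"),
                                              n_subjects = 2L)),
                           sample_rate = 10), "20 Hz")
  expect_error(group_params("TD", 0.5, 0.1, 0.7, 0.1, 0.3, 0.02,
                            corrective_rate = -1,
                            corrective_amplitude_frac = 0.1,
                            overshoot_frac = 0, peak_speed_scale = 1,
                            noise_sd_acc = 0), "corrective_rate")
})

test_that("identical cohort specs give byte-identical CSV output", {
  spec <- child_cohort_spec(n_td = 2L, n_asd = 2L, trials_per_subject = 2L,
                            seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(spec), d1)
  write_cohort(simulate_cohort(spec), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("ground-truth corrective counts order ADULT < TD < ASD", {
  rate_mean <- function(group) {
    p <- default_group_params(group)
    set.seed(42)
    mean(replicate(500, {
      plan <- reachkin:::plan_trial(p, blocks_per_trial = 2L)
      sum(plan$submovement_counts)
    }))
  }
  m <- vapply(c("ADULT", "TD", "ASD"), rate_mean, numeric(1))
  expect_lt(m[["ADULT"]], m[["TD"]])
  expect_lt(m[["TD"]], m[["ASD"]])
})
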