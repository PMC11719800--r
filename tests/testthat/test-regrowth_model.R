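test_that("ellipsoid volume follows the caliper formula and swaps axes", {
  d <- 4.2
  expect_equal(ellipsoid_volume(d, d), pi / 6 * d^3)
  expect_equal(ellipsoid_volume(6 / pi, 1), 1)
  set.seed(3)
  l <- runif(20, 2, 15); b <- runif(20, 1, 2)
  expect_equal(ellipsoid_volume(l, b), pi / 6 * l * b^2)
  expect_warning(v <- ellipsoid_volume(5, 8), "swapped")
  expect_equal(v, pi / 6 * 8 * 25)
  expect_error(ellipsoid_volume(0, 1), "positive")
})

test_that("the regrowth curve is normalized at t = 0 and hits its landmarks", {
  for (p in random_regrowth_params(50, seed = 9))
    expect_equal(eval_regrowth(p, 0), 1)
  ctrl <- regrowth_params(0, 0.1, log(3) / 33)
  expect_equal(eval_regrowth(ctrl, 33), 3)
  crt <- regrowth_params(0.6, 0.15, 0.045683)
  expect_equal(eval_regrowth(crt, 44.1), 3, tolerance = 1e-3 / 3)
})

test_that("parameter constraints are enforced", {
  expect_error(regrowth_params(1, 0.1, 0.05), "a2")
  expect_error(regrowth_params(-0.1, 0.1, 0.05), "a1")
  expect_error(regrowth_params(0.5, 0, 0.05), "alpha1")
  expect_error(regrowth_params(0.5, 0.1, -1), "alpha2")
  expect_equal(regrowth_params(0.3, 0.1, 0.05)$a2, 0.7)
})

test_that("global_min_time matches a fine grid scan and is stationary", {
  expect_equal(global_min_time(regrowth_params(0, 0.1, 0.05)), 0)
  # slowly-shrinking curves are monotone from the start
  expect_equal(global_min_time(regrowth_params(0.3, 0.01, 0.1)), 0)
  for (p in random_regrowth_params(1000, seed = 21)) {
    tm <- global_min_time(p)
    # two-stage grid scan oracle: coarse over [0, 200], then 1e-4 steps
    coarse <- seq(0, 200, by = 0.05)
    t0 <- coarse[which.min(eval_regrowth(p, coarse))]
    fine <- seq(max(0, t0 - 0.1), t0 + 0.1, by = 1e-4)
    tg <- fine[which.min(eval_regrowth(p, fine))]
    expect_lt(abs(tm - tg), 1e-3)
    if (tm > 0) {
      h <- 1e-6
      deriv <- (eval_regrowth(p, tm + h) - eval_regrowth(p, tm - h)) / (2 * h)
      expect_lt(abs(deriv), 1e-6)
    }
  }
})

test_that("regrowth starts on the next scheduled measurement day", {
  sched <- c(2, 4, 7, 9, 11, 14, 16)
  expect_equal(regrowth_start(12.4, c(sched, 18)), 14)
  expect_equal(regrowth_start(0, sched), 2)
  expect_true(is.na(regrowth_start(20, sched)))
  p <- regrowth_params(0.6, 0.15, 0.045683)
  expect_equal(regrowth_start(p, measurement_schedule()),
               min(measurement_schedule()[measurement_schedule() >
                                            global_min_time(p)]))
})

test_that("raw tripling time interpolates the recorded ratios", {
  rec <- mouse_record("m", "x", 100,
                      data.frame(day = c(10, 12),
                                 volume_mm3 = c(280, 320)),
                      reached_endpoint = TRUE)
  expect_equal(tripling_time(rec, "raw"), 11)
  # crossing before the first measurement anchors at (0, 1)
  rec2 <- mouse_record("m", "x", 100,
                       data.frame(day = 2, volume_mm3 = 500),
                       reached_endpoint = TRUE)
  expect_equal(tripling_time(rec2, "raw"), 2 * (3 - 1) / (5 - 1))
  # never reaching 3 x V0 is censored
  rec3 <- mouse_record("m", "x", 100,
                       data.frame(day = c(2, 4, 7), volume_mm3 = c(90, 95, 110)))
  expect_true(is.na(tripling_time(rec3, "raw")))
})

test_that("model tripling time equals the closed form for pure growth", {
  for (al2 in c(0.02, log(3) / 33, 0.1)) {
    p <- regrowth_params(0, 0.1, al2)
    expect_equal(tripling_time(p, "model"), log(3) / al2, tolerance = 1e-6)
  }
  crt <- regrowth_params(0.6, 0.15, 0.045683)
  t3 <- tripling_time(crt, "model")
  expect_equal(t3, 44.10, tolerance = 0.01 / 44.1)
  # bisection vs fine grid
  grid <- seq(40, 50, by = 1e-5)
  expect_equal(t3, grid[which.min(abs(eval_regrowth(crt, grid) - 3))],
               tolerance = 1e-4)
})

test_that("noise-free fits recover the generating parameters exactly", {
  truth <- regrowth_params(0.6, 0.15, 0.045683)
  days <- measurement_schedule()
  fit <- fit_regrowth(data.frame(day = days,
                                 ratio = eval_regrowth(truth, days)))
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$params$a1, 0.6, tolerance = 1e-3)
  expect_equal(fit$params$alpha1, 0.15, tolerance = 1e-3)
  expect_equal(fit$params$alpha2, 0.045683, tolerance = 1e-3)
  expect_equal(fit$t_min, global_min_time(truth), tolerance = 1e-3)

  # pure exponential data pins a1 at its boundary
  ctrl <- regrowth_params(0, 0.1, 0.0332913)
  fit0 <- fit_regrowth(data.frame(day = days,
                                  ratio = eval_regrowth(ctrl, days)))
  expect_lte(fit0$params$a1, 1e-3)
  expect_equal(fit0$params$alpha2, 0.0332913, tolerance = 1e-3)
})

test_that("fits are deterministic and demand enough points", {
  rec <- noise_free_record(regrowth_params(0.5, 0.2, 0.04))
  f1 <- fit_regrowth(rec); f2 <- fit_regrowth(rec)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_error(fit_regrowth(data.frame(day = c(2, 4, 7),
                                       ratio = c(0.9, 0.8, 0.85))),
               "insufficient data")
})

test_that("noisy series recover alpha2 within the Monte-Carlo bands", {
  truth <- regrowth_params(0.6, 0.15, 0.045683)
  days <- measurement_schedule()
  f <- eval_regrowth(truth, days)
  s2 <- log(1 + 0.15^2)
  set.seed(2024)
  al2 <- replicate(200, {
    obs <- f * rlnorm(length(days), meanlog = -s2 / 2, sdlog = sqrt(s2))
    fit_regrowth(data.frame(day = days, ratio = obs))$params$alpha2
  })
  expect_lt(median(abs(al2 / truth$alpha2 - 1)), 0.10)
  # linear-scale least squares carries a small (~3%) upward finite-sample
  # bias under multiplicative noise; it stays well under 5%
  expect_lt(abs(mean(al2) / truth$alpha2 - 1), 0.05)
})

test_that("measurement CSV round-trips into records and fits", {
  cohort <- generate_cohort(default_study_design(seed = 5, n = 2))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_measurements(cohort, tf)
  back <- read_measurements(tf)
  expect_length(back, length(cohort))
  r0 <- cohort[["CRT-01"]]; r1 <- back[["CRT-01"]]
  expect_equal(r1$v0, r0$v0)
  expect_equal(r1$measurements$day, r0$measurements$day)
  expect_equal(r1$measurements$volume_mm3, r0$measurements$volume_mm3)
  expect_equal(r1$reached_endpoint, r0$reached_endpoint)
})

test_that("records reject measurements after euthanasia and bad series", {
  expect_error(mouse_record("m", "x", 100,
                            data.frame(day = c(2, 4, 3),
                                       volume_mm3 = c(90, 100, 95))),
               "strictly increasing")
  expect_error(mouse_record("m", "x", 100,
                            data.frame(day = c(2, 4), volume_mm3 = c(90, 100)),
                            reached_endpoint = TRUE),
               "below 3 x v0")
  expect_error(mouse_record("m", "x", 100,
                            data.frame(day = c(2, 4, 6),
                                       volume_mm3 = c(90, 310, 320)),
                            reached_endpoint = TRUE, last_followup_day = 4),
               "after the endpoint")
})
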