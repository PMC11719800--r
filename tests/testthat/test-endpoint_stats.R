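test_that("growth delay statistics match direct recomputation", {
  set.seed(15)
  treated <- rnorm(9, 50, 8)
  control <- rnorm(9, 33, 5)
  d <- growth_delay(treated, control, arm = "CRT")
  delays <- treated - mean(control)
  expect_equal(d$per_mouse_delays, delays)
  expect_equal(d$mean_delay, mean(delays))
  expect_equal(d$sd, sd(delays))
  expect_equal(d$ci95_halfwidth, qt(0.975, 8) * sd(delays) / 3)
  expect_equal(d$p_vs_control, t.test(treated, control, var.equal = TRUE)$p.value)
  expect_equal(d$p_delay_vs_zero, t.test(delays)$p.value)
})

test_that("growth delay handles degenerate and censored inputs", {
  ctrl <- c(30, 33, 36)
  same <- growth_delay(ctrl, ctrl)
  expect_equal(same$mean_delay, 0)
  expect_equal(same$sd, sd(ctrl))
  cen <- growth_delay(c(40, NA, 44, NA), ctrl)
  expect_equal(cen$n, 2L)
  expect_equal(cen$n_censored, 2L)
  allc <- growth_delay(c(NA_real_, NA_real_), ctrl)
  expect_true(is.na(allc$mean_delay))
  expect_equal(allc$n, 0L)
  # noise-free worked example: identical treated times vs identical controls
  det <- growth_delay(rep(44.1, 9), rep(33, 9))
  expect_equal(det$mean_delay, 11.1)
  expect_equal(det$sd, 0)
})

test_that("the pooled t-test matches the textbook computation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  tt <- unpaired_t_test(a, b)
  sp2 <- (2 * var(a) + 3 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(tt$t, t_hand)
  expect_equal(tt$df, 5)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), 5))
  # symmetry and self-comparison
  rev <- unpaired_t_test(b, a)
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  self <- unpaired_t_test(a, a)
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)
  # degenerate variances
  expect_equal(unpaired_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(unpaired_t_test(c(2, 2), c(3, 3))$p, 0)
})

test_that("t-test p is invariant under joint affine transforms", {
  set.seed(8)
  a <- rnorm(7); b <- rnorm(9, 0.8)
  p0 <- unpaired_t_test(a, b)$p
  expect_equal(unpaired_t_test(3 * a - 5, 3 * b - 5)$p, p0)
})

test_that("KM estimate reproduces a hand-computed product-limit table", {
  rec <- data.frame(time = c(1, 2, 3, 4, 4, 5),
                    event = c(1, 0, 1, 1, 1, 0))
  km <- km_estimate(rec)
  ev <- km$n_events > 0
  expect_equal(km$times[ev], c(1, 3, 4))
  expect_equal(km$survival[ev], c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 3))
  expect_equal(km$at_risk[ev], c(6, 4, 3))
  expect_equal(km$median, 4)
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(77)
  times <- sample(1:40, 12, replace = TRUE)
  km <- km_estimate(data.frame(time = times, event = 1))
  for (i in seq_along(km$times))
    expect_equal(km$survival[i], mean(times > km$times[i]))
  expect_true(all(diff(km$survival) <= 1e-12))
  # all censored: flat at 1, median undefined
  flat <- km_estimate(data.frame(time = times, event = 0))
  expect_true(all(flat$survival == 1))
  expect_true(is.na(flat$median))
})

test_that("log-rank agrees with the hand-coded statistic and its permutation null", {
  a <- data.frame(time = c(5, 8, 12, 14, 20, 30, 33, 90),
                  event = c(1, 1, 1, 0, 1, 1, 1, 0))
  b <- data.frame(time = c(9, 14, 22, 28, 35, 44, 60, 90),
                  event = c(1, 1, 1, 1, 1, 0, 1, 0))
  lr <- logrank_test(a, b)
  dat <- rbind(a, b)
  grp <- rep(c("a", "b"), each = 8)
  expect_equal(lr$chi2, logrank_chi2_hand(dat$time, dat$event, grp),
               tolerance = 1e-9)
  # permutation null of the hand statistic
  set.seed(31)
  perm <- replicate(10000, {
    g <- sample(grp)
    logrank_chi2_hand(dat$time, dat$event, g)
  })
  expect_lt(abs(mean(perm >= lr$chi2 - 1e-12) - lr$p), 0.02)
})

test_that("log-rank degenerate and stratified reductions behave", {
  a <- data.frame(time = c(3, 6, 9, 12), event = c(1, 1, 0, 1))
  ident <- logrank_test(a, a)
  expect_equal(ident$chi2, 0, tolerance = 1e-9)
  expect_equal(ident$p, 1, tolerance = 1e-9)
  b <- data.frame(time = c(4, 7, 11, 15), event = c(1, 0, 1, 1))
  plain <- logrank_test(a, b)
  strat <- logrank_test(a, b, strata = rep("s1", 8))
  expect_equal(strat$chi2, plain$chi2)
  expect_equal(strat$p, plain$p)
  expect_error(logrank_test(data.frame(time = 1:3, event = 0),
                            data.frame(time = 1:3, event = 0)),
               "zero events")
})

test_that("the PFS dataset applies the event and cap rules", {
  df <- data.frame(mouse_id = c("a", "b", "c"),
                   arm = "MRT",
                   regrowth_start_day = c(14, NA, 95),
                   last_followup_day = c(14, 88, 95))
  pfs <- build_pfs_dataset(df, followup_cap = 90)
  expect_equal(pfs$time, c(14, 88, 90))
  expect_equal(pfs$event, c(1L, 0L, 0L))
  # list-of-fits interface
  cohort <- generate_cohort(default_study_design(seed = 2, n = 2))
  fits <- lapply(cohort, fit_regrowth)
  pfs2 <- build_pfs_dataset(fits,
                            arms = vapply(cohort, `[[`, "", "arm"),
                            last_followup = vapply(cohort, `[[`, 1, "last_followup_day"))
  expect_equal(nrow(pfs2), 8L)
  expect_true(all(pfs2$event %in% 0:1))
  expect_true(all(pfs2$time > 0 & pfs2$time <= 90))
})

test_that("pairwise log-rank covers every arm pair and can Holm-adjust", {
  set.seed(5)
  rec <- data.frame(
    arm = rep(c("control", "CRT", "MRT"), each = 6),
    time = c(sample(5:15, 6), sample(10:25, 6), sample(20:60, 6)),
    event = 1)
  pw <- pairwise_logrank(rec)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  pwh <- pairwise_logrank(rec, adjust = "holm")
  expect_equal(pwh$p_adj, p.adjust(pwh$p, "holm"))
})
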