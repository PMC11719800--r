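test_that("geometry invariants are enforced", {
  expect_error(beam_geometry(0, 400, 10), "beam_width")
  expect_error(beam_geometry(50, 40, 10), "exceed beam_width")
  expect_error(beam_geometry(50, 400, 0), "field_mm")
  expect_error(beam_geometry(500, 12000, 10), "field width")
})

test_that("count_beams reproduces the collimator counts and the placement scan", {
  expect_identical(count_beams(mrt_geometry()), 25L)
  expect_identical(count_beams(mbrt_geometry()), 5L)
  # single beam when the CTC equals the field width
  expect_identical(count_beams(beam_geometry(100, 10000, 10)), 1L)

  # brute-force placement scan: the largest m whose m full CTC periods fit
  # inside the field
  scan_count <- function(g) {
    m <- 0L
    while ((m + 1L) * g$ctc_um <= g$field_mm * 1000) m <- m + 1L
    m
  }
  set.seed(101)
  for (i in 1:1000) {
    bw <- runif(1, 10, 600)
    ctc <- bw + runif(1, 10, 3000)
    fw <- runif(1, ctc / 1000, 30)
    g <- beam_geometry(bw, ctc, fw)
    expect_identical(count_beams(g), scan_count(g))
  }
})

test_that("ideal profiles have the configured peak, valley and beam fill", {
  p <- build_ideal_profile(mrt_geometry(), peak_gy = 470, pvdr = 20)
  expect_equal(max(p$doses), 470)
  expect_equal(min(p$doses), 23.5)
  expect_equal(profile_pvdr(p), 20, tolerance = 1e-12)

  # pvdr -> 1 limit: uniform field
  u <- build_ideal_profile(mrt_geometry(), peak_gy = 12, pvdr = 1)
  expect_true(all(u$doses == 12))

  # fraction of samples at peak dose for the minibeam geometry: 500/2000 =
  # 0.25, up to one grid cell per beam edge; cross-checked against an
  # independent per-sample membership scan
  g <- mbrt_geometry()
  res <- 25
  p2 <- build_ideal_profile(g, 400, 20, resolution_um = res)
  frac <- mean(p2$doses == 400)
  n_beams <- 5
  cell <- (res / 1000) / (g$field_mm + res / 1000)
  expect_lt(abs(frac - 0.25), (2 * n_beams + 1) * cell)
  centers <- (seq_len(n_beams) - 3) * 2       # mm
  in_beam <- vapply(p2$positions, function(x)
    any(abs(x - centers) <= 0.25 + 1e-12), logical(1))
  expect_identical(p2$doses == 400, in_beam)
})

test_that("too-coarse sampling is rejected by name", {
  expect_error(build_ideal_profile(mrt_geometry(), 470, 20,
                                   resolution_um = 20),
               "beam_width / 5")
})

test_that("profile_pvdr is max over min and rejects a zero valley", {
  set.seed(7)
  d <- runif(50, 1, 100)
  prof <- dose_profile(seq_along(d), d)
  expect_equal(profile_pvdr(prof), max(d) / min(d))
  expect_equal(profile_pvdr(dose_profile(1:5, rep(3, 5))), 1)
  expect_error(profile_pvdr(dose_profile(1:3, c(0, 1, 2))), "undefined")
})

test_that("lq_survival matches the closed form and is monotone", {
  lq <- lq_params(0.4460, 0.0115)
  expect_equal(lq_survival(0, lq), 1)
  expect_equal(lq_survival(20, lq), exp(-0.4460 * 20 - 0.0115 * 400))
  d <- seq(0, 100, by = 0.5)
  expect_true(all(diff(lq_survival(d, lq)) < 0))
})

test_that("EUD is the uniform dose on uniform fields and zero on zero dose", {
  lq <- lq_params()
  expect_equal(eud(dose_profile(seq(0, 1, 0.1), rep(20, 11)), lq), 20,
               tolerance = 1e-9)
  expect_equal(eud(dose_profile(c(0, 1), c(0, 0)), lq), 0)
})

test_that("EUD of the ideal MRT field matches a fine-grid numerical oracle", {
  lq <- lq_params(0.4460, 0.0115)
  p <- build_ideal_profile(mrt_geometry(), 470, 20)
  # oracle: independent 1 um grid, survival averaged directly at long-double
  # precision through the valley-dominated sum, quadratic inverted by uniroot
  pos <- seq(-5, 5, by = 0.001)
  centers <- (1:25 - 13) * 0.4
  in_beam <- vapply(pos, function(x)
    any(abs(x - centers) <= 0.025 + 1e-12), logical(1))
  doses <- ifelse(in_beam, 470, 23.5)
  sbar <- mean(exp(-lq$alpha * doses - lq$beta * doses^2))
  oracle <- uniroot(function(D) lq$alpha * D + lq$beta * D^2 + log(sbar),
                    c(0, 470), tol = 1e-10)$root
  expect_equal(eud(p, lq), oracle, tolerance = 0.05 / oracle)
})

test_that("EUD respects bounds, monotonicity and beta -> 0 continuity", {
  set.seed(42)
  for (i in 1:50) {
    d <- runif(40, 0, 60)
    prof <- dose_profile(seq_len(40), d)
    lq <- lq_params(runif(1, 0.05, 1), runif(1, 0, 0.05))
    e <- eud(prof, lq)
    expect_gte(e, min(d) - 1e-9)
    expect_lte(e, max(d) + 1e-9)
    bump <- dose_profile(seq_len(40), d + runif(40, 0, 5))
    expect_gte(eud(bump, lq), e - 1e-9)
  }
  prof <- build_ideal_profile(mbrt_geometry(), 100, 10)
  expect_equal(eud(prof, lq_params(0.3, 1e-12)),
               eud(prof, lq_params(0.3, 0)), tolerance = 1e-4)
})

test_that("EUD stays finite at extreme peak doses (log-space averaging)", {
  prof <- build_ideal_profile(mrt_geometry(), 5000, 20)
  e <- eud(prof, lq_params())
  expect_true(is.finite(e))
  expect_lte(e, 5000)
})

test_that("solve_peak_for_eud inverts eud and agrees with a bisection oracle", {
  lq <- lq_params(0.4460, 0.0115)
  g <- mrt_geometry()
  # pvdr -> 1 limit: a uniform field needs peak = target
  expect_equal(solve_peak_for_eud(g, 1, lq, 20), 20, tolerance = 1e-6)
  p <- solve_peak_for_eud(g, 20, lq, 20)
  expect_equal(eud(build_ideal_profile(g, p, 20), lq), 20, tolerance = 1e-6)
  # bisection oracle at 1e-9 tolerance
  f <- function(pk) eud(build_ideal_profile(g, pk, 20), lq) - 20
  lo <- 20; hi <- 1e4
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(p, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("dose profile CSV round-trips", {
  p <- build_ideal_profile(mbrt_geometry(), 418, 20)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_dose_profile(p, tf)
  q <- read_dose_profile(tf)
  expect_equal(q$positions, p$positions)
  expect_equal(q$doses, p$doses)
  expect_error(read_dose_profile({
    tf2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1:3, y = 1:3), tf2, row.names = FALSE)
    tf2
  }), "missing column")
})
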