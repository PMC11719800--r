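# Independent oracles and fixture builders shared across the suite.

# Hand-coded two-group Mantel-Cox chi-square (observed minus expected with
# hypergeometric variance, ties grouped), independent of survival::survdiff.
logrank_chi2_hand <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  o <- e <- v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Random valid regrowth parameter sets for property tests.
random_regrowth_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    regrowth_params(a1 = runif(1, 0, 0.99),
                    alpha1 = runif(1, 0.01, 0.5),
                    alpha2 = runif(1, 0.005, 0.2)))
}

# Noise-free mouse record sampled on the study schedule, truncated at the
# endpoint like a real animal.
noise_free_record <- function(params, v0 = 80, id = "m1", arm = "x",
                              endpoint_multiple = 3, cap = 90) {
  days <- measurement_schedule(followup_cap = cap)
  vol <- v0 * eval_regrowth(params, days)
  hit <- which(vol >= endpoint_multiple * v0)
  keep <- if (length(hit)) seq_len(hit[1]) else seq_along(days)
  mouse_record(id, arm, v0,
               data.frame(day = days[keep], volume_mm3 = vol[keep]),
               reached_endpoint = length(hit) > 0,
               last_followup_day = if (length(hit)) days[hit[1]] else cap)
}

# The study's four kinetics (control tripling in 33 d; treated delays
# 11.1 / 20.2 / 34.9 d), used by several files.
study_kinetics <- function() {
  list(control = regrowth_params(0, 0.1, 0.0332913),
       CRT = regrowth_params(0.6, 0.15, 0.045683),
       MBRT = regrowth_params(0.6, 0.15, 0.037873),
       MRT = regrowth_params(0.6, 0.15, 0.029674))
}
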