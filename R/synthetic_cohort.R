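#' Specification of one synthetic treatment arm
#'
#' Defaults mirror the study design this package models: 9 animals per arm,
#' enrollment volumes uniform in 60-100 mm^3, and multiplicative caliper
#' noise with a 15% coefficient of variation (the study reports no error
#' magnitude; 15% is a realistic caliper CV for ~100 mm^3 hind-leg
#' xenografts, since length x breadth^2 compounds per-axis reading error).
#'
#' @param arm Arm label.
#' @param params True [regrowth_params()] of the arm.
#' @param n Number of animals (default 9).
#' @param noise_cv Multiplicative coefficient of variation of observed
#'   volumes (default 0.15; 0 gives noise-free kinetics).
#' @param enrollment_range Length-2 vector, V0 range in mm^3 (default
#'   `c(60, 100)`).
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(arm, params, n = 9, noise_cv = 0.15,
                     enrollment_range = c(60, 100)) {
  stopifnot(inherits(params, "regrowth_params"), n >= 1, noise_cv >= 0,
            length(enrollment_range) == 2L,
            enrollment_range[1] > 0,
            enrollment_range[2] >= enrollment_range[1])
  structure(list(arm = as.character(arm), params = params, n = as.integer(n),
                 noise_cv = noise_cv, enrollment_range = enrollment_range),
            class = "arm_spec")
}

#' Study design for a synthetic cohort
#'
#' @param arms List of [arm_spec()] objects.
#' @param schedule_offsets Measurement weekdays as day-of-week offsets from
#'   the irradiation day; the default `c(0, 2, 4)` is a
#'   Monday/Wednesday/Friday pattern (three measurements per week). Day 0
#'   itself is not a follow-up measurement.
#' @param followup_cap Follow-up in days after irradiation (default 90).
#' @param endpoint_multiple Euthanasia threshold as a multiple of V0
#'   (default 3).
#' @param seed Integer seed; required, so cohorts are reproducible.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, schedule_offsets = c(0, 2, 4),
                         followup_cap = 90, endpoint_multiple = 3, seed) {
  stopifnot(is.list(arms), length(arms) >= 1,
            all(vapply(arms, inherits, logical(1), "arm_spec")),
            followup_cap > 0, endpoint_multiple > 1)
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  structure(list(arms = arms, schedule_offsets = schedule_offsets,
                 followup_cap = followup_cap,
                 endpoint_multiple = endpoint_multiple,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' The default four-arm study design
#'
#' Control (pure exponential growth tripling in 33 days) plus three treated
#' arms sharing the shrinkage component (a1 0.6, alpha1 0.15/d) with
#' regrowth rates chosen so the model-based growth delays are 11.1 (CRT),
#' 20.2 (MBRT) and 34.9 (MRT) days.
#'
#' @param seed Integer seed.
#' @param n Animals per arm (default 9).
#' @param noise_cv Caliper noise CV (default 0.15).
#' @return A [study_design()].
#' @export
default_study_design <- function(seed, n = 9, noise_cv = 0.15) {
  study_design(list(
    arm_spec("control", regrowth_params(0, 0.1, 0.0332913), n, noise_cv),
    arm_spec("CRT",  regrowth_params(0.6, 0.15, 0.045683), n, noise_cv),
    arm_spec("MBRT", regrowth_params(0.6, 0.15, 0.037873), n, noise_cv),
    arm_spec("MRT",  regrowth_params(0.6, 0.15, 0.029674), n, noise_cv)),
    seed = seed)
}

#' Measurement schedule
#'
#' @param schedule_offsets Day-of-week offsets (see [study_design()]).
#' @param followup_cap Last day.
#' @return Sorted vector of measurement days in `(0, followup_cap]`.
#' @export
measurement_schedule <- function(schedule_offsets = c(0, 2, 4),
                                 followup_cap = 90) {
  weeks <- seq(0, ceiling(followup_cap / 7)) * 7
  days <- sort(unique(as.vector(outer(weeks, schedule_offsets, `+`))))
  days[days > 0 & days <= followup_cap]
}

# Deterministic per-animal seed: a small polynomial hash of the animal's
# name (arm label + index) mixed with the study seed, mod 2^31 - 1, so the
# cohort is stable under arm reordering.
animal_seed <- function(seed, arm, index) {
  key <- paste0(arm, "#", index)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 2654435) %% 2147483647)
}

simulate_animal <- function(spec, design, index) {
  set.seed(animal_seed(design$seed, spec$arm, index))
  days <- measurement_schedule(design$schedule_offsets, design$followup_cap)
  v0 <- stats::runif(1, spec$enrollment_range[1], spec$enrollment_range[2])
  true <- v0 * eval_regrowth(spec$params, days)
  if (spec$noise_cv > 0) {
    s2 <- log(1 + spec$noise_cv^2)            # lognormal with mean 1, CV = noise_cv
    noise <- stats::rlnorm(length(days), meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else noise <- rep(1, length(days))
  obs <- true * noise
  hit <- which(obs >= design$endpoint_multiple * v0)
  if (length(hit)) {
    keep <- seq_len(hit[1])
    reached <- TRUE
    last_day <- days[hit[1]]
  } else {
    keep <- seq_along(days)
    reached <- FALSE
    last_day <- design$followup_cap
  }
  vol <- obs[keep]
  # caliper dimensions back-derived from volume at a fixed 1.5 aspect ratio,
  # so ellipsoid_volume(length, breadth) reproduces the simulated volume
  breadth <- (6 * vol / (pi * 1.5))^(1 / 3)
  m <- data.frame(day = days[keep], length_mm = 1.5 * breadth,
                  breadth_mm = breadth, volume_mm3 = vol)
  mouse_record(sprintf("%s-%02d", spec$arm, index), spec$arm, v0, m,
               reached_endpoint = reached, last_followup_day = last_day,
               endpoint_multiple = design$endpoint_multiple)
}

#' Generate a synthetic cohort
#'
#' For each animal: V0 is drawn uniformly from the arm's enrollment range;
#' the true volume follows `V0 * f(t)` under the arm's bi-exponential
#' parameters; the observed volume at each scheduled day is the true volume
#' times a mean-one lognormal factor with the arm's CV. The series is
#' truncated at the first day the *observed* volume reaches
#' `endpoint_multiple * V0` (the animal is flagged endpoint-reached,
#' mirroring caliper-triggered euthanasia and its selection effect), or
#' censored at the follow-up cap. Each animal has its own named random
#' substream derived from the study seed, so identical seeds give
#' bit-identical cohorts regardless of arm order.
#'
#' @param design A [study_design()].
#' @return List of [mouse_record()] objects.
#' @examples
#' cohort <- generate_cohort(default_study_design(seed = 1))
#' length(cohort)  # 36
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "study_design"))
  out <- list()
  for (spec in design$arms)
    for (i in seq_len(spec$n))
      out[[sprintf("%s-%02d", spec$arm, i)]] <-
        simulate_animal(spec, design, i)
  out
}

#' Flatten a cohort to the tidy measurement table
#'
#' @param cohort List of [mouse_record()]s from [generate_cohort()].
#' @return data.frame in the measurement-CSV dialect
#'   (`mouse_id, arm, day, length_mm, breadth_mm, volume_mm3, v0_mm3`).
#' @export
cohort_measurements <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    cbind(data.frame(mouse_id = r$mouse_id, arm = r$arm),
          r$measurements, v0_mm3 = r$v0, row.names = NULL)
  }))
}

#' Write a cohort to the measurement CSV dialect
#' @param cohort List of [mouse_record()]s.
#' @param path Output CSV path.
#' @export
write_measurements <- function(cohort, path) {
  utils::write.csv(cohort_measurements(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Ct values are drawn from Normal(20, `ref_sd`); each
#' target-gene Ct is the sample's mean reference Ct plus a baseline dCt,
#' minus `log2(true fold)`, plus Normal(0, `noise_sd`) technical noise, so
#' the 2^-ddCt pipeline recovers the configured fold changes (exactly when
#' both SDs are 0).
#'
#' @param groups Character vector of group labels; the first is the control
#'   unless `control_group` says otherwise, and its true fold is forced
#'   to 1.
#' @param true_folds Named list, one entry per target gene, each a named
#'   numeric vector of true fold changes per group.
#' @param n_per_group Biological replicates per group (default 4).
#' @param seed Integer seed.
#' @param reference_genes Endogenous control genes (default GAPDH, B2M,
#'   ACTB).
#' @param control_group Control group label (default `groups[1]`).
#' @param baseline_dct Baseline dCt of each target in the control group
#'   (default 5 cycles).
#' @param ref_sd SD of reference Ct values (default 0.3 cycles).
#' @param noise_sd SD of target Ct noise (default 0.3 cycles).
#' @return A Ct data.frame (`sample_id, group, gene, ct`).
#' @export
generate_ct_table <- function(groups, true_folds, n_per_group = 4, seed,
                              reference_genes = c("GAPDH", "B2M", "ACTB"),
                              control_group = groups[1], baseline_dct = 5,
                              ref_sd = 0.3, noise_sd = 0.3) {
  stopifnot(is.list(true_folds), length(true_folds) >= 1)
  if (missing(seed)) stop("a seed is required")
  for (g in names(true_folds)) {
    if (any(true_folds[[g]] <= 0)) stop("true folds must be positive")
    true_folds[[g]][control_group] <- 1
  }
  set.seed(as.integer(seed) %% 2147483647)
  rows <- list()
  for (grp in groups) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s-r%d", grp, i)
      ref_ct <- stats::rnorm(length(reference_genes), 20, ref_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = grp, gene = reference_genes, ct = ref_ct)
      for (g in names(true_folds)) {
        fold <- true_folds[[g]][[grp]]
        ct <- mean(ref_ct) + baseline_dct - log2(fold) +
          stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp, gene = g, ct = ct)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
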