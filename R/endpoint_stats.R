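#' Tumor growth-delay statistics for one treated arm
#'
#' The growth delay of a treated animal is its growth (tripling) time minus
#' the mean growth time of the untreated controls. Per arm the function
#' reports the mean delay, its SD, the half-width of the t-based 95%
#' confidence interval of the mean (`qt(0.975, n - 1) * sd / sqrt(n)`), and
#' two p-values: a one-sample t-test of the per-mouse delays against zero
#' and a two-sample pooled t-test of treated vs. control growth times. (The
#' two coincide in the balanced noise-free limit; both are reported because
#' either reading of "compared to controls" is defensible.)
#'
#' Censored animals (`NA` growth times) are excluded and counted in
#' `n_censored`.
#'
#' @param treated_times Growth times (days) of the treated arm; `NA` =
#'   censored.
#' @param control_times Growth times (days) of the control arm.
#' @param arm Label for the treated arm.
#' @return A list of class `delay_result`: `arm`, `per_mouse_delays`,
#'   `mean_delay`, `sd`, `ci95_halfwidth`, `n`, `n_censored`,
#'   `p_delay_vs_zero`, `p_vs_control`.
#' @export
growth_delay <- function(treated_times, control_times, arm = "") {
  if (!length(treated_times) || !length(control_times))
    stop("both treated and control growth times must be nonempty")
  n_censored <- sum(is.na(treated_times))
  treated <- treated_times[!is.na(treated_times)]
  control <- control_times[!is.na(control_times)]
  if (!length(control)) stop("all control growth times are censored")
  if (!length(treated)) {
    return(structure(list(arm = arm, per_mouse_delays = numeric(0),
                          mean_delay = NA_real_, sd = NA_real_,
                          ci95_halfwidth = NA_real_, n = 0L,
                          n_censored = n_censored,
                          p_delay_vs_zero = NA_real_,
                          p_vs_control = NA_real_),
                     class = "delay_result"))
  }
  delays <- treated - mean(control)
  n <- length(delays)
  s <- stats::sd(delays)
  ci <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
  p_zero <- if (n > 1 && s > 0)
    tryCatch(unpaired_style_one_sample_p(delays),
             error = function(e) if (abs(mean(delays)) < 1e-12) 1 else 0)
  else NA_real_
  p_two <- if (n > 1 && length(control) > 1)
    tryCatch(unpaired_t_test(treated, control)$p,
             error = function(e)
               if (abs(mean(treated) - mean(control)) < 1e-12) 1 else 0)
  else NA_real_
  structure(list(arm = arm, per_mouse_delays = delays,
                 mean_delay = mean(delays), sd = s, ci95_halfwidth = ci,
                 n = n, n_censored = n_censored,
                 p_delay_vs_zero = p_zero, p_vs_control = p_two),
            class = "delay_result")
}

unpaired_style_one_sample_p <- function(x) {
  stats::t.test(x, mu = 0)$p.value
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf("<delay_result %s: %.1f +/- %.1f d (95%% CI half-width %.1f), n = %d (%d censored), p vs control = %.3g>\n",
              x$arm, x$mean_delay, x$sd, x$ci95_halfwidth, x$n,
              x$n_censored, x$p_vs_control))
  invisible(x)
}

#' Two-sample unpaired t-test
#'
#' Classic pooled-variance (Student) two-sample test by default, the test
#' the growth-delay comparison uses; Welch's unequal-variance flavor is
#' available behind `welch = TRUE`. Degenerate zero-variance inputs are
#' resolved explicitly: identical constant samples give `t = 0, p = 1`;
#' constant samples with different means give `p = 0` (infinite t).
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return A list with `t`, `p`, and `df`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  res <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                  error = function(e) NULL)
  if (is.null(res)) {  # numerically constant data
    same <- abs(mean(a) - mean(b)) < 1e-12 * max(1, abs(mean(a)))
    return(list(t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                p = if (same) 1 else 0,
                df = length(a) + length(b) - 2))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Kaplan-Meier progression-free-survival estimate
#'
#' Product-limit estimator with right censoring, via [survival::survfit()].
#' The median is the smallest event time at which the survival estimate
#' drops to 0.5 or below, `NA` if never reached.
#'
#' @param records data.frame with columns `time` (days, > 0) and `event`
#'   (1 = regrowth started, 0 = censored); optionally `mouse_id`, `arm`.
#' @return A list of class `km_curve`: `times`, `survival`, `at_risk`,
#'   `n_events`, `median`, `n`.
#' @export
km_estimate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (!nrow(records)) stop("records must be nonempty")
  if (any(records$time <= 0)) stop("times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                          conf.type = "none")
  s <- summary(sf, censored = TRUE)
  med <- {
    drop <- s$time[s$surv <= 0.5 + 1e-12]
    if (length(drop)) min(drop) else NA_real_
  }
  structure(list(times = s$time, survival = s$surv, at_risk = s$n.risk,
                 n_events = s$n.event, median = med, n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n = %d, %d events, median PFS %s d>\n",
              x$n, sum(x$n_events),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Mantel-Cox log-rank test between two arms
#'
#' Sums observed-minus-expected events over the distinct event times
#' (standard hypergeometric variance, ties grouped), giving a chi-square
#' statistic with 1 df; computed with [survival::survdiff()]. Strata, when
#' supplied, are combined by summing the per-stratum contributions; with no
#' (or a single) stratum this is the plain Mantel-Cox test — the default,
#' since the study names no stratification factor.
#'
#' @param a,b data.frames of survival records (`time`, `event`) for the two
#'   arms.
#' @param strata Optional vector of stratum labels, one per record of
#'   `rbind(a, b)`.
#' @param labels Length-2 character vector naming the arms.
#' @return A list of class `logrank_result`: `chi2`, `p`, `groups`.
#' @export
logrank_test <- function(a, b, strata = NULL, labels = c("a", "b")) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (!nrow(a) || !nrow(b)) stop("both groups must be nonempty")
  dat <- rbind(a[c("time", "event")], b[c("time", "event")])
  dat$group <- rep(labels, c(nrow(a), nrow(b)))
  if (sum(dat$event) == 0)
    stop("log-rank test undefined with zero events")
  if (is.null(strata)) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  } else {
    stopifnot(length(strata) == nrow(dat))
    dat$stratum <- strata
    sd <- survival::survdiff(
      survival::Surv(time, event) ~ group + survival::strata(stratum),
      data = dat)
  }
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 groups = labels),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank %s vs %s: chi2 = %.3f, p = %.4g>\n",
              x$groups[1], x$groups[2], x$chi2, x$p))
  invisible(x)
}

#' Build the progression-free-survival dataset from per-mouse fits
#'
#' PFS time is the model-defined regrowth-start day (the first measurement
#' day after the fitted curve's global minimum). A mouse whose regrowth
#' starts on or before the follow-up cap contributes an event; otherwise it
#' is censored at `min(last_followup_day, cap)`.
#'
#' @param fits Named list of [fit_regrowth()] results keyed by mouse id, or
#'   a data.frame with columns `mouse_id`, `arm`, `regrowth_start_day`
#'   (`NA` = censored) and `last_followup_day`.
#' @param arms Optional character vector of arm labels parallel to `fits`
#'   when `fits` is a list.
#' @param last_followup Optional numeric vector of last follow-up days
#'   parallel to `fits` when `fits` is a list (defaults to the cap).
#' @param followup_cap Follow-up cap in days (default 90).
#' @return data.frame with columns `mouse_id`, `arm`, `time`, `event`.
#' @export
build_pfs_dataset <- function(fits, arms = NULL, last_followup = NULL,
                              followup_cap = 90) {
  if (is.data.frame(fits)) {
    df <- fits
    stopifnot(all(c("mouse_id", "arm", "regrowth_start_day") %in% names(df)))
    if (is.null(df$last_followup_day)) df$last_followup_day <- followup_cap
  } else {
    ids <- names(fits)
    if (is.null(ids)) ids <- as.character(seq_along(fits))
    df <- data.frame(
      mouse_id = ids,
      arm = if (is.null(arms)) "" else arms,
      regrowth_start_day = vapply(fits, function(f) {
        d <- f$regrowth_start_day
        if (is.null(d)) NA_real_ else as.numeric(d)
      }, numeric(1)),
      last_followup_day = if (is.null(last_followup)) followup_cap
                          else last_followup)
  }
  ev <- !is.na(df$regrowth_start_day) &
    df$regrowth_start_day <= followup_cap
  data.frame(
    mouse_id = df$mouse_id,
    arm = df$arm,
    time = ifelse(ev, df$regrowth_start_day,
                  pmin(df$last_followup_day, followup_cap)),
    event = as.integer(ev),
    row.names = NULL)
}

#' Pairwise log-rank matrix across arms
#'
#' Runs [logrank_test()] for every unordered pair of arms in a PFS dataset.
#' Raw p-values are reported (matching the study's pairwise comparisons);
#' Holm adjustment is available behind `adjust = "holm"`.
#'
#' @param records data.frame with columns `arm`, `time`, `event`.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per pair: `arm1`, `arm2`, `chi2`, `p`
#'   (and `p_adj` when adjusted).
#' @export
pairwise_logrank <- function(records, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  arms <- unique(records$arm)
  if (length(arms) < 2L) stop("need at least two arms")
  pairs <- utils::combn(arms, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- records[records$arm == pairs[1, i], , drop = FALSE]
    b <- records[records$arm == pairs[2, i], , drop = FALSE]
    lr <- logrank_test(a, b, labels = pairs[, i])
    data.frame(arm1 = pairs[1, i], arm2 = pairs[2, i],
               chi2 = lr$chi2, p = lr$p)
  }))
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}
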