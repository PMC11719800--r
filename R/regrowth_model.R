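#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = (pi / 6) * length * breadth^2` in mm^3, the standard caliper formula
#' for subcutaneous xenografts. By caliper convention the breadth is the
#' smaller axis; if `breadth > length` the two are swapped with a warning.
#'
#' @param length_mm Longest tumor axis in mm.
#' @param breadth_mm Perpendicular (smaller) axis in mm.
#' @return Volume(s) in mm^3, vectorized.
#' @examples
#' ellipsoid_volume(8, 6)
#' @export
ellipsoid_volume <- function(length_mm, breadth_mm) {
  stopifnot(is.numeric(length_mm), is.numeric(breadth_mm))
  if (any(length_mm <= 0) || any(breadth_mm <= 0))
    stop("caliper measurements must be positive")
  swap <- breadth_mm > length_mm
  if (any(swap)) {
    warning("breadth > length for ", sum(swap),
            " measurement(s); axes swapped (breadth is the smaller axis)")
    tmp <- length_mm[swap]
    length_mm[swap] <- breadth_mm[swap]
    breadth_mm[swap] <- tmp
  }
  pi / 6 * length_mm * breadth_mm^2
}

#' Bi-exponential regrowth parameters
#'
#' The normalized tumor-volume curve after irradiation is modeled as
#' `f(t) = V(t)/V0 = a1 * exp(-alpha1 * t) + a2 * exp(alpha2 * t)` with
#' `a1 + a2 = 1` and all parameters non-negative (`a2`, `alpha1`, `alpha2`
#' strictly positive). The shrinking term represents the lethally irradiated
#' cell fraction, the growing term the surviving proliferating fraction;
#' the constraint pins `f(0) = 1`.
#'
#' @param a1 Shrinking fraction, in `[0, 1)`; `a2` is `1 - a1`.
#' @param alpha1 Shrinkage rate in 1/day (> 0).
#' @param alpha2 Regrowth rate in 1/day (> 0).
#' @return An object of class `regrowth_params` with fields
#'   `a1, a2, alpha1, alpha2`.
#' @export
regrowth_params <- function(a1, alpha1, alpha2) {
  stopifnot(is.numeric(a1), is.numeric(alpha1), is.numeric(alpha2),
            length(a1) == 1L, length(alpha1) == 1L, length(alpha2) == 1L)
  if (a1 < 0 || a1 >= 1) stop("a1 must be in [0, 1) so that a2 = 1 - a1 > 0")
  if (alpha1 <= 0) stop("alpha1 must be > 0")
  if (alpha2 <= 0) stop("alpha2 must be > 0")
  structure(list(a1 = a1, a2 = 1 - a1, alpha1 = alpha1, alpha2 = alpha2),
            class = "regrowth_params")
}

#' @export
print.regrowth_params <- function(x, ...) {
  cat(sprintf("<regrowth_params: a1 = %.4g, a2 = %.4g, alpha1 = %.4g /d, alpha2 = %.4g /d>\n",
              x$a1, x$a2, x$alpha1, x$alpha2))
  invisible(x)
}

#' Evaluate the bi-exponential regrowth curve
#'
#' @param params A [regrowth_params()] object.
#' @param t Days since irradiation (>= 0), vectorized.
#' @return Normalized volume ratio `V(t)/V0`; equals 1 at `t = 0`.
#' @export
eval_regrowth <- function(params, t) {
  stopifnot(inherits(params, "regrowth_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  params$a1 * exp(-params$alpha1 * t) + params$a2 * exp(params$alpha2 * t)
}

#' Time of the curve's global minimum
#'
#' Setting the derivative of the regrowth curve to zero gives the unique
#' stationary point `t = log(a1 * alpha1 / (a2 * alpha2)) / (alpha1 + alpha2)`,
#' which lies at positive time iff `a1 * alpha1 > a2 * alpha2`; otherwise the
#' curve increases monotonically on `t >= 0` and the minimum is at 0.
#'
#' @param params A [regrowth_params()] object.
#' @return Day of the global minimum (0 for monotone growth).
#' @export
global_min_time <- function(params) {
  stopifnot(inherits(params, "regrowth_params"))
  num <- params$a1 * params$alpha1
  den <- params$a2 * params$alpha2
  if (num <= den) return(0)
  log(num / den) / (params$alpha1 + params$alpha2)
}

#' Regrowth-start day
#'
#' Regrowth is said to start the day after the fitted curve's global
#' minimum; since tumors are only observed on measurement days, this is the
#' smallest scheduled measurement day strictly after `t_min`. When the curve
#' is monotone (`t_min = 0`) the first post-irradiation measurement day is
#' returned. If no measurement day follows `t_min`, the animal never shows
#' regrowth within follow-up and `NA` (censored) is returned.
#'
#' @param fit A [fit_regrowth()] result, a [regrowth_params()] object, or a
#'   numeric `t_min` in days.
#' @param measurement_days Scheduled measurement days (positive, sorted).
#' @return The regrowth-start day, or `NA_real_` if censored.
#' @export
regrowth_start <- function(fit, measurement_days) {
  t_min <-
    if (inherits(fit, "regrowth_fit")) fit$t_min
    else if (inherits(fit, "regrowth_params")) global_min_time(fit)
    else if (is.numeric(fit) && length(fit) == 1L) fit
    else stop("fit must be a regrowth_fit, regrowth_params or numeric t_min")
  if (!length(measurement_days)) stop("measurement_days must be nonempty")
  after <- measurement_days[measurement_days > t_min]
  if (!length(after)) return(NA_real_)
  min(after)
}

#' One animal's longitudinal record
#'
#' @param mouse_id Identifier.
#' @param arm Treatment arm label (e.g. `"control"`, `"CRT"`, `"MBRT"`,
#'   `"MRT"`).
#' @param v0 Volume at irradiation in mm^3 (> 0).
#' @param measurements data.frame with column `day` (days since
#'   irradiation, strictly increasing) and either `volume_mm3` or the
#'   caliper pair `length_mm`/`breadth_mm` (volume is then derived with
#'   [ellipsoid_volume()]).
#' @param reached_endpoint Logical: did the animal reach the 3 x V0
#'   euthanasia endpoint? If so the final recorded volume must be at least
#'   `endpoint_multiple * v0` and no measurement may follow it.
#' @param last_followup_day Last day of follow-up (endpoint day, or the
#'   follow-up cap for censored animals).
#' @param endpoint_multiple Endpoint threshold as a multiple of `v0`
#'   (default 3).
#' @return An object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, arm, v0, measurements,
                         reached_endpoint = FALSE,
                         last_followup_day = NULL,
                         endpoint_multiple = 3) {
  stopifnot(is.data.frame(measurements), "day" %in% names(measurements))
  if (v0 <= 0) stop("v0 must be > 0")
  if (is.null(measurements$volume_mm3)) {
    if (!all(c("length_mm", "breadth_mm") %in% names(measurements)))
      stop("measurements need volume_mm3 or length_mm + breadth_mm")
    measurements$volume_mm3 <-
      ellipsoid_volume(measurements$length_mm, measurements$breadth_mm)
  }
  if (any(measurements$volume_mm3 <= 0)) stop("volumes must be positive")
  if (is.unsorted(measurements$day, strictly = TRUE))
    stop("measurement days must be strictly increasing")
  n <- nrow(measurements)
  if (isTRUE(reached_endpoint)) {
    if (measurements$volume_mm3[n] < endpoint_multiple * v0)
      stop("reached_endpoint is set but the final volume is below ",
           endpoint_multiple, " x v0")
  }
  if (is.null(last_followup_day)) last_followup_day <- measurements$day[n]
  if (isTRUE(reached_endpoint) && any(measurements$day > last_followup_day))
    stop("measurements recorded after the endpoint (euthanasia) day")
  structure(list(mouse_id = as.character(mouse_id), arm = as.character(arm),
                 v0 = v0, measurements = measurements,
                 reached_endpoint = isTRUE(reached_endpoint),
                 last_followup_day = last_followup_day,
                 endpoint_multiple = endpoint_multiple),
            class = "mouse_record")
}

#' @export
print.mouse_record <- function(x, ...) {
  cat(sprintf("<mouse_record %s [%s]: V0 %.1f mm3, %d measurements to day %g%s>\n",
              x$mouse_id, x$arm, x$v0, nrow(x$measurements),
              x$last_followup_day,
              if (x$reached_endpoint) ", endpoint reached" else ", censored"))
  invisible(x)
}

# deterministic multi-start grid for the constrained least-squares fit
default_fit_starts <- function() {
  expand.grid(a1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
              alpha1 = c(0.03, 0.1, 0.3),
              alpha2 = c(0.01, 0.03, 0.06))
}

fit_regrowth_points <- function(days, ratios, starts = default_fit_starts()) {
  stopifnot(length(days) == length(ratios))
  lower <- c(0, 1e-4, 1e-4)
  upper <- c(1 - 1e-6, 1, 1)
  sse_fun <- function(p) {
    f <- p[1] * exp(-p[2] * days) + (1 - p[1]) * exp(p[3] * days)
    sum((f - ratios)^2)
  }
  # analytic gradient: the late-time ratios respond exponentially to alpha2,
  # so finite-difference gradients are far too coarse in that direction
  sse_grad <- function(p) {
    e1 <- exp(-p[2] * days)
    e2 <- exp(p[3] * days)
    r2 <- 2 * (p[1] * e1 + (1 - p[1]) * e2 - ratios)
    c(sum(r2 * (e1 - e2)),
      sum(r2 * (-p[1] * days * e1)),
      sum(r2 * ((1 - p[1]) * days * e2)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), sse_fun, sse_grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("regrowth fit failed from every start of the multi-start grid")
  best
}

#' Fit the constrained bi-exponential regrowth model
#'
#' Minimizes the sum of squared residuals between `f(t)` and the normalized
#' volumes `V(t)/V0` on the post-irradiation measurements, subject to the
#' [regrowth_params()] constraints. `a2` is eliminated as `1 - a1` so the
#' normalization holds exactly; `a1` is bounded to `[0, 1 - 1e-6]` and both
#' rates to `[1e-4, 1]` per day. A deterministic multi-start grid
#' (`a1` in \{0.1, 0.3, 0.5, 0.7, 0.9\}, `alpha1` in \{0.03, 0.1, 0.3\},
#' `alpha2` in \{0.01, 0.03, 0.06\}) of bounded L-BFGS-B local searches
#' guards against the model's local minima; the lowest objective is kept,
#' so identical inputs always give identical fits.
#'
#' Pre-irradiation measurements (`day <= 0`) are excluded, and no `f(0) = 1`
#' pseudo-point is added: the constraint already enforces it.
#'
#' @param record A [mouse_record()], or a data.frame with columns `day` and
#'   `ratio` (normalized volume) for pooled fitting.
#' @param v0 Ignored for a `mouse_record`; required only when `record` is a
#'   data.frame of raw volumes (column `volume_mm3`) instead of ratios.
#' @param starts Multi-start grid, a data.frame with columns
#'   `a1, alpha1, alpha2`.
#' @return An object of class `regrowth_fit`: `params` ([regrowth_params()]),
#'   `sse`, `t_min` (day of the model's global minimum),
#'   `regrowth_start_day` (next measurement day after `t_min`; `NA` if
#'   censored), `n_points`, and `measurement_days`.
#' @examples
#' truth <- regrowth_params(0.6, 0.15, 0.045683)
#' days <- seq(2, 60, by = 2)
#' fit <- fit_regrowth(data.frame(day = days, ratio = eval_regrowth(truth, days)))
#' fit$params
#' @export
fit_regrowth <- function(record, v0 = NULL, starts = default_fit_starts()) {
  if (inherits(record, "mouse_record")) {
    m <- record$measurements
    days <- m$day
    ratios <- m$volume_mm3 / record$v0
  } else if (is.data.frame(record)) {
    days <- record$day
    if (!is.null(record$ratio)) ratios <- record$ratio
    else if (!is.null(record$volume_mm3)) {
      if (is.null(v0)) stop("v0 is required to normalize raw volumes")
      ratios <- record$volume_mm3 / v0
    } else stop("data.frame input needs a ratio or volume_mm3 column")
  } else stop("record must be a mouse_record or a data.frame")
  keep <- days > 0
  days <- days[keep]; ratios <- ratios[keep]
  if (length(days) < 4L)
    stop("insufficient data: the 3-parameter fit needs >= 4 post-irradiation measurements, got ",
         length(days))
  best <- fit_regrowth_points(days, ratios, starts)
  params <- regrowth_params(best$par[1], best$par[2], best$par[3])
  t_min <- global_min_time(params)
  structure(list(params = params, sse = best$value, t_min = t_min,
                 regrowth_start_day = regrowth_start(t_min, days),
                 n_points = length(days), measurement_days = days,
                 convergence = best$convergence),
            class = "regrowth_fit")
}

#' @export
print.regrowth_fit <- function(x, ...) {
  cat(sprintf("<regrowth_fit: a1 %.4g, alpha1 %.4g, alpha2 %.4g; sse %.3g on %d points; t_min %.2f d; regrowth starts day %s>\n",
              x$params$a1, x$params$alpha1, x$params$alpha2, x$sse,
              x$n_points, x$t_min,
              if (is.na(x$regrowth_start_day)) "NA (censored)"
              else format(x$regrowth_start_day)))
  invisible(x)
}

#' Tumor tripling time
#'
#' Time for a tumor to reach three times (generally `endpoint_multiple`
#' times) its volume at irradiation.
#'
#' * `method = "raw"` (default): first crossing of the piecewise-linear
#'   interpolant of the recorded `(day, V/V0)` points, matching the study's
#'   definition of growth time from recorded volumes. The known ratio 1 at
#'   day 0 anchors a crossing that happens before the first measurement.
#' * `method = "model"`: smallest `t` with `eval_regrowth(params, t) ==
#'   endpoint_multiple`, located by bracketed bisection to 1e-6 days; the
#'   curve is monotone beyond its global minimum so the crossing is unique.
#'
#' @param record A [mouse_record()]; for `method = "model"` a
#'   [regrowth_params()] or [fit_regrowth()] object may be given instead.
#' @param method `"raw"` or `"model"`.
#' @param fit Optional [fit_regrowth()] (or [regrowth_params()]) supplying
#'   the model for `method = "model"` when `record` is a `mouse_record`.
#' @param endpoint_multiple Threshold multiple of `v0` (default 3).
#' @param max_days Search horizon for the model-based crossing.
#' @return Tripling time in days, or `NA_real_` if the threshold is never
#'   reached (censored).
#' @export
tripling_time <- function(record, method = c("raw", "model"), fit = NULL,
                          endpoint_multiple = 3, max_days = 1e4) {
  method <- match.arg(method)
  if (method == "model") {
    params <-
      if (inherits(record, "regrowth_params")) record
      else if (inherits(record, "regrowth_fit")) record$params
      else if (inherits(fit, "regrowth_fit")) fit$params
      else if (inherits(fit, "regrowth_params")) fit
      else stop("model-based tripling time needs a fit or regrowth_params")
    g <- function(t) eval_regrowth(params, t) - endpoint_multiple
    if (g(max_days) < 0) return(NA_real_)
    lo <- global_min_time(params)
    if (g(lo) >= 0) return(lo)  # threshold below the starting ratio
    return(stats::uniroot(g, c(lo, max_days), tol = 1e-6)$root)
  }
  stopifnot(inherits(record, "mouse_record"))
  m <- record$measurements[record$measurements$day > 0, , drop = FALSE]
  if (!nrow(m)) return(NA_real_)
  day <- c(0, m$day)
  ratio <- c(1, m$volume_mm3 / record$v0)
  thr <- endpoint_multiple
  for (i in seq_len(length(day) - 1L)) {
    if (ratio[i] < thr && ratio[i + 1L] >= thr) {
      return(day[i] + (thr - ratio[i]) / (ratio[i + 1L] - ratio[i]) *
               (day[i + 1L] - day[i]))
    }
  }
  NA_real_
}

#' Read a longitudinal measurement CSV
#'
#' Dialect: header `mouse_id,arm,day,length_mm,breadth_mm[,volume_mm3]`;
#' if `volume_mm3` is absent it is derived with [ellipsoid_volume()]. `v0`
#' for each animal is taken from a `v0_mm3` column when present, otherwise
#' from the last measurement at `day <= 0`.
#'
#' @param path CSV file path.
#' @param endpoint_multiple Endpoint threshold multiple (default 3).
#' @return A list of [mouse_record()] objects, one per `mouse_id`.
#' @export
read_measurements <- function(path, endpoint_multiple = 3) {
  df <- utils::read.csv(path)
  need <- c("mouse_id", "arm", "day")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement CSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$volume_mm3)) {
    if (!all(c("length_mm", "breadth_mm") %in% names(df)))
      stop("measurement CSV needs volume_mm3 or length_mm + breadth_mm")
    df$volume_mm3 <- ellipsoid_volume(df$length_mm, df$breadth_mm)
  }
  lapply(split(df, df$mouse_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    v0 <- if (!is.null(d$v0_mm3)) d$v0_mm3[1]
          else if (any(d$day <= 0)) utils::tail(d$volume_mm3[d$day <= 0], 1)
          else stop("no v0_mm3 column and no pre-irradiation measurement for mouse ",
                    d$mouse_id[1])
    post <- d[d$day > 0, , drop = FALSE]
    reached <- nrow(post) > 0 &&
      post$volume_mm3[nrow(post)] >= endpoint_multiple * v0
    mouse_record(d$mouse_id[1], d$arm[1], v0, post,
                 reached_endpoint = reached,
                 endpoint_multiple = endpoint_multiple)
  })
}
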