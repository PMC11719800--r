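#' Collimator beam geometry for a spatially fractionated field
#'
#' Describes a planar multislit SFRT field by its beam width, center-to-center
#' (CTC) spacing and field width. The microbeam (MRT) collimator of the study
#' this package models uses 50 um beams at 400 um CTC; the minibeam (MBRT)
#' collimator 500 um beams at 2000 um CTC, both over a 10 x 10 mm field.
#'
#' @param beam_width_um Beam (slit) width in micrometres; must be positive.
#' @param ctc_um Center-to-center distance between adjacent beams in
#'   micrometres; must exceed `beam_width_um` and fit inside the field.
#' @param field_mm Field width in millimetres.
#' @param label Free-text modality label (e.g. `"MRT"`, `"MBRT"`).
#' @return An object of class `beam_geometry`.
#' @examples
#' mrt_geometry()
#' beam_geometry(500, 2000, 10, "MBRT")
#' @export
beam_geometry <- function(beam_width_um, ctc_um, field_mm, label = "") {
  stopifnot(is.numeric(beam_width_um), length(beam_width_um) == 1L,
            is.numeric(ctc_um), length(ctc_um) == 1L,
            is.numeric(field_mm), length(field_mm) == 1L)
  if (beam_width_um <= 0) stop("beam_width_um must be > 0")
  if (ctc_um <= beam_width_um) stop("ctc_um must exceed beam_width_um")
  if (field_mm <= 0) stop("field_mm must be > 0")
  if (ctc_um > field_mm * 1000) stop("ctc_um must not exceed the field width")
  structure(list(beam_width_um = beam_width_um, ctc_um = ctc_um,
                 field_mm = field_mm, label = as.character(label)),
            class = "beam_geometry")
}

#' @rdname beam_geometry
#' @export
mrt_geometry <- function() beam_geometry(50, 400, 10, "MRT")

#' @rdname beam_geometry
#' @export
mbrt_geometry <- function() beam_geometry(500, 2000, 10, "MBRT")

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry %s: %g um beams, CTC %g um, field %g mm, %d beams>\n",
              if (nzchar(x$label)) x$label else "?", x$beam_width_um,
              x$ctc_um, x$field_mm, count_beams(x)))
  invisible(x)
}

#' Number of beams in a field
#'
#' Beams are placed on a grid of spacing `ctc_um`, centered symmetrically in
#' the field; a beam is counted iff its center lies within the field. This
#' reduces to `floor(field_mm * 1000 / ctc_um)` and reproduces the 25
#' microbeams / 5 minibeams of the 10 mm study field.
#'
#' @param geometry A [beam_geometry()].
#' @return Integer beam count.
#' @examples
#' count_beams(mrt_geometry())  # 25
#' count_beams(mbrt_geometry()) # 5
#' @export
count_beams <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  as.integer(floor(geometry$field_mm * 1000 / geometry$ctc_um))
}

#' Linear-quadratic cell-survival parameters
#'
#' @param alpha Linear coefficient in 1/Gy; must be positive. The A549 value
#'   used throughout the study is 0.4460.
#' @param beta Quadratic coefficient in 1/Gy^2; non-negative. A549: 0.0115.
#' @return An object of class `lq_params`.
#' @export
lq_params <- function(alpha = 0.4460, beta = 0.0115) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta), class = "lq_params")
}

#' Linear-quadratic survival fraction
#'
#' `S(D) = exp(-alpha * D - beta * D^2)`, vectorized over dose.
#'
#' @param dose Dose(s) in Gy, each >= 0.
#' @param lq An [lq_params()] object.
#' @return Survival fraction(s) in (0, 1].
#' @export
lq_survival <- function(dose, lq = lq_params()) {
  stopifnot(inherits(lq, "lq_params"), is.numeric(dose))
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-lq$alpha * dose - lq$beta * dose^2)
}

new_dose_profile <- function(positions, doses) {
  structure(list(positions = positions, doses = doses), class = "dose_profile")
}

#' Sampled 1-D lateral dose profile
#'
#' A `dose_profile` holds a strictly increasing regular position grid (mm)
#' and the dose (Gy) at each position. Construct one from geometry with
#' [build_ideal_profile()] or from a CSV with [read_dose_profile()].
#'
#' @param positions Regular, strictly increasing grid in mm.
#' @param doses Non-negative doses in Gy, same length as `positions`.
#' @return An object of class `dose_profile`.
#' @export
dose_profile <- function(positions, doses) {
  stopifnot(is.numeric(positions), is.numeric(doses))
  if (length(positions) != length(doses))
    stop("positions and doses must have the same length")
  if (length(positions) < 2L) stop("a profile needs at least 2 samples")
  dp <- diff(positions)
  if (any(dp <= 0)) stop("positions must be strictly increasing")
  # regular grid to within 1 ppm
  if ((max(dp) - min(dp)) > 1e-6 * mean(dp))
    stop("positions must form a regular grid")
  if (any(doses < 0)) stop("doses must be >= 0")
  new_dose_profile(as.numeric(positions), as.numeric(doses))
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile: %d samples over [%.3f, %.3f] mm, dose %.4g-%.4g Gy>\n",
              length(x$positions), min(x$positions), max(x$positions),
              min(x$doses), max(x$doses)))
  invisible(x)
}

#' @export
as.data.frame.dose_profile <- function(x, ...) {
  data.frame(position_mm = x$positions, dose_gy = x$doses)
}

#' Build an idealized top-hat SFRT dose profile
#'
#' Samples a rectangular peak/valley pattern: dose equals `peak_gy` within
#' each beam of width `beam_width_um` centered on a symmetric grid of
#' spacing `ctc_um`, and `peak_gy / pvdr` in the valleys between. This is
#' the binary idealization of a film-measured SFRT profile (no penumbra).
#'
#' @param geometry A [beam_geometry()].
#' @param peak_gy Peak dose in Gy (> 0).
#' @param pvdr Peak-to-valley dose ratio (>= 1; 1 gives a uniform field).
#' @param resolution_um Sampling step in micrometres; must be at most
#'   `beam_width_um / 5` so each beam is resolved. Default
#'   `min(beam_width_um / 10, 25)`: 5 um for the MRT geometry, 25 um for
#'   MBRT, i.e. at least 10 samples per beam.
#' @return A [dose_profile()] spanning the field.
#' @examples
#' p <- build_ideal_profile(mrt_geometry(), peak_gy = 470, pvdr = 20)
#' range(p$doses)  # 23.5 470
#' @export
build_ideal_profile <- function(geometry, peak_gy, pvdr,
                                resolution_um = min(geometry$beam_width_um / 10, 25)) {
  stopifnot(inherits(geometry, "beam_geometry"))
  if (peak_gy <= 0) stop("peak_gy must be > 0")
  if (pvdr < 1) stop("pvdr must be >= 1")
  if (resolution_um > geometry$beam_width_um / 5)
    stop(sprintf("resolution_um = %g is too coarse: must be <= beam_width / 5 = %g um",
                 resolution_um, geometry$beam_width_um / 5))
  half <- geometry$field_mm / 2
  step <- resolution_um / 1000
  positions <- seq(-half, half, by = step)
  n <- count_beams(geometry)
  centers <- (seq_len(n) - (n + 1) / 2) * geometry$ctc_um / 1000
  hw <- geometry$beam_width_um / 2000  # half beam width in mm
  in_beam <- rep(FALSE, length(positions))
  for (c0 in centers)
    in_beam <- in_beam | (abs(positions - c0) <= hw + 1e-12)
  doses <- ifelse(in_beam, peak_gy, peak_gy / pvdr)
  new_dose_profile(positions, doses)
}

#' Peak-to-valley dose ratio of a profile
#'
#' @param profile A [dose_profile()].
#' @return `max(doses) / min(doses)`.
#' @export
profile_pvdr <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  v <- min(profile$doses)
  if (v <= 0) stop("valley dose is zero: PVDR undefined")
  max(profile$doses) / v
}

#' Valley (minimum) dose of a profile
#' @param profile A [dose_profile()].
#' @return Minimum dose in Gy.
#' @export
valley_dose <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  min(profile$doses)
}

#' Peak (maximum) dose of a profile
#' @param profile A [dose_profile()].
#' @return Maximum dose in Gy.
#' @export
peak_dose <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  max(profile$doses)
}

# log of the spatially averaged LQ survival, computed in log space so that
# peak doses of hundreds of Gy (exp(-0.0115 * 470^2) underflows double
# arithmetic) still contribute correctly.
log_mean_survival <- function(doses, lq) {
  logs <- -lq$alpha * doses - lq$beta * doses^2
  m <- max(logs)
  m + log(mean(exp(logs - m)))
}

#' Equivalent uniform dose (EUD) of a dose profile
#'
#' The EUD is the uniform dose producing the same mean linear-quadratic cell
#' survival as the nonuniform profile, with every grid sample weighted
#' equally. With mean survival `S`, the unique non-negative root of
#' `alpha * D + beta * D^2 = -log(S)` is
#' `D = (-alpha + sqrt(alpha^2 - 4 * beta * log(S))) / (2 * beta)`,
#' reducing to `-log(S) / alpha` when `beta = 0`. Survival is averaged in
#' log-sum-exp form, so the result is finite for any finite profile.
#'
#' @param profile A [dose_profile()].
#' @param lq An [lq_params()] object.
#' @return EUD in Gy, always within `[min(doses), max(doses)]`.
#' @examples
#' u <- dose_profile(seq(0, 1, 0.1), rep(20, 11))
#' eud(u)  # 20
#' @export
eud <- function(profile, lq = lq_params()) {
  stopifnot(inherits(profile, "dose_profile"), inherits(lq, "lq_params"))
  ls <- log_mean_survival(profile$doses, lq)
  if (lq$beta == 0) return(-ls / lq$alpha)
  (-lq$alpha + sqrt(lq$alpha^2 - 4 * lq$beta * ls)) / (2 * lq$beta)
}

#' Solve the peak dose that delivers a target EUD
#'
#' Finds the peak dose `P` such that the ideal profile built from `geometry`
#' with the given PVDR has `eud() == target_eud`, by bracketed root search
#' (EUD is strictly increasing in the peak dose).
#'
#' @param geometry A [beam_geometry()].
#' @param pvdr Peak-to-valley dose ratio (>= 1).
#' @param lq An [lq_params()] object.
#' @param target_eud Target EUD in Gy (> 0).
#' @param resolution_um Grid resolution passed to [build_ideal_profile()].
#' @return Peak dose in Gy reproducing `target_eud` to within 1e-6 Gy.
#' @export
solve_peak_for_eud <- function(geometry, pvdr, lq = lq_params(), target_eud,
                               resolution_um = min(geometry$beam_width_um / 10, 25)) {
  stopifnot(inherits(geometry, "beam_geometry"))
  if (target_eud <= 0) stop("target_eud must be > 0")
  if (pvdr < 1) stop("pvdr must be >= 1")
  obj <- function(p)
    eud(build_ideal_profile(geometry, p, pvdr, resolution_um), lq) - target_eud
  lo <- target_eud
  hi <- 1e4
  flo <- obj(lo)
  if (abs(flo) < 1e-9) return(lo)
  if (flo > 0 || obj(hi) < 0)
    stop("no bracketing interval for the peak dose within [target_eud, 1e4] Gy")
  stats::uniroot(obj, c(lo, hi), tol = 1e-9)$root
}

#' Read / write a dose-profile CSV
#'
#' The profile CSV dialect has a header and two columns,
#' `position_mm,dose_gy` (dot decimal separator).
#'
#' @param path File path.
#' @return `read_dose_profile` returns a [dose_profile()];
#'   `write_dose_profile` returns `path` invisibly.
#' @export
read_dose_profile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_mm", "dose_gy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV missing column(s): ", paste(miss, collapse = ", "))
  dose_profile(df$position_mm, df$dose_gy)
}

#' @rdname read_dose_profile
#' @param profile A [dose_profile()] to write.
#' @export
write_dose_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dose_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Dosimetric summary of an SFRT arm
#'
#' Convenience wrapper producing, for one geometry, the beam count, valley
#' dose, measured PVDR of the ideal profile, its EUD at the given peak dose,
#' and the peak dose that would deliver a target EUD.
#'
#' @param geometry A [beam_geometry()].
#' @param peak_gy Nominal peak dose in Gy.
#' @param pvdr Peak-to-valley dose ratio.
#' @param lq An [lq_params()] object.
#' @param target_eud Target EUD in Gy for the inverse solve (default 20).
#' @return A one-row data.frame.
#' @export
dose_summary <- function(geometry, peak_gy, pvdr, lq = lq_params(),
                         target_eud = 20) {
  prof <- build_ideal_profile(geometry, peak_gy, pvdr)
  data.frame(
    label = geometry$label,
    beam_width_um = geometry$beam_width_um,
    ctc_um = geometry$ctc_um,
    n_beams = count_beams(geometry),
    peak_gy = peak_gy,
    valley_gy = valley_dose(prof),
    pvdr = profile_pvdr(prof),
    eud_gy = eud(prof, lq),
    peak_for_target_eud_gy = solve_peak_for_eud(geometry, pvdr, lq, target_eud),
    target_eud_gy = target_eud
  )
}
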