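#' Run the full study analysis pipeline
#'
#' Sequences the stages end to end: obtain a cohort (simulate from a design
#' or read a measurement CSV), fit the bi-exponential regrowth model, derive
#' tripling times and per-arm growth delays against the control arm, build
#' the progression-free-survival dataset and its Kaplan-Meier / pairwise
#' log-rank analysis, quantify qPCR fold changes when a Ct table is given,
#' and summarize the SFRT dosimetry when a dose block is given. The run is
#' deterministic given the config and seed.
#'
#' @param config A named list, or path to a JSON/YAML file with the same
#'   shape. Recognized entries:
#'   \describe{
#'     \item{simulate}{list(`seed`, optional `n`, `noise_cv`) — generate the
#'       default four-arm cohort; mutually exclusive with `measurements`.}
#'     \item{measurements}{path to a measurement CSV.}
#'     \item{control_arm}{label of the control arm (default `"control"`).}
#'     \item{fit_scope}{`"mouse"` (default, one fit per animal) or
#'       `"group"` (one fit per arm on the pooled normalized points of its
#'       animals).}
#'     \item{delay_method}{`"raw"` (default) or `"model"` tripling time.}
#'     \item{followup_cap}{days, default 90.}
#'     \item{ct_table}{path to a Ct CSV (optional).}
#'     \item{reference_genes, control_group}{qPCR options.}
#'     \item{dose}{list of blocks with `beam_width_um`, `ctc_um`,
#'       `field_mm`, `label`, `peak_gy`, `pvdr`, and optional `alpha`,
#'       `beta`, `target_eud` (optional).}
#'     \item{out_dir}{directory for the report JSON and tidy CSVs
#'       (optional; nothing is written when absent).}
#'   }
#' @return A list of class `study_report`: `fits`, `growth_times`,
#'   `delays`, `pfs`, `km`, `logrank`, `qpcr`, `dose`, `provenance`.
#' @examples
#' rep <- run_pipeline(list(simulate = list(seed = 1, n = 3)))
#' rep$delays
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulate)
  has_csv <- !is.null(config$measurements)
  if (has_sim == has_csv)
    stop("config must contain exactly one of 'simulate' or 'measurements'")
  control_arm <- config$control_arm %||% "control"
  fit_scope <- match.arg(config$fit_scope %||% "mouse", c("mouse", "group"))
  delay_method <- match.arg(config$delay_method %||% "raw", c("raw", "model"))
  followup_cap <- config$followup_cap %||% 90

  if (has_sim) {
    sim <- config$simulate
    if (is.null(sim$seed)) stop("a seed is required when simulating")
    design <- default_study_design(seed = sim$seed,
                                   n = sim$n %||% 9,
                                   noise_cv = sim$noise_cv %||% 0.15)
    cohort <- generate_cohort(design)
  } else {
    cohort <- read_measurements(config$measurements)
  }

  arms <- vapply(cohort, function(r) r$arm, character(1))
  if (!control_arm %in% arms)
    stop("control arm '", control_arm, "' not present in the cohort")

  # --- regrowth fits -------------------------------------------------------
  fit_one <- function(r) tryCatch(fit_regrowth(r), error = function(e) e)
  fits <- lapply(cohort, fit_one)
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed))
    warning(sum(failed), " mouse fit(s) failed: ",
            paste(names(fits)[failed], collapse = ", "))
  group_fits <- NULL
  if (fit_scope == "group") {
    group_fits <- lapply(split(cohort, arms), function(recs) {
      pts <- do.call(rbind, lapply(recs, function(r)
        data.frame(day = r$measurements$day,
                   ratio = r$measurements$volume_mm3 / r$v0)))
      tryCatch(fit_regrowth(pts[pts$day > 0, ]), error = function(e) e)
    })
  }

  # --- growth times and delays --------------------------------------------
  growth_times <- data.frame(
    mouse_id = vapply(cohort, function(r) r$mouse_id, character(1)),
    arm = arms,
    growth_time = vapply(seq_along(cohort), function(i) {
      if (delay_method == "raw")
        tripling_time(cohort[[i]], method = "raw")
      else if (!failed[i])
        tripling_time(cohort[[i]], method = "model", fit = fits[[i]])
      else NA_real_
    }, numeric(1)),
    row.names = NULL)
  ctrl_times <- growth_times$growth_time[growth_times$arm == control_arm]
  treated_arms <- setdiff(unique(arms), control_arm)
  delays <- lapply(treated_arms, function(a)
    growth_delay(growth_times$growth_time[growth_times$arm == a],
                 ctrl_times, arm = a))
  names(delays) <- treated_arms
  delay_table <- do.call(rbind, lapply(delays, function(d)
    data.frame(arm = d$arm, mean_delay = d$mean_delay, sd = d$sd,
               ci95_halfwidth = d$ci95_halfwidth, n = d$n,
               n_censored = d$n_censored,
               p_vs_control = d$p_vs_control,
               p_delay_vs_zero = d$p_delay_vs_zero)))
  if (!is.null(delay_table)) rownames(delay_table) <- NULL

  # --- progression-free survival ------------------------------------------
  fit_df <- data.frame(
    mouse_id = names(fits),
    arm = arms,
    regrowth_start_day = vapply(seq_along(fits), function(i) {
      if (failed[i]) NA_real_ else fits[[i]]$regrowth_start_day
    }, numeric(1)),
    last_followup_day = vapply(cohort, function(r) r$last_followup_day,
                               numeric(1)),
    row.names = NULL)
  pfs <- build_pfs_dataset(fit_df, followup_cap = followup_cap)
  km <- lapply(split(pfs, pfs$arm), km_estimate)
  logrank <- if (length(unique(pfs$arm)) >= 2L)
    pairwise_logrank(pfs) else NULL

  # --- qPCR ----------------------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$ct_table)) {
    ct <- if (is.character(config$ct_table)) read_ct_table(config$ct_table)
          else validate_ct_table(config$ct_table)
    qpcr <- fold_change(
      ct,
      control_group = config$control_group %||% control_arm,
      reference_genes = config$reference_genes %||% c("GAPDH", "B2M", "ACTB"))
  }

  # --- dosimetry ------------------------------------------------------------
  dose <- NULL
  if (!is.null(config$dose)) {
    blocks <- config$dose
    if (!is.null(blocks$beam_width_um)) blocks <- list(blocks)
    dose <- do.call(rbind, lapply(blocks, function(b) {
      g <- beam_geometry(b$beam_width_um, b$ctc_um, b$field_mm %||% 10,
                         b$label %||% "")
      dose_summary(g, peak_gy = b$peak_gy, pvdr = b$pvdr,
                   lq = lq_params(b$alpha %||% 0.4460, b$beta %||% 0.0115),
                   target_eud = b$target_eud %||% 20)
    }))
  }

  report <- structure(list(
    fits = fits, group_fits = group_fits, growth_times = growth_times,
    delays = delays, delay_table = delay_table,
    pfs = pfs, km = km, logrank = logrank,
    qpcr = qpcr, dose = dose,
    provenance = list(config_hash = config_hash(config),
                      seed = if (has_sim) config$simulate$seed else NA,
                      package_version =
                        as.character(utils::packageVersion("sfrtgrowth")))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline config file (JSON or YAML)
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return The config as a named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d mice, %d arm(s)\n", nrow(x$growth_times),
              length(unique(x$growth_times$arm))))
  if (!is.null(x$delay_table)) {
    cat("  growth delays vs control:\n")
    print(x$delay_table[c("arm", "mean_delay", "sd", "ci95_halfwidth",
                          "p_vs_control")], digits = 3)
  }
  if (!is.null(x$logrank)) {
    cat("  pairwise log-rank:\n")
    print(x$logrank, digits = 3)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (fits, delays, KM tables, log-rank matrix, qPCR and
#' dose summaries, provenance) plus tidy CSVs (`growth_times.csv`,
#' `delays.csv`, `pfs.csv`, `logrank.csv`, and `qpcr_folds.csv` /
#' `dose_summary.csv` when present).
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- !vapply(report$fits, inherits, logical(1), "error")
  fit_json <- lapply(report$fits[ok], function(f)
    list(a1 = f$params$a1, a2 = f$params$a2, alpha1 = f$params$alpha1,
         alpha2 = f$params$alpha2, sse = f$sse, t_min = f$t_min,
         regrowth_start_day = f$regrowth_start_day,
         censored = is.na(f$regrowth_start_day), n_points = f$n_points))
  body <- list(
    fits = fit_json,
    failed_fits = names(report$fits)[!ok],
    delays = report$delay_table,
    km = lapply(report$km, function(k)
      list(times = k$times, survival = k$survival, at_risk = k$at_risk,
           median = k$median, n = k$n)),
    logrank = report$logrank,
    qpcr = if (!is.null(report$qpcr)) report$qpcr$summary,
    dose = report$dose,
    provenance = report$provenance)
  jsonlite::write_json(body, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(report$growth_times,
                   file.path(out_dir, "growth_times.csv"), row.names = FALSE)
  if (!is.null(report$delay_table))
    utils::write.csv(report$delay_table, file.path(out_dir, "delays.csv"),
                     row.names = FALSE)
  utils::write.csv(report$pfs, file.path(out_dir, "pfs.csv"),
                   row.names = FALSE)
  if (!is.null(report$logrank))
    utils::write.csv(report$logrank, file.path(out_dir, "logrank.csv"),
                     row.names = FALSE)
  if (!is.null(report$qpcr))
    utils::write.csv(report$qpcr$summary,
                     file.path(out_dir, "qpcr_folds.csv"), row.names = FALSE)
  if (!is.null(report$dose))
    utils::write.csv(report$dose, file.path(out_dir, "dose_summary.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
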