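#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Ct tables are plain data.frames with columns `sample_id`, `group`,
#' `gene`, `ct` (threshold cycles, in (0, 45)). Technical replicates (rows
#' sharing `sample_id` and `gene`) are collapsed to their mean Ct before
#' normalization, so biological replicates are the unit of analysis.
#'
#' @name qpcr
NULL

validate_ct_table <- function(ct_df) {
  stopifnot(is.data.frame(ct_df),
            all(c("sample_id", "group", "gene", "ct") %in% names(ct_df)))
  if (!nrow(ct_df)) stop("Ct table is empty")
  if (any(ct_df$ct <= 0 | ct_df$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  invisible(ct_df)
}

collapse_technical_replicates <- function(ct_df) {
  stats::aggregate(ct ~ sample_id + group + gene, data = ct_df, FUN = mean)
}

#' Delta-Ct normalization against multiple reference genes
#'
#' For each sample and target gene, `dCt = Ct_target - mean(Ct of the
#' reference genes)`; the arithmetic mean of reference Ct values is the
#' log-scale equivalent of the geometric mean of reference quantities.
#' Samples missing any reference gene are skipped with a warning.
#'
#' @param ct_df Ct table (see [qpcr]).
#' @param reference_genes Character vector of endogenous control genes
#'   (default the study's GAPDH, B2M, ACTB).
#' @param target_genes Target genes; defaults to every non-reference gene
#'   present.
#' @return data.frame with columns `sample_id`, `group`, `gene`, `delta_ct`.
#' @examples
#' ct <- data.frame(sample_id = "s1", group = "control",
#'                  gene = c("GAPDH", "B2M", "ACTB", "GPx1"),
#'                  ct = c(20, 20, 20, 25))
#' delta_ct(ct)  # GPx1 dCt = 5
#' @export
delta_ct <- function(ct_df, reference_genes = c("GAPDH", "B2M", "ACTB"),
                     target_genes = NULL) {
  validate_ct_table(ct_df)
  ct_df <- collapse_technical_replicates(ct_df)
  if (is.null(target_genes))
    target_genes <- setdiff(unique(ct_df$gene), reference_genes)
  if (!length(target_genes)) stop("no target genes in the Ct table")
  out <- lapply(split(ct_df, ct_df$sample_id), function(s) {
    refs <- s$ct[match(reference_genes, s$gene)]
    if (anyNA(refs)) {
      warning("sample ", s$sample_id[1],
              " is missing reference gene(s); skipped")
      return(NULL)
    }
    tg <- s[s$gene %in% target_genes, , drop = FALSE]
    if (!nrow(tg)) return(NULL)
    data.frame(sample_id = tg$sample_id, group = tg$group, gene = tg$gene,
               delta_ct = tg$ct - mean(refs))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no sample had a complete reference-gene set")
  rownames(res) <- NULL
  res
}

#' Fold change by 2^-ddCt against a control group
#'
#' `ddCt = dCt_sample - mean(dCt of the control group)` per gene, and the
#' per-sample fold change is `2^-ddCt`. Group summaries (mean, SD over
#' biological replicates) are computed on the fold scale. The control
#' group's mean fold is 1 by construction when folds are averaged on the
#' log scale; on the linear scale reported here it is exactly 1 only for
#' noise-free data — both behaviors are standard and documented.
#'
#' @param ct_df Ct table (see [qpcr]).
#' @param control_group Label of the reference (sham) group.
#' @param reference_genes,target_genes Passed to [delta_ct()].
#' @return A list of class `fold_change_result` with
#'   `per_sample` (data.frame: `sample_id`, `group`, `gene`, `delta_ct`,
#'   `ddct`, `fold`) and
#'   `summary` (data.frame: `gene`, `group`, `mean_fold`, `sd_fold`, `n`).
#' @examples
#' ct <- generate_ct_table(groups = c("control", "MRT"),
#'                         true_folds = list(GPx1 = c(control = 1, MRT = 3)),
#'                         n_per_group = 4, seed = 1,
#'                         ref_sd = 0, noise_sd = 0)
#' fold_change(ct, "control")$summary
#' @export
fold_change <- function(ct_df, control_group,
                        reference_genes = c("GAPDH", "B2M", "ACTB"),
                        target_genes = NULL) {
  dct <- delta_ct(ct_df, reference_genes, target_genes)
  if (!control_group %in% dct$group)
    stop("control group '", control_group, "' not present in the Ct table")
  per <- do.call(rbind, lapply(split(dct, dct$gene), function(g) {
    ctrl <- g$delta_ct[g$group == control_group]
    if (!length(ctrl)) {
      warning("gene ", g$gene[1], " has no control samples; skipped")
      return(NULL)
    }
    g$ddct <- g$delta_ct - mean(ctrl)
    g$fold <- 2^(-g$ddct)
    g
  }))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, list(per$gene, per$group),
                                      drop = TRUE), function(s) {
    data.frame(gene = s$gene[1], group = s$group[1],
               mean_fold = mean(s$fold),
               sd_fold = if (nrow(s) > 1) stats::sd(s$fold) else NA_real_,
               n = nrow(s))
  }))
  rownames(summ) <- NULL
  structure(list(per_sample = per, summary = summ,
                 control_group = control_group),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result vs '%s'>\n", x$control_group))
  print(x$summary)
  invisible(x)
}

#' Per-gene expression comparisons between groups
#'
#' Unpaired t-tests of per-sample dCt values (the log2-scale expression
#' measure) of each treated group against the control group, per gene.
#'
#' @param fc A [fold_change()] result.
#' @param welch Use Welch's correction (default FALSE, pooled variance).
#' @return data.frame: `gene`, `group`, `t`, `p`.
#' @export
qpcr_group_tests <- function(fc, welch = FALSE) {
  stopifnot(inherits(fc, "fold_change_result"))
  per <- fc$per_sample
  ctrl <- fc$control_group
  combos <- unique(per[per$group != ctrl, c("gene", "group")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; grp <- combos$group[i]
    a <- per$delta_ct[per$gene == g & per$group == grp]
    b <- per$delta_ct[per$gene == g & per$group == ctrl]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(gene = g, group = grp, t = NA_real_, p = NA_real_))
    tt <- unpaired_t_test(a, b, welch = welch)
    data.frame(gene = g, group = grp, t = tt$t, p = tt$p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a Ct CSV
#'
#' Dialect: header `sample_id,group,gene,ct`.
#'
#' @param path CSV file path.
#' @return A validated Ct data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path)
  validate_ct_table(df)
  df
}
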