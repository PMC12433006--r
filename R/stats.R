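#' Read a qPCR CT table
#'
#' @param path TSV with header columns `sample_id`, `marker`, `ct_target`,
#'   `ct_ref`. Empty, `NA` or `ND` target CT entries denote no amplification
#'   within the run (censored).
#' @return `data.frame` with those columns; censored targets are `NA`.
#' @export
read_ct_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "ND"))
  need <- c("sample_id", "marker", "ct_target", "ct_ref")
  if (!all(need %in% names(tab)))
    .stopf("CT table must have columns: %s", paste(need, collapse = ", "))
  tab$ct_target <- as.numeric(tab$ct_target)
  tab$ct_ref <- as.numeric(tab$ct_ref)
  if (any(tab$ct_target <= 0, na.rm = TRUE) || any(tab$ct_ref <= 0, na.rm = TRUE))
    .stopf("CT values must be positive")
  tab[need]
}

#' Normalize target CT values against the reference assay
#'
#' `delta_ct = ct_target - ct_ref` quantifies methylation relative to the
#' amount of amplifiable bisulfite-converted DNA (the reference assay, e.g.
#' ACTB, is methylation-independent); lower values mean more methylated
#' template. Censored targets (no amplification) are imputed at
#' `censor_value` cycles - the run's cycle count, 43 by default - and
#' flagged.
#'
#' @param measurements `data.frame` as from [read_ct_table()].
#' @param manifest Optional manifest `data.frame` with `sample_id`, `group`;
#'   when given, each record is annotated with its group and unknown samples
#'   raise an error.
#' @param censor_value Imputed target CT for censored measurements.
#' @return `data.frame` with `sample_id`, `marker`, `group` (`NA` without a
#'   manifest), `delta_ct`, `censored`.
#' @export
compute_delta_ct <- function(measurements, manifest = NULL, censor_value = 43) {
  if (anyNA(measurements$ct_ref))
    .stopf("missing reference CT for sample '%s' (marker %s)",
           measurements$sample_id[which(is.na(measurements$ct_ref))[1]],
           measurements$marker[which(is.na(measurements$ct_ref))[1]])
  censored <- is.na(measurements$ct_target)
  ct_target <- ifelse(censored, censor_value, measurements$ct_target)
  group <- NA_character_
  if (!is.null(manifest)) {
    group <- manifest$group[match(measurements$sample_id, manifest$sample_id)]
    if (anyNA(group))
      .stopf("sample '%s' absent from manifest",
             measurements$sample_id[which(is.na(group))[1]])
  }
  data.frame(sample_id = measurements$sample_id, marker = measurements$marker,
             group = group, delta_ct = ct_target - measurements$ct_ref,
             censored = censored, stringsAsFactors = FALSE)
}

.split_groups <- function(records) {
  if (!all(records$group %in% c("tumor", "control")))
    .stopf("records must carry group 'tumor' or 'control'")
  list(tumor = records$delta_ct[records$group == "tumor"],
       control = records$delta_ct[records$group == "control"])
}

#' Welch two-sample test of delta-CT between groups
#'
#' Two-sided Welch (unequal-variance) t-test of tumor vs control delta-CT
#' for one marker.
#'
#' @param records Delta-CT `data.frame` for one marker (columns `group`,
#'   `delta_ct`).
#' @return One-row `data.frame`: `marker`, group means and standard
#'   deviations, `statistic`, `df`, `p_raw`.
#' @export
group_test <- function(records) {
  g <- .split_groups(records)
  if (length(g$tumor) < 2L || length(g$control) < 2L)
    .stopf("need >= 2 records per group, got %d tumor / %d control",
           length(g$tumor), length(g$control))
  if (sd(g$tumor) == 0 && sd(g$control) == 0)
    .stopf("zero variance in both groups")
  tt <- t.test(g$tumor, g$control, var.equal = FALSE,
               alternative = "two.sided")
  data.frame(marker = if ("marker" %in% names(records)) records$marker[1]
                      else NA_character_,
             mean_tumor = mean(g$tumor), sd_tumor = sd(g$tumor),
             mean_control = mean(g$control), sd_control = sd(g$control),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving; the family size `m` defaults
#' to the number of p-values supplied.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Area under the ROC curve for one marker
#'
#' Orientation "lower delta-CT indicates tumor" (hypermethylation means
#' earlier amplification): `AUC = (#pairs tumor < control + 0.5 * ties) /
#' (n_tumor * n_control)`, i.e. the Mann-Whitney probability that a random
#' tumor sample looks more tumor-like than a random control.
#'
#' @inheritParams group_test
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(records) {
  g <- .split_groups(records)
  if (!length(g$tumor) || !length(g$control))
    .stopf("need >= 1 record per group")
  cmp <- outer(g$tumor, g$control, `<`)
  ties <- outer(g$tumor, g$control, `==`)
  (sum(cmp) + 0.5 * sum(ties)) / (length(g$tumor) * length(g$control))
}

#' Youden-optimal delta-CT cutpoint for one marker
#'
#' Candidate cutpoints are the midpoints between adjacent distinct sorted
#' delta-CT values plus minus/plus infinity, so the reported threshold is
#' centered in the separating margin. Samples classify as tumor iff
#' `delta_ct <= cutpoint`. The cutpoint maximizing Youden's
#' `J = sensitivity + specificity - 1` is returned; ties break toward
#' higher specificity, then the lower cutpoint.
#'
#' @inheritParams group_test
#' @return One-row `data.frame`: `marker`, `cutpoint`, `sensitivity`,
#'   `specificity`, `youden_j`, `auc`, `direction`.
#' @export
youden_optimal_cutpoint <- function(records) {
  g <- .split_groups(records)
  if (!length(g$tumor) || !length(g$control))
    .stopf("need >= 1 record per group")
  v <- sort(unique(c(g$tumor, g$control)))
  cand <- c(-Inf, if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(cand, function(c) mean(g$tumor <= c), 0)
  spec <- vapply(cand, function(c) mean(g$control > c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], cand[best])][1]
  data.frame(marker = if ("marker" %in% names(records)) records$marker[1]
                      else NA_character_,
             cutpoint = cand[best], sensitivity = sens[best],
             specificity = spec[best], youden_j = j[best],
             auc = roc_auc(records),
             direction = "tumor if delta_ct <= cutpoint",
             stringsAsFactors = FALSE)
}

#' Per-marker validation summary
#'
#' For each marker: group descriptives (mean, sd, min, max, range), the
#' Welch test with Bonferroni adjustment over the marker family, the
#' Youden-optimal cutpoint block, and a perfect-separation flag (minimum
#' control delta-CT above the maximum tumor delta-CT).
#'
#' @param records Delta-CT `data.frame` for one or more markers (columns
#'   `marker`, `group`, `delta_ct`).
#' @return `data.frame`, one row per marker, ordered by marker name.
#' @export
summarize_markers <- function(records) {
  if (!nrow(records)) .stopf("no records")
  markers <- sort(unique(records$marker))
  rows <- lapply(markers, function(mk) {
    rec <- records[records$marker == mk, , drop = FALSE]
    g <- .split_groups(rec)
    tst <- group_test(rec)
    cp <- youden_optimal_cutpoint(rec)
    data.frame(marker = mk,
               n_tumor = length(g$tumor), n_control = length(g$control),
               mean_tumor = tst$mean_tumor, sd_tumor = tst$sd_tumor,
               min_tumor = min(g$tumor), max_tumor = max(g$tumor),
               range_tumor = max(g$tumor) - min(g$tumor),
               mean_control = tst$mean_control, sd_control = tst$sd_control,
               min_control = min(g$control), max_control = max(g$control),
               range_control = max(g$control) - min(g$control),
               p_raw = tst$p_raw,
               separated = min(g$control) > max(g$tumor),
               cutpoint = cp$cutpoint, sensitivity = cp$sensitivity,
               specificity = cp$specificity, youden_j = cp$youden_j,
               auc = cp$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw, m = length(markers))
  rownames(out) <- NULL
  out
}
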