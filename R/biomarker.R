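#' Round half away from zero
#'
#' Display rounding used throughout the marker tables: halves round away
#' from zero (62.5 -> 63), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Detection threshold at 100% specificity
#'
#' The smallest threshold at which every control sample scores negative,
#' with positivity defined as a value strictly greater than the threshold:
#' the maximum of the control values. When the protein is not detected in
#' any control the threshold is 0 and positivity reduces to detection
#' itself.
#'
#' @param control_values Non-empty numeric vector of control abundances.
#' @return Scalar threshold.
#' @examples
#' full_specificity_threshold(c(1, 2, 3))
#' full_specificity_threshold(rep(0, 15))
#' @export
full_specificity_threshold <- function(control_values) {
  if (length(control_values) == 0L) {
    stop("at least one control value is required", call. = FALSE)
  }
  stopifnot(is.numeric(control_values), all(is.finite(control_values)))
  max(control_values)
}

#' Sensitivity at the full-specificity threshold
#'
#' Fraction of patients scoring strictly above the threshold, with the
#' rounded-percent display used in candidate tables (half away from zero,
#' so 10/16 = 62.5% prints as 63%).
#'
#' @param patient_values Numeric vector of patient abundances.
#' @param threshold Detection threshold (typically
#'   [full_specificity_threshold()] of the controls).
#' @param n_patient Number of patients (defaults to
#'   `length(patient_values)`).
#' @return List with `count` (patients positive), `fraction` and `percent`
#'   (integer, rounded half away from zero).
#' @examples
#' sensitivity_at_full_specificity(c(rep(5, 10), rep(0, 6)), 0)
#' @export
sensitivity_at_full_specificity <- function(patient_values, threshold,
                                            n_patient = length(patient_values)) {
  stopifnot(n_patient >= 1L, length(patient_values) <= n_patient)
  count <- sum(patient_values > threshold)
  fraction <- count / n_patient
  list(
    count = as.integer(count),
    fraction = fraction,
    percent = as.integer(round_half_up(100 * fraction))
  )
}

.roc_candidate_thresholds <- function(control_values, patient_values) {
  sort(unique(c(-Inf, control_values, patient_values, Inf)))
}

#' Threshold maximizing Youden's J
#'
#' Scans all candidate thresholds -- midpoints between adjacent distinct
#' pooled values, with -Inf/+Inf sentinels -- and returns the one
#' maximizing J = sensitivity + specificity - 1 (positivity strictly above
#' the threshold). Ties are broken toward the higher threshold, preferring
#' specificity when operating points are otherwise equivalent.
#'
#' @param control_values,patient_values Non-empty numeric vectors.
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`.
#' @examples
#' youden_threshold(c(1, 2), c(3, 4))
#' @export
youden_threshold <- function(control_values, patient_values) {
  stopifnot(length(control_values) >= 1L, length(patient_values) >= 1L)
  pooled <- sort(unique(c(control_values, patient_values)))
  mids <- if (length(pooled) > 1L) {
    (pooled[-1L] + pooled[-length(pooled)]) / 2
  } else {
    numeric(0L)
  }
  cand <- c(-Inf, mids, Inf)
  sens <- vapply(cand, function(t) mean(patient_values > t), numeric(1L))
  spec <- vapply(cand, function(t) mean(control_values <= t), numeric(1L))
  j <- sens + spec - 1
  best <- which(j >= max(j))            # ties -> highest threshold
  best <- best[length(best)]
  list(threshold = cand[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Empirical ROC points
#'
#' One operating point per distinct threshold (every observed value plus
#' -Inf/+Inf sentinels), with positivity strictly above the threshold.
#' Points run from (0, 0) at threshold +Inf to (1, 1) at threshold -Inf;
#' duplicated operating points are dropped.
#'
#' @param control_values,patient_values Non-empty numeric vectors.
#' @return Data frame with columns `threshold`, `fpr` (1 - specificity) and
#'   `tpr` (sensitivity), ordered by increasing `fpr` then `tpr`.
#' @export
roc_points <- function(control_values, patient_values) {
  stopifnot(length(control_values) >= 1L, length(patient_values) >= 1L)
  thr <- rev(.roc_candidate_thresholds(control_values, patient_values))
  fpr <- vapply(thr, function(t) mean(control_values > t), numeric(1L))
  tpr <- vapply(thr, function(t) mean(patient_values > t), numeric(1L))
  keep <- !duplicated(cbind(fpr, tpr))
  data.frame(threshold = thr[keep], fpr = fpr[keep], tpr = tpr[keep])
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under [roc_points()]. Ties between a control and a
#' patient value contribute one half, so the result equals the Mann-Whitney
#' U statistic divided by the number of control-patient pairs: the
#' probability that a random patient outscores a random control.
#'
#' @param control_values,patient_values Non-empty numeric vectors.
#' @return Scalar in \[0, 1\].
#' @examples
#' auc(c(1, 2), c(3, 4))   # perfect separation
#' auc(rep(1, 5), rep(1, 5)) # all tied -> 0.5
#' @export
auc <- function(control_values, patient_values) {
  pts <- roc_points(control_values, patient_values)
  sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
}

#' Combine markers with the OR rule
#'
#' A sample is panel-positive when it is positive on any member marker at
#' that marker's own threshold (strictly above). Built from
#' full-specificity thresholds this keeps specificity exactly 1 on the
#' defining controls while sensitivity can only grow, which is the
#' mechanism by which a complementary second marker lifts a panel to 100%
#' sensitivity.
#'
#' @param thresholds Numeric vector, one threshold per marker.
#' @param patient_values,control_values Matrices (samples x markers) of
#'   abundances on a common sample set; column count must match
#'   `length(thresholds)`.
#' @return List with `sensitivity`, `specificity`, and the per-sample
#'   logical vectors `patient_positive`, `control_positive`.
#' @export
combine_markers_or_rule <- function(thresholds, patient_values, control_values) {
  patient_values <- as.matrix(patient_values)
  control_values <- as.matrix(control_values)
  if (ncol(patient_values) != length(thresholds) ||
      ncol(control_values) != length(thresholds)) {
    stop("markers mismatch: need one column per threshold in both matrices",
         call. = FALSE)
  }
  pat_pos <- rowSums(sweep(patient_values, 2L, thresholds, `>`)) > 0
  ctr_pos <- rowSums(sweep(control_values, 2L, thresholds, `>`)) > 0
  list(
    sensitivity = mean(pat_pos),
    specificity = mean(!ctr_pos),
    patient_positive = pat_pos,
    control_positive = ctr_pos
  )
}

#' AUC of a rank-combined marker panel
#'
#' Combines markers into one score per sample: each marker is reduced to
#' its within-cohort empirical quantile (average ranks for ties, scaled to
#' (0, 1\]) and the combined score is the mean of quantiles across markers.
#' The AUC of that score is returned. This is one simple, scale-free
#' convention for multi-marker ROC analysis; it is this package's choice,
#' not a uniquely defined procedure.
#'
#' @param marker_values Matrix (samples x markers) of abundances.
#' @param labels Character/factor vector per sample; `patient_group` marks
#'   cases.
#' @param patient_group Label identifying patients (default `"patient"`).
#' @return Scalar AUC of the combined score.
#' @export
combined_rank_score_auc <- function(marker_values, labels,
                                    patient_group = "patient") {
  marker_values <- as.matrix(marker_values)
  stopifnot(nrow(marker_values) == length(labels), ncol(marker_values) >= 1L)
  q <- apply(marker_values, 2L, function(v) rank(v) / length(v))
  score <- rowMeans(q)
  is_pat <- labels == patient_group
  auc(score[!is_pat], score[is_pat])
}

#' Focus-list criteria
#'
#' The three retention criteria for the candidate-marker focus list:
#' (i) significant change by both label-free channels and by validated
#' iBAQ, (ii) sensitivity at the full-specificity threshold of at least
#' `min_sensitivity`, (iii) fold change (in either direction) of at least
#' `min_fold_change`. Both boundary comparisons are inclusive.
#'
#' @param alpha Significance level (default 0.05).
#' @param min_sensitivity Minimum sensitivity as a fraction (default 0.50).
#' @param min_fold_change Minimum up- or down-regulation factor (default
#'   1.75).
#' @return An object of class `focus_criteria`.
#' @export
focus_criteria <- function(alpha = 0.05, min_sensitivity = 0.50,
                           min_fold_change = 1.75) {
  stopifnot(alpha > 0, min_sensitivity > 0, min_sensitivity <= 1,
            min_fold_change > 0)
  structure(list(alpha = alpha, min_sensitivity = min_sensitivity,
                 min_fold_change = min_fold_change),
            class = "focus_criteria")
}

#' Evaluate every protein of a quantification matrix as a marker
#'
#' Computes, per protein: the full-specificity threshold and the resulting
#' sensitivity (count, fraction, rounded percent), the Youden-optimal
#' threshold and J, and the AUC. Patient-group mean ppm abundance is
#' attached for reporting.
#'
#' @param x Sample-level [protein_quant_matrix()].
#' @param control_group,patient_group Group labels.
#' @return Data frame, one row per protein, invariantly ordered as in `x`.
#' @export
evaluate_markers <- function(x, control_group = "control",
                             patient_group = "patient") {
  stopifnot(inherits(x, "protein_quant_matrix"))
  ctr <- group_columns(x, control_group)
  pat <- group_columns(x, patient_group)
  stopifnot(length(ctr) >= 1L, length(pat) >= 1L)
  ppm <- ppm_abundance(x)
  accs <- rownames(x$values)
  res <- lapply(accs, function(acc) {
    cv <- x$values[acc, ctr]
    pv <- x$values[acc, pat]
    thr <- full_specificity_threshold(cv)
    sens <- sensitivity_at_full_specificity(pv, thr)
    yj <- youden_threshold(cv, pv)
    data.frame(
      protein_accession = acc,
      threshold_full_spec = thr,
      n_patients_positive = sens$count,
      sensitivity_full_spec = sens$fraction,
      sensitivity_percent = sens$percent,
      threshold_youden = yj$threshold,
      youden_j = yj$j,
      auc = auc(cv, pv),
      abundance_ppm_patient = mean(ppm[acc, pat]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble the biomarker focus list
#'
#' Joins differential results and marker evaluations on accession and keeps
#' proteins passing all three [focus_criteria()]; the effect size is
#' `max(ratio, 1/ratio)` of the validated iBAQ ratio, so down-regulation
#' counts symmetrically (a ratio of 0.48 is a 2.08-fold effect). Output is
#' ordered by sensitivity, then effect, both descending.
#'
#' @param differential Data frame from [differential_analysis()].
#' @param markers Data frame from [evaluate_markers()].
#' @param criteria A [focus_criteria()].
#' @return Data frame of retained candidates with an `effect` column.
#' @export
focus_list_filter <- function(differential, markers,
                              criteria = focus_criteria()) {
  stopifnot(inherits(criteria, "focus_criteria"))
  missing_keys <- setdiff(differential$protein_accession,
                          markers$protein_accession)
  if (length(missing_keys) > 0L) {
    stop(sprintf("no marker evaluation for accession(s): %s",
                 paste(utils::head(missing_keys, 5L), collapse = ", ")),
         call. = FALSE)
  }
  joined <- merge(differential, markers, by = "protein_accession")
  ratio <- joined$ibaq_ratio
  effect <- pmax(ratio, 1 / ratio)
  effect[is.na(effect)] <- 0
  keep <- joined$lfq_significant &
    !is.na(joined$ibaq_significant) & joined$ibaq_significant &
    joined$sensitivity_full_spec >= criteria$min_sensitivity &
    effect >= criteria$min_fold_change
  out <- joined[keep, , drop = FALSE]
  out$effect <- effect[keep]
  out <- out[order(-out$sensitivity_full_spec, -out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove confounded candidates
#'
#' Drops candidates whose accession appears in a confounder set (for
#' example proteins that also differ between first and second morning urine
#' voids and therefore cannot be attributed to disease). Removals are
#' reported via a message and returned as an attribute.
#'
#' @param candidates Data frame with a `protein_accession` column.
#' @param confounder_set Character vector of accessions to exclude.
#' @return Filtered data frame with attribute `removed` listing the dropped
#'   accessions.
#' @export
exclusion_filter <- function(candidates, confounder_set) {
  confounder_set <- unique(as.character(confounder_set))
  hit <- candidates$protein_accession %in% confounder_set
  if (any(hit)) {
    message(sprintf("excluding %d confounded candidate(s): %s", sum(hit),
                    paste(candidates$protein_accession[hit], collapse = ", ")))
  }
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- candidates$protein_accession[hit]
  out
}

#' Sample-by-marker positivity matrix
#'
#' Binary heat-map input: entry (sample, marker) is the positivity call of
#' the sample on the marker at its threshold (strictly above). Thresholds
#' may come from the full-specificity or the Youden operating point.
#'
#' @param x Sample-level [protein_quant_matrix()].
#' @param thresholds Named numeric vector of thresholds; names are
#'   accessions present in `x`.
#' @return Logical matrix, samples in rows, markers in columns.
#' @export
biomarker_heatmap_matrix <- function(x, thresholds) {
  stopifnot(inherits(x, "protein_quant_matrix"),
            !is.null(names(thresholds)),
            all(names(thresholds) %in% rownames(x$values)))
  vals <- t(x$values[names(thresholds), , drop = FALSE])
  sweep(vals, 2L, thresholds, `>`)
}
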