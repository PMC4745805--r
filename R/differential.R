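#' Two-sided Fisher exact test on a presence/absence 2x2 table
#'
#' Exact two-sided p-value for a difference in detection frequency between
#' groups, computed by hypergeometric enumeration with the
#' probability-ordering rule: all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7 to absorb floating-point ties) contribute to p. This is
#' the most common two-sided convention for the exact test; other
#' conventions (doubling the one-sided p) exist and give different values on
#' asymmetric margins.
#'
#' @param detected_a,absent_a Detected / not-detected counts in group A
#'   (e.g. controls).
#' @param detected_b,absent_b Counts in group B (e.g. patients).
#' @return p-value in \[0, 1\].
#' @examples
#' presence_fisher_test(8, 8, 8, 8)    # identical proportions -> 1
#' presence_fisher_test(0, 15, 12, 4)  # detection only in patients
#' @export
presence_fisher_test <- function(detected_a, absent_a, detected_b, absent_b) {
  counts <- c(detected_a, absent_a, detected_b, absent_b)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts))) {
    stop("all four counts must be non-negative integers", call. = FALSE)
  }
  m <- detected_a + detected_b   # total detected
  n <- absent_a + absent_b       # total absent
  k <- detected_a + absent_a     # size of group A
  if (m + n == 0L) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[match(detected_a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Welch's heteroscedastic two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom (no
#' equal-variance assumption). Degenerate cases follow the conventions
#' natural for censored abundance data: when both groups are constant, p is
#' 1 if the constants agree and 0 otherwise (the groups are then separated
#' without sampling noise).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Dual-channel label-free significance rule
#'
#' A protein counts as significantly altered by label-free quantification
#' only when the group comparison is significant on both quantification
#' channels (spectral counts and Top3TIC), each at strict `p < alpha`.
#'
#' @param p_psm,p_top3 p-values (vectors recycle) from the two channels.
#' @param alpha Significance level (default 0.05); the comparison is strict.
#' @return Logical vector.
#' @examples
#' dual_channel_significance(c(0.01, 0.01, 0.05), c(0.2, 0.01, 0.01))
#' @export
dual_channel_significance <- function(p_psm, p_top3, alpha = 0.05) {
  stopifnot(all(p_psm >= 0 & p_psm <= 1, na.rm = TRUE),
            all(p_top3 >= 0 & p_top3 <= 1, na.rm = TRUE))
  (p_psm < alpha) & (p_top3 < alpha)
}

#' Patient-to-control fold change
#'
#' Ratio of group mean abundances, patient over control. Conventions for
#' censored data: `Inf` when the protein is absent from every control but
#' present in patients ("patient-unique"), 1 when absent from both groups.
#'
#' @param control_values,patient_values Non-negative numeric vectors.
#' @return Positive scalar or `Inf`.
#' @export
fold_change_ratio <- function(control_values, patient_values) {
  stopifnot(all(control_values >= 0), all(patient_values >= 0))
  mc <- mean(control_values)
  mp <- mean(patient_values)
  if (mc == 0 && mp == 0) return(1)
  if (mc == 0) return(Inf)
  mp / mc
}

#' Validate a fold change on pooled iBAQ replicates
#'
#' The validation design pools each group's samples into three sets,
#' quantifies each pool by iBAQ, and normalizes all pools to the patient
#' total. A protein's change is `valid` only when it is present in at least
#' 2 of the 3 pools of each group where it occurs at all; presence in just 1
#' of 3 pools of a group is considered irreproducible. The reported ratio is
#' mean(patient pools) / mean(control pools) and the p-value comes from a
#' two-sided heteroscedastic t-test on the pool triplicates.
#'
#' @param control_pools,patient_pools Numeric vectors of length 3
#'   (normalized pooled iBAQ values; 0 = not detected).
#' @param alpha Significance level for the `significant` flag.
#' @return List with `ratio`, `p`, `valid`, `significant` and
#'   `patient_unique` (protein absent from all control pools but present in
#'   patient pools; the ratio is then `Inf`).
#' @export
ibaq_pool_validation <- function(control_pools, patient_pools, alpha = 0.05) {
  stopifnot(length(control_pools) == 3L, length(patient_pools) == 3L,
            all(control_pools >= 0), all(patient_pools >= 0))
  pres_c <- sum(control_pools > 0)
  pres_p <- sum(patient_pools > 0)
  # a group with no presence at all carries no evidence either way; the
  # invalidity rule targets irreproducible single-pool observations
  valid <- !(pres_c == 1L) && !(pres_p == 1L) && (pres_c + pres_p > 0L)
  ratio <- fold_change_ratio(control_pools, patient_pools)
  tt <- welch_t_test(patient_pools, control_pools)
  list(
    ratio = ratio,
    p = tt$p,
    valid = valid,
    significant = valid && tt$p < alpha,
    patient_unique = pres_c == 0L && pres_p > 0L
  )
}

#' Differential-abundance analysis of a case-control cohort
#'
#' Runs, for every protein detected in at least one sample: the
#' presence/absence Fisher exact test on per-sample detection counts, the
#' heteroscedastic t-test on each label-free channel (spectral counts and
#' Top3TIC), the dual-channel significance rule, and -- when a pooled iBAQ
#' matrix is supplied -- the pooled-triplicate validation after normalizing
#' all pools to the mean patient-pool total. Non-detected sample values
#' enter the t-tests as zeros by default, which treats absence as
#' informative (consistent with detection-limit censoring); set
#' `zeros = "exclude"` to drop them instead.
#'
#' @param psm,top3 Sample-level [protein_quant_matrix()] objects with the
#'   same proteins and samples, groups labelled `control_group` /
#'   `patient_group`.
#' @param ibaq_pools Optional pool-level `protein_quant_matrix` (3 pools per
#'   group) for validation.
#' @param alpha Significance level (default 0.05), applied strictly.
#' @param zeros `"include"` (default) or `"exclude"`: how non-detected
#'   values enter the t-tests.
#' @param control_group,patient_group Group labels (defaults `"control"`,
#'   `"patient"`).
#' @return Data frame with one row per protein: detection counts, Fisher p,
#'   per-channel Welch p, `lfq_significant`, Top3TIC fold change, iBAQ
#'   ratio/p/validity, the master `significantly_altered` flag
#'   (dual-channel AND valid significant iBAQ change), a `direction` call,
#'   and Benjamini-Hochberg adjusted versions of the p-value columns
#'   (emitted for modern reuse; no filtering in this function uses them).
#' @export
differential_analysis <- function(psm, top3, ibaq_pools = NULL,
                                  alpha = 0.05,
                                  zeros = c("include", "exclude"),
                                  control_group = "control",
                                  patient_group = "patient") {
  zeros <- match.arg(zeros)
  stopifnot(inherits(psm, "protein_quant_matrix"),
            inherits(top3, "protein_quant_matrix"))
  if (!identical(rownames(psm$values), rownames(top3$values)) ||
      !identical(colnames(psm$values), colnames(top3$values))) {
    stop("`psm` and `top3` must share proteins and samples", call. = FALSE)
  }
  ctr <- group_columns(top3, control_group)
  pat <- group_columns(top3, patient_group)
  if (length(ctr) < 2L || length(pat) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  accs <- rownames(top3$values)
  n_ctr <- length(ctr)
  n_pat <- length(pat)
  detected_any <- psm$detected | top3$detected
  det_ctr <- rowSums(detected_any[, ctr, drop = FALSE])
  det_pat <- rowSums(detected_any[, pat, drop = FALSE])

  test_channel <- function(vals, i) {
    x <- vals[i, pat]
    y <- vals[i, ctr]
    if (zeros == "exclude") {
      x <- x[x > 0]
      y <- y[y > 0]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    }
    welch_t_test(x, y)$p
  }

  fisher_p <- welch_p_psm <- welch_p_top3 <- ratio_top3 <- numeric(length(accs))
  for (i in seq_along(accs)) {
    fisher_p[i] <- presence_fisher_test(
      det_ctr[i], n_ctr - det_ctr[i], det_pat[i], n_pat - det_pat[i]
    )
    welch_p_psm[i] <- test_channel(psm$values, i)
    welch_p_top3[i] <- test_channel(top3$values, i)
    ratio_top3[i] <- fold_change_ratio(top3$values[i, ctr], top3$values[i, pat])
  }
  lfq_sig <- dual_channel_significance(welch_p_psm, welch_p_top3, alpha)
  lfq_sig[is.na(lfq_sig)] <- FALSE

  ibaq_ratio <- rep(NA_real_, length(accs))
  ibaq_p <- rep(NA_real_, length(accs))
  ibaq_valid <- rep(NA, length(accs))
  ibaq_sig <- rep(NA, length(accs))
  if (!is.null(ibaq_pools)) {
    stopifnot(inherits(ibaq_pools, "protein_quant_matrix"))
    pc <- group_columns(ibaq_pools, control_group)
    pp <- group_columns(ibaq_pools, patient_group)
    if (length(pc) != 3L || length(pp) != 3L) {
      stop("`ibaq_pools` must contain exactly 3 pools per group", call. = FALSE)
    }
    ref <- mean(colSums(ibaq_pools$values[, pp, drop = FALSE]))
    pools <- normalize_to_reference_total(ibaq_pools, ref)
    common <- intersect(accs, rownames(pools$values))
    for (acc in common) {
      i <- match(acc, accs)
      v <- ibaq_pool_validation(pools$values[acc, pc], pools$values[acc, pp],
                                alpha = alpha)
      ibaq_ratio[i] <- v$ratio
      ibaq_p[i] <- v$p
      ibaq_valid[i] <- v$valid
      ibaq_sig[i] <- v$significant
    }
    ibaq_valid[is.na(ibaq_valid)] <- FALSE
    ibaq_sig[is.na(ibaq_sig)] <- FALSE
  }

  altered <- lfq_sig & !is.na(ibaq_sig) & ibaq_sig
  dir_ratio <- ifelse(is.na(ibaq_ratio), ratio_top3, ibaq_ratio)
  direction <- ifelse(!altered, "none",
                      ifelse(dir_ratio > 1, "up",
                             ifelse(dir_ratio < 1, "down", "none")))

  out <- data.frame(
    protein_accession = accs,
    control_detected = as.integer(det_ctr),
    patient_detected = as.integer(det_pat),
    n_control = n_ctr,
    n_patient = n_pat,
    fisher_p = fisher_p,
    welch_p_psm = welch_p_psm,
    welch_p_top3 = welch_p_top3,
    lfq_significant = lfq_sig,
    ratio_top3 = ratio_top3,
    ibaq_ratio = ibaq_ratio,
    ibaq_p = ibaq_p,
    ibaq_valid = ibaq_valid,
    ibaq_significant = ibaq_sig,
    significantly_altered = altered,
    direction = direction,
    stringsAsFactors = FALSE
  )
  out$fisher_p_bh <- stats::p.adjust(out$fisher_p, "BH")
  out$welch_p_psm_bh <- stats::p.adjust(out$welch_p_psm, "BH")
  out$welch_p_top3_bh <- stats::p.adjust(out$welch_p_top3, "BH")
  rownames(out) <- NULL
  out
}
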