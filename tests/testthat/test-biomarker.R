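test_that("full-specificity threshold makes every control negative", {
  expect_equal(full_specificity_threshold(c(1, 2, 3)), 3)
  expect_equal(full_specificity_threshold(rep(0, 15)), 0)
  expect_error(full_specificity_threshold(numeric(0)), "control")
  set.seed(3)
  for (i in 1:30) {
    ctr <- rlnorm(sample(2:20, 1L))
    thr <- full_specificity_threshold(ctr)
    expect_true(all(ctr <= thr))        # specificity exactly 1
    expect_true(any(ctr == thr))        # smallest such threshold
  }
})

test_that("sensitivity percents round half away from zero", {
  # 10/16 = 62.5 -> 63 and 11/16 = 68.75 -> 69
  expect_equal(sensitivity_at_full_specificity(c(rep(1, 10), rep(0, 6)), 0)$percent, 63L)
  expect_equal(sensitivity_at_full_specificity(c(rep(1, 11), rep(0, 5)), 0)$percent, 69L)
  s <- sensitivity_at_full_specificity(c(0.5, 2, 3), 1, n_patient = 16L)
  expect_equal(s$count, 2L)
  expect_equal(s$fraction, 2 / 16)
  expect_equal(s$percent, 13L)
  expect_equal(sensitivity_at_full_specificity(rep(0, 16), 0)$percent, 0L)
  # positivity is strictly above the threshold
  expect_equal(sensitivity_at_full_specificity(c(3, 3.1), 3)$count, 1L)
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(c(62.5, 68.75)), c(63, 69))
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.345, 2), 2.35)
})

test_that("Youden threshold maximizes J over all candidate cuts", {
  y <- youden_threshold(c(1, 2), c(3, 4))
  expect_equal(y$j, 1)
  expect_gt(y$threshold, 2); expect_lt(y$threshold, 3)
  expect_equal(youden_threshold(c(1, 2, 3), c(1, 2, 3))$j, 0)
  set.seed(13)
  for (i in 1:50) {
    ctr <- round(rnorm(sample(3:12, 1L)), 1)
    pat <- round(rnorm(sample(3:12, 1L), 0.8), 1)
    y <- youden_threshold(ctr, pat)
    expect_equal(y$j, oracle_youden_j(ctr, pat), tolerance = 1e-12)
    # J at the Youden threshold is at least J at the full-specificity one
    thr_fs <- full_specificity_threshold(ctr)
    j_fs <- mean(pat > thr_fs) + mean(ctr <= thr_fs) - 1
    expect_gte(y$j + 1e-12, j_fs)
  }
})

test_that("ROC points form the expected staircase", {
  pts <- roc_points(1, 2)
  expect_equal(pts$fpr, c(0, 0, 1))
  expect_equal(pts$tpr, c(0, 1, 1))
  pts2 <- roc_points(c(1, 2), c(3, 4))
  expect_true(any(pts2$fpr == 0 & pts2$tpr == 1))  # perfect separation
  set.seed(19)
  for (i in 1:30) {
    ctr <- sample(1:6, sample(2:8, 1L), replace = TRUE)
    pat <- sample(2:8, sample(2:8, 1L), replace = TRUE)
    pts <- roc_points(ctr, pat)
    expect_equal(pts$fpr[1L], 0); expect_equal(pts$tpr[1L], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    # staircase agrees with per-threshold counting
    for (k in seq_len(nrow(pts))) {
      expect_equal(pts$fpr[k], mean(ctr > pts$threshold[k]))
      expect_equal(pts$tpr[k], mean(pat > pts$threshold[k]))
    }
  }
})

test_that("AUC equals the pairwise Mann-Whitney oracle with half-ties", {
  expect_equal(auc(c(1, 2), c(3, 4)), 1)
  expect_equal(auc(rep(2, 4), rep(2, 6)), 0.5)
  set.seed(29)
  for (i in 1:100) {
    ctr <- sample(1:10, sample(1:12, 1L), replace = TRUE)
    pat <- sample(1:10, sample(1:12, 1L), replace = TRUE)
    expect_equal(auc(ctr, pat), oracle_auc(ctr, pat), tolerance = 1e-12)
    # label swap reflects the AUC
    expect_equal(auc(pat, ctr), 1 - auc(ctr, pat), tolerance = 1e-12)
  }
})

test_that("OR-rule combination can only gain sensitivity at full specificity", {
  # marker A positive on patients 1..15, marker B on patient 16 only
  pat <- cbind(A = c(rep(2, 15), 0), B = c(rep(0, 15), 2))
  ctr <- cbind(A = rep(1, 15), B = rep(1, 15))
  thr <- c(A = 1, B = 1)
  comb <- combine_markers_or_rule(thr, pat, ctr)
  expect_equal(comb$sensitivity, 1)
  expect_equal(comb$specificity, 1)
  # combining a marker with itself changes nothing
  self <- combine_markers_or_rule(c(1, 1), pat[, c(1, 1)], ctr[, c(1, 1)])
  expect_equal(self$sensitivity, 15 / 16)
  expect_error(combine_markers_or_rule(1, pat, ctr), "mismatch")
  set.seed(37)
  for (i in 1:30) {
    cv <- matrix(rlnorm(30), 15, 2)
    pv <- matrix(rlnorm(32, 0.5), 16, 2)
    th <- apply(cv, 2L, max)
    comb <- combine_markers_or_rule(th, pv, cv)
    singles <- vapply(1:2, function(j) mean(pv[, j] > th[j]), numeric(1L))
    expect_gte(comb$sensitivity, max(singles))
    expect_equal(comb$specificity, 1)
  }
})

test_that("rank-score panel AUC behaves on degenerate combinations", {
  set.seed(43)
  ctr <- rnorm(10); pat <- rnorm(12, 1)
  vals <- c(ctr, pat)
  labels <- rep(c("control", "patient"), c(10, 12))
  single <- auc(ctr, pat)
  # identical markers -> combined equals single (ranks are shared)
  expect_equal(combined_rank_score_auc(cbind(vals, vals), labels), single)
  # two perfectly separating markers -> combined AUC 1
  sep <- c(sort(rnorm(10)), sort(rnorm(12)) + 100)
  expect_equal(combined_rank_score_auc(cbind(sep, sep + rnorm(22, sd = 1e-3)),
                                       labels), 1)
})

test_that("complementary markers usually raise the combined AUC", {
  set.seed(47)
  gains <- replicate(200, {
    n_c <- 15L; n_p <- 16L
    # each marker informative on a different half of the patients
    active1 <- c(rep(TRUE, 8), rep(FALSE, 8))
    m1 <- c(rnorm(n_c), rnorm(n_p) + ifelse(active1, 3, 0))
    m2 <- c(rnorm(n_c), rnorm(n_p) + ifelse(!active1, 3, 0))
    labels <- rep(c("control", "patient"), c(n_c, n_p))
    a1 <- auc(m1[1:n_c], m1[-(1:n_c)])
    a2 <- auc(m2[1:n_c], m2[-(1:n_c)])
    combined_rank_score_auc(cbind(m1, m2), labels) >= max(a1, a2)
  })
  expect_gte(mean(gains), 0.95)
})

test_that("focus-list criteria are applied with inclusive boundaries", {
  differential <- data.frame(
    protein_accession = c("in1", "lowsens", "down_in", "weak_fc", "notsig"),
    lfq_significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    ibaq_significant = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    ibaq_valid = TRUE,
    ibaq_ratio = c(2.1, 3.0, 0.48, 1.6, 9.0),
    stringsAsFactors = FALSE
  )
  markers <- data.frame(
    protein_accession = differential$protein_accession,
    sensitivity_full_spec = c(0.56, 0.40, 0.50, 0.75, 0.94),
    stringsAsFactors = FALSE
  )
  fl <- focus_list_filter(differential, markers)
  expect_setequal(fl$protein_accession, c("in1", "down_in"))
  # 0.48 down-regulation is a 2.08-fold effect
  expect_equal(fl$effect[fl$protein_accession == "down_in"], 1 / 0.48,
               tolerance = 1e-12)
  # ordering: sensitivity desc, then effect desc
  expect_equal(fl$protein_accession, c("in1", "down_in"))
  # exact 1.75-fold boundary is retained
  differential$ibaq_ratio[4] <- 1.75
  fl2 <- focus_list_filter(differential, markers)
  expect_true("weak_fc" %in% fl2$protein_accession)
  expect_error(
    focus_list_filter(differential,
                      markers[markers$protein_accession != "in1", ]),
    "in1"
  )
})

test_that("exclusion filter removes confounded candidates and reports them", {
  cand <- data.frame(protein_accession = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  expect_message(out <- exclusion_filter(cand, c("b", "zzz")), "b")
  expect_equal(out$protein_accession, c("a", "c"))
  expect_equal(attr(out, "removed"), "b")
  expect_equal(exclusion_filter(cand, character(0))$protein_accession,
               cand$protein_accession)
})

test_that("heat-map positivity matrix is consistent with sensitivity counts", {
  fx <- generate_worked_example_fixture()
  vals <- t(rbind(fx$control, fx$patient))
  m <- protein_quant_matrix(vals, rep(c("control", "patient"), c(15, 16)),
                            "TOP3TIC")
  thr <- apply(fx$control, 2L, max)
  hm <- biomarker_heatmap_matrix(m, thr)
  # control rows all negative at full-specificity thresholds
  expect_true(all(!hm[rownames(fx$control), ]))
  # per-marker patient sums reproduce the intended positive counts
  expect_equal(colSums(hm[rownames(fx$patient), ]), fx$n_positive)
})

test_that("marker evaluation table round-trips the fixture patterns", {
  fx <- generate_worked_example_fixture()
  vals <- t(rbind(fx$control, fx$patient))
  m <- protein_quant_matrix(vals, rep(c("control", "patient"), c(15, 16)),
                            "TOP3TIC")
  ev <- evaluate_markers(m)
  expect_equal(ev$n_patients_positive,
               unname(fx$n_positive[ev$protein_accession]))
  expect_equal(ev$sensitivity_percent[ev$protein_accession == "tm256_like"], 94L)
  # thresholds really silence every control
  for (k in seq_len(nrow(ev))) {
    acc <- ev$protein_accession[k]
    expect_true(all(fx$control[, acc] <= ev$threshold_full_spec[k]))
  }
  # Youden J never below J at the full-specificity threshold
  expect_true(all(ev$youden_j + 1e-12 >=
                    ev$n_patients_positive / 16 + 1 - 1))
})
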