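test_that("tabular writers and readers round-trip", {
  tmp <- withr::local_tempdir()
  ev <- make_mini_evidence()
  write_evidence_tsv(ev, file.path(tmp, "ev.tsv"))
  expect_equal(read_evidence_tsv(file.path(tmp, "ev.tsv")), ev)

  rd <- mini_run_design()
  write_design_tsv(rd, file.path(tmp, "design.tsv"))
  expect_equal(read_design_tsv(file.path(tmp, "design.tsv")), rd)

  m <- protein_quant_matrix(
    matrix(c(0, 1.5, 2.25, 3), 2,
           dimnames = list(c("p1", "p2"), c("s1", "s2"))),
    groups = c("control", "patient"), channel = "TOP3TIC"
  )
  write_quant_matrix_tsv(m, file.path(tmp, "m.tsv"))
  m2 <- read_quant_matrix_tsv(file.path(tmp, "m.tsv"),
                              groups = c("control", "patient"),
                              channel = "TOP3TIC")
  expect_equal(m2$values, m$values)
  expect_equal(m2$detected, m$detected)
})

test_that("FASTA writer and reader round-trip with first-token accessions", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(P1 = "MKRAAKC", P2 = "AAAAAAK")
  write_fasta_sequences(seqs, tmp)
  expect_equal(read_fasta_sequences(tmp), seqs)
  # accession is the first whitespace-delimited header token
  writeLines(c(">ACC1 some description", "MKR", ">ACC2\tother", "AAK"), tmp)
  expect_equal(read_fasta_sequences(tmp), c(ACC1 = "MKR", ACC2 = "AAK"))
})

test_that("pairwise overlap percent is symmetric and rounded for display", {
  a <- protein_set("a", as.character(1:1644))
  b <- protein_set("b", as.character(1:1536))
  ov <- pairwise_overlap(a, b)
  expect_equal(ov$shared, 1536L)
  expect_equal(ov$union, 1644L)
  expect_equal(ov$percent, 93L)
  expect_equal(pairwise_overlap(b, a)$percent, 93L)
  expect_equal(pairwise_overlap(a, a)$percent, 100L)
  expect_equal(pairwise_overlap(a, protein_set("c", "x"))$percent, 0L)
})

test_that("Venn region counts match brute-force membership enumeration", {
  s1 <- protein_set("one", c("a", "b"))
  s2 <- protein_set("two", c("c", "d", "e"))
  disjoint <- multiset_intersection_counts(list(s1, s2))
  expect_equal(sum(disjoint$count), 5L)
  expect_equal(disjoint$count[disjoint$one & disjoint$two], 0L)
  same <- multiset_intersection_counts(list(s1, protein_set("two", c("a", "b"))))
  expect_equal(same$count[same$one & same$two], 2L)
  expect_equal(sum(same$count), 2L)
  set.seed(61)
  sets <- lapply(1:4, function(i) {
    protein_set(paste0("s", i), sample(letters, sample(5:20, 1L)))
  })
  regions <- multiset_intersection_counts(sets)
  uni <- unique(unlist(lapply(sets, `[[`, "accessions")))
  expect_equal(sum(regions$count), length(uni))
  # spot-check each region against direct membership counting
  member <- sapply(sets, function(s) uni %in% s$accessions)
  for (r in seq_len(nrow(regions))) {
    pattern <- unlist(regions[r, 1:4])
    expect_equal(regions$count[r],
                 sum(apply(member, 1L, function(m) all(m == pattern))))
  }
  expect_error(multiset_intersection_counts(list(s1)), "between 2 and 4")
})

test_that("top-n abundance share matches a manual sort-and-sum", {
  vals <- matrix(rep(1, 100 * 2), 100,
                 dimnames = list(paste0("p", 1:100), c("s1", "s2")))
  m <- protein_quant_matrix(vals, c("control", "control"), "IBAQ")
  expect_equal(top_n_abundance_share(m, 25L, "control"), 25)
  expect_warning(full <- top_n_abundance_share(m, 500L, "control"), "protein count")
  expect_equal(full, 100)
  set.seed(71)
  r <- matrix(rlnorm(300), 100,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:3)))
  mr <- protein_quant_matrix(r, rep("patient", 3), "IBAQ")
  means <- rowMeans(r)
  expect_equal(top_n_abundance_share(mr, 10L, "patient"),
               100 * sum(sort(means, decreasing = TRUE)[1:10]) / sum(means))
})

test_that("ratio interval summary counts inclusively and preserves totals", {
  expect_equal(ratio_distribution_summary(rep(1, 5))$n_in, 5L)
  s <- ratio_distribution_summary(c(0.4, 1.0, 3.0))
  expect_equal(s$n_in, 1L); expect_equal(s$n_out, 2L)
  # inclusive bounds; Inf counts as outside
  s2 <- ratio_distribution_summary(c(0.5, 2, Inf))
  expect_equal(s2$n_in, 2L); expect_equal(s2$n_out, 1L)
  set.seed(81)
  r <- rlnorm(500, 0, 1)
  s3 <- ratio_distribution_summary(r)
  expect_equal(s3$n_in, sum(r >= 0.5 & r <= 2))
  expect_equal(s3$n_in + s3$n_out, 500L)
})

test_that("pipeline runs end to end, writes outputs and is reproducible", {
  co <- generate_cohort(small_config(seed = 91L))
  tmp <- withr::local_tempdir()
  res <- run_pipeline(co, out_dir = tmp)
  expect_true(all(c("differential_results.tsv", "marker_evaluation.tsv",
                    "focus_list.tsv", "run_design.tsv", "manifest.json")
                  %in% list.files(tmp)))
  manifest <- jsonlite::read_json(file.path(tmp, "manifest.json"))
  expect_equal(manifest$seed, 91L)
  expect_equal(manifest$package, "exomarker")
  # identical rerun from the same seed
  res2 <- run_pipeline(generate_cohort(small_config(seed = 91L)))
  expect_equal(res$differential, res2$differential)
  expect_equal(res$summary, res2$summary)
  # summary is internally consistent
  expect_equal(res$summary$n_focus, nrow(res$focus_list))
  expect_equal(res$summary$n_lfq_significant,
               sum(res$differential$lfq_significant))
})

test_that("pipeline applies the confounder exclusion to the focus list", {
  co <- generate_cohort(small_config(seed = 93L))
  res <- run_pipeline(co)
  if (nrow(res$focus_list) > 0L) {
    drop <- res$focus_list$protein_accession[1L]
    suppressMessages(
      res2 <- run_pipeline(co, confounder_set = drop)
    )
    expect_false(drop %in% res2$focus_list$protein_accession)
    expect_equal(nrow(res2$focus_list), nrow(res$focus_list) - 1L)
  } else {
    succeed("focus list empty for this seed")
  }
})

test_that("published focus-list table loads with its documented columns", {
  tab <- published_focus_candidates()
  expect_equal(nrow(tab), 37L)
  expect_true(all(c("accession", "present_ctr", "present_pat",
                    "sensitivity_pct", "n_pat_pos", "ibaq_ratio",
                    "abundance_ppm") %in% names(tab)))
  expect_true(all(tab$n_pat_pos <= tab$present_pat))
  # every printed ratio passes the inclusive 1.75-fold focus criterion
  expect_true(all(pmax(tab$ibaq_ratio, 1 / tab$ibaq_ratio) >= 1.75))
})
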