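#' Run the full biomarker-discovery pipeline
#'
#' Executes quantification aggregation, differential testing, marker
#' evaluation and focus-list assembly on a cohort, optionally writing every
#' result table plus a reproducibility manifest to a directory. The cohort
#' may be a [generate_cohort()] object or an equivalent list with elements
#' `matrices` (sample-level `psm` and `top3` [protein_quant_matrix()]
#' objects), optional `ibaq_pools`, and optionally `truth` / `config`.
#'
#' @param cohort A `synthetic_cohort` or compatible list.
#' @param criteria [focus_criteria()] for the focus list.
#' @param alpha Significance level for all tests.
#' @param confounder_set Accessions to exclude from the focus list (e.g.
#'   markers confounded by sampling conditions).
#' @param threshold_type Threshold used for the positivity heat map:
#'   `"full_specificity"` (default) or `"youden"`.
#' @param out_dir Output directory for TSV tables and `manifest.json`, or
#'   `NULL` (default) to return results only.
#' @return List with `differential`, `markers`, `focus_list`, `heatmap`,
#'   `summary` (detected-protein counts, significant counts, ratio
#'   distribution, top-25 abundance shares, group overlap).
#' @export
run_pipeline <- function(cohort, criteria = focus_criteria(),
                         alpha = 0.05, confounder_set = character(0L),
                         threshold_type = c("full_specificity", "youden"),
                         out_dir = NULL) {
  threshold_type <- match.arg(threshold_type)
  m <- cohort$matrices
  if (is.null(m$psm) || is.null(m$top3)) {
    stop("cohort must provide sample-level `psm` and `top3` matrices",
         call. = FALSE)
  }

  differential <- differential_analysis(m$psm, m$top3,
                                        ibaq_pools = cohort$ibaq_pools,
                                        alpha = alpha)
  markers <- evaluate_markers(m$top3)
  focus <- focus_list_filter(differential, markers, criteria)
  focus <- exclusion_filter(focus, confounder_set)

  thr_col <- if (threshold_type == "full_specificity") {
    "threshold_full_spec"
  } else {
    "threshold_youden"
  }
  top_markers <- markers[markers$protein_accession %in%
                           focus$protein_accession, , drop = FALSE]
  heatmap <- if (nrow(top_markers) > 0L) {
    biomarker_heatmap_matrix(
      m$top3,
      stats::setNames(top_markers[[thr_col]], top_markers$protein_accession)
    )
  } else {
    NULL
  }

  ctr_cols <- group_columns(m$top3, "control")
  pat_cols <- group_columns(m$top3, "patient")
  det <- m$top3$detected | m$psm$detected
  ctr_set <- protein_set("control", rownames(det)[rowSums(det[, ctr_cols, drop = FALSE]) > 0])
  pat_set <- protein_set("patient", rownames(det)[rowSums(det[, pat_cols, drop = FALSE]) > 0])
  summary <- list(
    n_proteins = nrow(m$top3$values),
    mean_detected_control = mean(colSums(det[, ctr_cols, drop = FALSE])),
    mean_detected_patient = mean(colSums(det[, pat_cols, drop = FALSE])),
    n_lfq_significant = sum(differential$lfq_significant),
    n_significantly_altered = sum(differential$significantly_altered),
    n_up = sum(differential$direction == "up"),
    n_down = sum(differential$direction == "down"),
    group_overlap = pairwise_overlap(ctr_set, pat_set),
    ratio_distribution = ratio_distribution_summary(differential$ratio_top3),
    top25_share_control = top_n_abundance_share(m$top3, 25L, "control"),
    top25_share_patient = top_n_abundance_share(m$top3, 25L, "patient"),
    n_focus = nrow(focus)
  )

  result <- list(differential = differential, markers = markers,
                 focus_list = focus, heatmap = heatmap, summary = summary)
  if (!is.null(out_dir)) {
    .write_pipeline_outputs(result, cohort, out_dir)
  }
  result
}

.write_pipeline_outputs <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$differential, file.path(out_dir, "differential_results.tsv"))
  .write_tsv(result$markers, file.path(out_dir, "marker_evaluation.tsv"))
  focus <- result$focus_list
  attr(focus, "removed") <- NULL
  .write_tsv(focus, file.path(out_dir, "focus_list.tsv"))
  if (!is.null(result$heatmap)) {
    hm <- data.frame(sample_id = rownames(result$heatmap),
                     result$heatmap + 0L, check.names = FALSE)
    .write_tsv(hm, file.path(out_dir, "biomarker_heatmap.tsv"))
  }
  if (!is.null(cohort$run_design)) {
    write_design_tsv(cohort$run_design, file.path(out_dir, "run_design.tsv"))
  }
  manifest <- list(
    package = "exomarker",
    package_version = as.character(utils::packageVersion("exomarker")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = if (!is.null(cohort$config)) cohort$config$seed else NULL,
    parameters = if (!is.null(cohort$config)) {
      unclass(cohort$config)
    } else {
      NULL
    },
    outputs = vapply(
      list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE),
      function(f) unname(tools::md5sum(f)), character(1L)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
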