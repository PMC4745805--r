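#' Protein quantification matrix
#'
#' Container for one quantification channel: a proteins x samples (or
#' proteins x runs, or proteins x pools) matrix of non-negative abundances
#' with a parallel detection matrix and a group label per column. A value of
#' exactly zero means "not detected"; the `detected` matrix is derived from
#' that convention and kept alongside so downstream presence/absence tests
#' need no threshold of their own.
#'
#' @param values Numeric matrix, proteins in rows (rownames = accessions),
#'   observation units in columns (colnames = sample/run/pool ids). All
#'   values must be non-negative and finite.
#' @param groups Character vector of group labels, one per column (e.g.
#'   `"control"` / `"patient"`).
#' @param channel Quantification channel, one of `"PSM"`, `"TOP3TIC"`,
#'   `"IBAQ"`.
#' @return An object of class `protein_quant_matrix`: a list with elements
#'   `values`, `detected`, `groups`, `channel`.
#' @export
protein_quant_matrix <- function(values, groups,
                                 channel = c("PSM", "TOP3TIC", "IBAQ")) {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have protein accessions as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("row and column labels of a quantification matrix must be unique",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundance values must be finite and non-negative", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("`groups` must have one label per column", call. = FALSE)
  }
  structure(
    list(
      values = values,
      detected = values > 0,
      groups = stats::setNames(groups, colnames(values)),
      channel = channel
    ),
    class = "protein_quant_matrix"
  )
}

#' @export
print.protein_quant_matrix <- function(x, ...) {
  cat(sprintf(
    "protein_quant_matrix [%s]: %d proteins x %d columns (%s)\n",
    x$channel, nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
          collapse = ", ")
  ))
  cat(sprintf("detected entries: %.1f%%\n", 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.protein_quant_matrix <- function(x) dim(x$values)

#' Rescale every column to a common reference total
#'
#' Rescales each column so that its sum equals `reference_total`, preserving
#' within-column ratios. This is the "normalize to the reference pool total"
#' step used before comparing pooled iBAQ replicates: it removes per-column
#' loading differences, at the cost of folding any genuine difference in
#' total abundance between groups into the per-protein ratios.
#'
#' @param x A [protein_quant_matrix()].
#' @param reference_total Positive scalar; the common column total after
#'   normalization.
#' @return A `protein_quant_matrix` with rescaled values.
#' @export
normalize_to_reference_total <- function(x, reference_total) {
  stopifnot(inherits(x, "protein_quant_matrix"),
            is.numeric(reference_total), length(reference_total) == 1L,
            reference_total > 0)
  totals <- colSums(x$values)
  zero <- totals <= 0
  if (any(zero)) {
    stop(sprintf("column(s) with zero total abundance: %s",
                 paste(colnames(x$values)[zero], collapse = ", ")),
         call. = FALSE)
  }
  out <- x
  out$values <- sweep(x$values, 2L, reference_total / totals, `*`)
  out$detected <- out$values > 0
  out
}

#' Relative abundance in parts per million
#'
#' Expresses each value as a fraction of its column total, scaled to parts
#' per million, so every column sums to 1e6. This is the "ppm of total
#' proteome" display used for candidate-marker abundance.
#'
#' @param x A [protein_quant_matrix()].
#' @return Numeric matrix of the same shape as `x$values`.
#' @export
ppm_abundance <- function(x) {
  stopifnot(inherits(x, "protein_quant_matrix"))
  totals <- colSums(x$values)
  zero <- totals <= 0
  if (any(zero)) {
    stop(sprintf("column(s) with zero total abundance: %s",
                 paste(colnames(x$values)[zero], collapse = ", ")),
         call. = FALSE)
  }
  sweep(x$values, 2L, 1e6 / totals, `*`)
}

#' Collapse technical replicate runs into samples
#'
#' Per-sample abundance is the mean over that sample's runs; a protein
#' counts as detected in a sample when it was detected in at least one run.
#'
#' @param x A run-level [protein_quant_matrix()] whose columns are run ids.
#' @param run_design Data frame with columns `run_id`, `sample_id`, `group`;
#'   one row per run, every column of `x` must appear exactly once.
#' @return A sample-level `protein_quant_matrix`, columns ordered by first
#'   appearance of each sample in `run_design`. Detection is recorded from
#'   the any-run rule, so a sample can be flagged detected even when run
#'   averaging would keep the value positive anyway (values are means of
#'   non-negative runs, so value 0 still coincides with "no run detected").
#' @export
aggregate_replicates <- function(x, run_design) {
  stopifnot(inherits(x, "protein_quant_matrix"))
  .check_run_design(run_design)
  runs <- colnames(x$values)
  unknown <- setdiff(runs, run_design$run_id)
  if (length(unknown) > 0L) {
    stop(sprintf("run(s) not present in the design: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rd <- run_design[match(runs, run_design$run_id), , drop = FALSE]
  sample_ids <- unique(rd$sample_id)
  vals <- matrix(0, nrow(x$values), length(sample_ids),
                 dimnames = list(rownames(x$values), sample_ids))
  det <- matrix(FALSE, nrow(x$values), length(sample_ids),
                dimnames = dimnames(vals))
  for (s in sample_ids) {
    cols <- runs[rd$sample_id == s]
    vals[, s] <- rowMeans(x$values[, cols, drop = FALSE])
    det[, s] <- rowSums(x$detected[, cols, drop = FALSE]) > 0
  }
  out <- protein_quant_matrix(
    vals,
    groups = rd$group[match(sample_ids, rd$sample_id)],
    channel = x$channel
  )
  out$detected <- det
  out
}

.check_run_design <- function(run_design) {
  if (!is.data.frame(run_design) ||
      !all(c("run_id", "sample_id", "group") %in% names(run_design))) {
    stop("`run_design` must be a data frame with columns run_id, sample_id, group",
         call. = FALSE)
  }
  if (anyDuplicated(run_design$run_id)) {
    stop("duplicated run_id in design", call. = FALSE)
  }
  smp <- unique(run_design[, c("sample_id", "group")])
  if (anyDuplicated(smp$sample_id)) {
    stop("a sample_id is assigned to more than one group", call. = FALSE)
  }
  invisible(run_design)
}

#' Group-wise column indices of a quantification matrix
#'
#' @param x A [protein_quant_matrix()].
#' @param group Group label to select.
#' @return Integer vector of column indices.
#' @keywords internal
group_columns <- function(x, group) {
  which(unname(x$groups) == group)
}
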