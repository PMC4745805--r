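#' Read protein sequences from a FASTA file
#'
#' Accessions are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicated accessions in FASTA file", call. = FALSE)
  }
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector (names = accessions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

.read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = ""))
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read / write a peptide-evidence table
#'
#' TSV with mandatory header columns `peptide_sequence`,
#' `protein_accession`, `sample_id`, `run_id`, `precursor_intensity`,
#' `spectrum_count`.
#'
#' @param path File path.
#' @return `read_evidence_tsv`: the evidence data frame.
#' @export
read_evidence_tsv <- function(path) {
  ev <- .read_tsv(path)
  .check_evidence(ev)
  ev
}

#' @rdname read_evidence_tsv
#' @param evidence Evidence data frame.
#' @export
write_evidence_tsv <- function(evidence, path) {
  .check_evidence(evidence)
  .write_tsv(evidence[, .EVIDENCE_COLUMNS], path)
}

#' Read / write a run design table
#'
#' TSV with columns `run_id`, `sample_id`, `group`, one row per run.
#'
#' @param path File path.
#' @return `read_design_tsv`: the design data frame.
#' @export
read_design_tsv <- function(path) {
  d <- .read_tsv(path)
  .check_run_design(d)
  d
}

#' @rdname read_design_tsv
#' @param design Design data frame.
#' @export
write_design_tsv <- function(design, path) {
  .check_run_design(design)
  .write_tsv(design[, c("run_id", "sample_id", "group")], path)
}

#' Read / write a protein quantification matrix
#'
#' TSV layout: first column `protein_accession`, remaining columns one per
#' sample/run/pool. Group labels travel in the companion design file (or
#' are supplied directly to the reader).
#'
#' @param path File path.
#' @param groups Character vector of group labels, one per value column.
#' @param channel Quantification channel of the stored matrix.
#' @return `read_quant_matrix_tsv`: a [protein_quant_matrix()].
#' @export
read_quant_matrix_tsv <- function(path, groups,
                                  channel = c("PSM", "TOP3TIC", "IBAQ")) {
  d <- .read_tsv(path)
  if (names(d)[1L] != "protein_accession") {
    stop("first column of a quantification matrix must be protein_accession",
         call. = FALSE)
  }
  vals <- as.matrix(d[, -1L, drop = FALSE])
  rownames(vals) <- d$protein_accession
  protein_quant_matrix(vals, groups, match.arg(channel))
}

#' @rdname read_quant_matrix_tsv
#' @param x A `protein_quant_matrix`.
#' @export
write_quant_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "protein_quant_matrix"))
  d <- data.frame(protein_accession = rownames(x$values),
                  x$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  .write_tsv(d, path)
}

#' Named set of protein accessions
#'
#' @param name Set label (e.g. a study name).
#' @param accessions Character vector; duplicates are dropped.
#' @return An object of class `protein_set`.
#' @export
protein_set <- function(name, accessions) {
  structure(list(name = as.character(name),
                 accessions = unique(as.character(accessions))),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set '%s': %d accessions\n", x$name,
              length(x$accessions)))
  invisible(x)
}

#' Qualitative overlap of two protein sets
#'
#' Shared and union counts with the percent overlap (shared / union x 100)
#' rounded to an integer for display, the convention used when comparing
#' detected subproteomes between studies or groups.
#'
#' @param a,b [protein_set()] objects.
#' @return List with `shared`, `union`, `percent`.
#' @examples
#' pairwise_overlap(protein_set("x", letters[1:5]),
#'                  protein_set("y", letters[3:7]))
#' @export
pairwise_overlap <- function(a, b) {
  stopifnot(inherits(a, "protein_set"), inherits(b, "protein_set"))
  shared <- length(intersect(a$accessions, b$accessions))
  uni <- length(union(a$accessions, b$accessions))
  list(shared = shared, union = uni,
       percent = if (uni == 0L) NA_real_ else
         as.integer(round_half_up(100 * shared / uni)))
}

#' Venn region counts for up to four protein sets
#'
#' One count per membership pattern over the given sets; counts sum to the
#' size of the union.
#'
#' @param sets List of 2-4 [protein_set()] objects.
#' @return Data frame with one logical column per set and a `count` column;
#'   only non-empty-membership regions (at least one set) are listed.
#' @export
multiset_intersection_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 4L) {
    stop("between 2 and 4 sets are supported", call. = FALSE)
  }
  stopifnot(all(vapply(sets, inherits, logical(1L), "protein_set")))
  nm <- vapply(sets, `[[`, character(1L), "name")
  all_acc <- unique(unlist(lapply(sets, `[[`, "accessions")))
  member <- vapply(sets, function(s) all_acc %in% s$accessions,
                   logical(length(all_acc)))
  member <- matrix(member, nrow = length(all_acc),
                   dimnames = list(NULL, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- nm
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  patterns$count <- apply(patterns[, nm, drop = FALSE], 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  rownames(patterns) <- NULL
  patterns
}

#' Abundance share of the n most abundant proteins
#'
#' Percent of total group-mean abundance carried by the `n` most abundant
#' proteins of a group (a standard summary of proteome dynamic range).
#'
#' @param x Sample-level [protein_quant_matrix()].
#' @param n Number of top proteins (default 25); clamped with a warning
#'   when larger than the protein count.
#' @param group Group label whose columns are averaged.
#' @return Percent (scalar, full precision).
#' @export
top_n_abundance_share <- function(x, n = 25L, group) {
  stopifnot(inherits(x, "protein_quant_matrix"))
  cols <- group_columns(x, group)
  if (length(cols) == 0L) stop(sprintf("no columns in group '%s'", group),
                               call. = FALSE)
  means <- rowMeans(x$values[, cols, drop = FALSE])
  if (n > length(means)) {
    warning("n exceeds the protein count; using all proteins")
    n <- length(means)
  }
  100 * sum(sort(means, decreasing = TRUE)[seq_len(n)]) / sum(means)
}

#' Summarize the distribution of patient:control ratios
#'
#' Counts proteins whose ratio lies inside the (inclusive) interval
#' \[`lower`, `upper`\] versus outside of it; infinite ratios
#' (patient-unique proteins) count as outside.
#'
#' @param ratios Numeric vector of positive ratios (may contain `Inf`).
#' @param lower,upper Interval bounds (defaults 0.5 and 2).
#' @return List with `n_in`, `n_out`, `n_total`.
#' @export
ratio_distribution_summary <- function(ratios, lower = 0.5, upper = 2) {
  ratios <- ratios[!is.na(ratios)]
  inside <- ratios >= lower & ratios <= upper
  list(n_in = sum(inside), n_out = sum(!inside), n_total = length(ratios))
}

#' Published focus-list summary of urinary-exosome biomarker candidates
#'
#' The 37-candidate focus list of a published urinary-exosome biomarker
#' study of prostate cancer (15 controls, 16 patients), shipped as a
#' worked-example input: per protein, the detection counts in each group,
#' the printed sensitivity at the 100%-specificity threshold (percent and
#' positive-patient count), the validated iBAQ patient:control ratio and
#' the abundance in ppm of total proteome. Used in regression tests of the
#' reporting conventions (percent rounding, inclusive fold-change
#' boundary).
#'
#' @return Data frame with columns `rank`, `accession`, `protein_name`,
#'   `present_ctr`, `present_pat`, `sensitivity_pct`, `n_pat_pos`,
#'   `ibaq_ratio`, `abundance_ppm`.
#' @export
published_focus_candidates <- function() {
  .read_tsv(system.file("extdata", "published_focus_list.tsv",
                        package = "exomarker", mustWork = TRUE))
}
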