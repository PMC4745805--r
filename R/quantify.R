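#' Top-3 precursor intensity summary (Top3TIC)
#'
#' Protein abundance proxy from the most intense peptide precursor signals:
#' the mean of the three largest peptide intensities, or the mean of those
#' present when fewer than three peptides were observed, and 0 with no
#' evidence at all. The mean (rather than the sum) keeps proteins with one
#' or two observed peptides on the same scale as fully covered ones; the
#' aggregator is exposed for callers preferring the summed variant.
#'
#' @param intensities Numeric vector of peptide precursor intensities for
#'   one protein in one run (one entry per distinct peptide).
#' @param n_top Number of top peptides to aggregate (default 3).
#' @param aggregate Function applied to the top intensities (default
#'   [mean()]).
#' @return Non-negative scalar.
#' @examples
#' top3_tic(c(1, 10, 20, 30)) # mean of 30, 20, 10
#' top3_tic(8)
#' @export
top3_tic <- function(intensities, n_top = 3L, aggregate = mean) {
  if (length(intensities) == 0L) return(0)
  stopifnot(is.numeric(intensities), all(is.finite(intensities)),
            all(intensities >= 0))
  top <- sort(intensities, decreasing = TRUE)
  aggregate(top[seq_len(min(n_top, length(top)))])
}

#' iBAQ abundance of a protein
#'
#' Intensity-based absolute quantification: the summed peptide intensity of
#' the protein divided by its number of theoretically observable tryptic
#' peptides (see [count_observable_peptides()]). Division by the observable
#' count puts proteins of different length and cleavability on a common,
#' approximately molar scale.
#'
#' @param total_protein_intensity Summed peptide precursor intensity
#'   (non-negative scalar).
#' @param observable_count Number of observable tryptic peptides (positive
#'   integer).
#' @return Non-negative scalar.
#' @export
ibaq_intensity <- function(total_protein_intensity, observable_count) {
  stopifnot(is.numeric(total_protein_intensity),
            length(total_protein_intensity) == 1L,
            is.finite(total_protein_intensity),
            total_protein_intensity >= 0)
  if (length(observable_count) != 1L || is.na(observable_count) ||
      observable_count == 0) {
    stop("protein has no observable peptides: iBAQ is undefined",
         call. = FALSE)
  }
  total_protein_intensity / observable_count
}

.EVIDENCE_COLUMNS <- c(
  "peptide_sequence", "protein_accession", "sample_id", "run_id",
  "precursor_intensity", "spectrum_count"
)

.check_evidence <- function(evidence) {
  miss <- setdiff(.EVIDENCE_COLUMNS, names(evidence))
  if (length(miss) > 0L) {
    stop(sprintf("evidence table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(evidence$precursor_intensity < 0) ||
      any(evidence$spectrum_count < 0)) {
    stop("precursor_intensity and spectrum_count must be non-negative",
         call. = FALSE)
  }
  if (any(!nzchar(evidence$peptide_sequence))) {
    stop("empty peptide_sequence in evidence table", call. = FALSE)
  }
  invisible(evidence)
}

#' Quantify peptide evidence into run-level protein matrices
#'
#' Collapses a peptide-evidence table into run-level protein quantification
#' matrices for three channels: spectral counts (PSM; summed spectrum
#' counts), Top3TIC (see [top3_tic()]) and, when protein sequences are
#' supplied, iBAQ (summed intensity over the observable-peptide count).
#' Duplicate rows for the same peptide in the same run (e.g. charge states)
#' are collapsed first: intensity by maximum, spectrum counts by sum.
#'
#' @param evidence Data frame with columns `peptide_sequence`,
#'   `protein_accession`, `sample_id`, `run_id`, `precursor_intensity`,
#'   `spectrum_count`.
#' @param run_design Data frame with columns `run_id`, `sample_id`, `group`.
#' @param sequences Named character vector of protein sequences (names =
#'   accessions) used for the iBAQ denominator, or `NULL` to skip the iBAQ
#'   channel.
#' @param config A [digest_config()] for the observable-peptide count.
#' @return Named list of run-level [protein_quant_matrix()] objects:
#'   `psm`, `top3` and (with sequences) `ibaq`.
#' @export
quantify_evidence <- function(evidence, run_design, sequences = NULL,
                              config = digest_config()) {
  .check_evidence(evidence)
  .check_run_design(run_design)
  ev <- data.table::as.data.table(evidence)
  unknown <- setdiff(unique(ev$run_id), run_design$run_id)
  if (length(unknown) > 0L) {
    stop(sprintf("evidence refers to run(s) absent from the design: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  # collapse duplicates of the same peptide within a run
  precursor_intensity <- spectrum_count <- peptide_sequence <- NULL
  protein_accession <- run_id <- intensity <- NULL
  pep <- ev[, list(
    intensity = max(precursor_intensity),
    spectra = sum(spectrum_count)
  ), by = list(protein_accession, run_id, peptide_sequence)]
  prot <- pep[, list(
    psm = sum(spectra),
    top3 = top3_tic(intensity),
    total = sum(intensity)
  ), by = list(protein_accession, run_id)]

  accs <- sort(unique(prot$protein_accession))
  runs <- run_design$run_id
  groups <- run_design$group
  to_matrix <- function(col) {
    m <- matrix(0, length(accs), length(runs),
                dimnames = list(accs, runs))
    m[cbind(match(prot$protein_accession, accs),
            match(prot$run_id, runs))] <- prot[[col]]
    m
  }
  out <- list(
    psm = protein_quant_matrix(to_matrix("psm"), groups, "PSM"),
    top3 = protein_quant_matrix(to_matrix("top3"), groups, "TOP3TIC")
  )
  if (!is.null(sequences)) {
    miss <- setdiff(accs, names(sequences))
    if (length(miss) > 0L) {
      stop(sprintf("no sequence provided for accession(s): %s",
                   paste(utils::head(miss, 5L), collapse = ", ")),
           call. = FALSE)
    }
    obs <- vapply(sequences[accs], count_observable_peptides, integer(1L),
                  config = config)
    if (any(obs == 0L)) {
      stop(sprintf("protein(s) with no observable peptides: %s",
                   paste(accs[obs == 0L], collapse = ", ")), call. = FALSE)
    }
    out$ibaq <- protein_quant_matrix(to_matrix("total") / obs, groups, "IBAQ")
  }
  out
}
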