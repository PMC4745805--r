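#' Digestion settings for in-silico trypsin
#'
#' Trypsin cleaves C-terminal of lysine (K) and arginine (R). With
#' `proline_restriction = TRUE` cleavage is suppressed when the next residue
#' is proline (the classical "no P" rule); the default keeps cleavage before
#' proline enabled, matching the "without proline restriction" convention of
#' MaxQuant-style searches. The observable-length window bounds which fully
#' cleaved peptides count towards the iBAQ denominator.
#'
#' @param max_missed_cleavages Maximum number of internal cleavage sites a
#'   reported peptide may contain (default 2).
#' @param proline_restriction Suppress cleavage before proline? Default
#'   `FALSE`.
#' @param observable_min_len,observable_max_len Length window, in residues,
#'   for peptides considered observable by LC-MS (defaults 7 and 30).
#' @return An object of class `digest_config`.
#' @examples
#' digest_config()
#' digest_config(max_missed_cleavages = 1)
#' @export
digest_config <- function(max_missed_cleavages = 2L,
                          proline_restriction = FALSE,
                          observable_min_len = 7L,
                          observable_max_len = 30L) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  observable_min_len <- as.integer(observable_min_len)
  observable_max_len <- as.integer(observable_max_len)
  stopifnot(
    length(max_missed_cleavages) == 1L, max_missed_cleavages >= 0L,
    is.logical(proline_restriction), length(proline_restriction) == 1L,
    observable_min_len >= 1L,
    observable_min_len <= observable_max_len
  )
  structure(
    list(
      max_missed_cleavages = max_missed_cleavages,
      proline_restriction = proline_restriction,
      observable_min_len = observable_min_len,
      observable_max_len = observable_max_len
    ),
    class = "digest_config"
  )
}

# the 20 canonical amino-acid one-letter codes
CANONICAL_AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty amino-acid string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% CANONICAL_AA)
  if (length(bad) > 0L) {
    stop(
      sprintf(
        "non-canonical residue '%s' at position %d of sequence",
        chars[bad[1L]], bad[1L]
      ),
      call. = FALSE
    )
  }
  chars
}

#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal of K and R (also before P unless
#' `config$proline_restriction`) and returns every peptide with up to
#' `config$max_missed_cleavages` internal cleavage sites. Peptides repeated
#' in the sequence are listed with their multiplicity.
#'
#' @param sequence Single amino-acid string (uppercase, 20 canonical
#'   letters).
#' @param config A [digest_config()].
#' @return Character vector of peptides, ordered by position then by number
#'   of missed cleavages.
#' @examples
#' tryptic_digest("AKPA", digest_config(max_missed_cleavages = 0))
#' tryptic_digest("MKRAAKC")
#' @export
tryptic_digest <- function(sequence, config = digest_config()) {
  stopifnot(inherits(config, "digest_config"))
  chars <- .check_sequence(sequence)
  n <- length(chars)
  # cleave after position i when residue i is K/R (and i+1 is not P under the
  # proline restriction); position n never cleaves (C-terminus)
  is_kr <- chars %in% c("K", "R")
  cut_after <- is_kr & seq_len(n) < n
  if (config$proline_restriction) {
    next_is_p <- c(chars[-1L] == "P", FALSE)
    cut_after <- cut_after & !next_is_p
  }
  bounds <- c(0L, which(cut_after), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_frag <- length(starts)
  peptides <- character(0L)
  for (m in 0:config$max_missed_cleavages) {
    if (m + 1L > n_frag) break
    i <- seq_len(n_frag - m)
    peptides <- c(peptides, substring(sequence, starts[i], ends[i + m]))
  }
  peptides
}

#' Count observable peptides of a protein
#'
#' Number of fully cleaved tryptic peptides (zero missed cleavages) whose
#' length falls inside the observable window of `config`. This is the iBAQ
#' denominator: the count of peptides the instrument could in principle
#' observe for the protein.
#'
#' @inheritParams tryptic_digest
#' @return Integer count (possibly zero).
#' @examples
#' count_observable_peptides("AAAAAAA") # single 7-mer, in window
#' count_observable_peptides("AK")      # both fragments too short
#' @export
count_observable_peptides <- function(sequence, config = digest_config()) {
  cfg0 <- config
  cfg0$max_missed_cleavages <- 0L
  peps <- tryptic_digest(sequence, cfg0)
  len <- nchar(peps)
  sum(len >= config$observable_min_len & len <= config$observable_max_len)
}
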