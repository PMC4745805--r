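# Independent oracles used to cross-check the implementation.

# Brute-force tryptic digest: enumerate every contiguous fragment bounded by
# two cleavage boundaries with at most `max_missed` internal sites.
oracle_digest <- function(sequence, max_missed = 2L,
                          proline_restriction = FALSE) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  sites <- which(ch %in% c("K", "R") & seq_len(n) < n)
  if (proline_restriction) sites <- sites[ch[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  out <- character(0L)
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      if (j - i - 1L <= max_missed) {
        out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j]))
      }
    }
  }
  out
}

# Closed-form Welch statistic with Welch-Satterthwaite degrees of freedom.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pairwise Mann-Whitney AUC: wins plus half-ties over all pairs.
oracle_auc <- function(control, patient) {
  s <- 0
  for (p in patient) for (ctl in control) {
    s <- s + (p > ctl) + 0.5 * (p == ctl)
  }
  s / (length(control) * length(patient))
}

# Exhaustive Youden search: best J over a dense grid of thresholds
# (every observed value, midpoints, and sentinels).
oracle_youden_j <- function(control, patient) {
  vals <- sort(unique(c(control, patient)))
  cand <- unique(c(-Inf, vals, vals - 1e-9, vals + 1e-9,
                   (head(vals, -1) + tail(vals, -1)) / 2, Inf))
  max(vapply(cand, function(t) {
    mean(patient > t) + mean(control <= t) - 1
  }, numeric(1L)))
}

# Random amino-acid sequence from the canonical alphabet.
random_aa_sequence <- function(len) {
  paste(sample(exomarker:::CANONICAL_AA, len, replace = TRUE), collapse = "")
}

# Small evidence table for quantification tests, built in code.
make_mini_evidence <- function() {
  data.frame(
    peptide_sequence = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK",
                         "FFFFFFK", "AAAAAAK",
                         "AAAAAAK", "CCCCCCK",
                         "GGGGGGR", "HHHHHHR"),
    protein_accession = c(rep("P1", 6L), rep("P1", 2L), rep("P2", 2L)),
    sample_id = c(rep("S1", 6L), rep("S2", 2L), rep("S1", 2L)),
    run_id = c(rep("S1_r1", 6L), rep("S2_r1", 2L), rep("S1_r1", 2L)),
    precursor_intensity = c(10, 40, 30, 20, 5, 8, 12, 6, 100, 50),
    spectrum_count = c(1L, 3L, 2L, 2L, 1L, 1L, 2L, 1L, 5L, 4L),
    stringsAsFactors = FALSE
  )
}

mini_run_design <- function() {
  data.frame(run_id = c("S1_r1", "S2_r1"),
             sample_id = c("S1", "S2"),
             group = c("control", "patient"),
             stringsAsFactors = FALSE)
}

# Small down-scaled synthetic configuration for fast tests.
small_config <- function(seed, n_proteins = 150L, ...) {
  synthetic_config(
    n_proteins = n_proteins,
    n_up = 12L, n_down = 3L,
    target_detected = as.integer(round(n_proteins * 1150 / 1600)),
    seed = seed, ...
  )
}
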