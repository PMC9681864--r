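# Shared fixtures, built in code.

# A minimal hand-written graded feature table (4 subjects, 6 patient-days).
tiny_records <- function() {
  tibble::tibble(
    subject_id = c("A", "A", "B", "B", "C", "D"),
    day = c(1, 2, 1, 2, 1, 1),
    delta_le1 = c(0, 0, 0, 1, 0, 0),
    delta_1_2 = c(0, 1, 0, 0, 0, 0),
    theta_4_5 = c(0, 1, 1, 0, 0, 0),
    gpds      = c(0, 0, 1, 1, 0, 0),
    pdr       = c(1, 0, 0, 0, 1, 1),
    alpha_ge9 = c(1, 0, 0, 0, 0, 1),
    burst_suppression = c(0, 0, 0, 0, 0, 0),
    icans = c(0, 2, 2, 4, 0, 1)
  )
}

# Feature-presence vector helper: a named 0/1 row over the full vocabulary.
fv_row <- function(present, subject = "X", day = 1, icans = NULL) {
  row <- tibble::tibble(subject_id = subject, day = day)
  for (f in veicans::feature_names()) row[[f]] <- as.integer(f %in% present)
  if (!is.null(icans)) row$icans <- icans
  row
}

# Brute-force pairwise accuracy of scores against grades (ties half).
brute_pair_accuracy <- function(scores, grades) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (grades[i] == grades[j]) next
    hi <- if (grades[i] > grades[j]) i else j
    lo <- if (grades[i] > grades[j]) j else i
    den <- den + 1
    d <- scores[hi] - scores[lo]
    num <- num + (d > 0) + 0.5 * (d == 0)
  }
  if (den == 0) NA_real_ else num / den
}

# Independent closed-form chi-square with (unfloored) continuity correction,
# computed cell-wise from expected counts.
chi2_cellwise <- function(a, n1, c, n2, correct = TRUE) {
  o <- c(a, n1 - a, c, n2 - c)
  rows <- c(a + c, n1 + n2 - a - c)
  e <- c(rows[1] * n1, rows[2] * n1, rows[1] * n2, rows[2] * n2) / (n1 + n2)
  corr <- if (correct) 0.5 else 0
  stat <- sum((abs(o - e) - corr)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}
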