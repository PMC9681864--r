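#' Default emission parameters for the synthetic cohort
#'
#' Per-feature logistic emission parameters: presence log-odds
#' `b0 + loading * severity`, where severity is the day's ICANS grade plus
#' Gaussian noise. Baselines were fixed once so that, at the cohort's mean
#' severity, marginal prevalences approximate the observed all-time-point
#' prevalences in the source cohort (e.g. PDR ~13%, GPDs ~5%, moderately low
#' voltage ~7%); loadings are non-negative for abnormal features and
#' non-positive for normal features so that prevalence moves with severity in
#' the clinically expected direction.
#'
#' @return tibble `feature`, `b0`, `loading`.
#' @export
default_emissions <- function() {
  tibble::tribble(
    ~feature,               ~b0,   ~loading,
    "beta",                 -0.39, -0.4,
    "pdr",                   1.13, -1.2,
    "awake_signs",           1.66, -0.5,
    "grda",                 -4.41,  0.3,
    "gpds",                 -4.92,  0.8,
    "lpds",                 -5.37,  0.5,
    "lrda",                 -4.60,  0.0,
    "low_voltage_moderate", -3.88,  0.5,
    "attenuation_brief",    -6.08,  0.7
  )
}

# Slowing-band emission: presence via logistic(p0 + p1 * severity); when
# present, a latent dominant frequency f0 - fslope * severity + noise is
# discretized at `cuts` into the band's 1 Hz bins (lower frequency at higher
# severity, matching the ordinal structure of the vocabulary).
default_bands <- function() {
  list(
    delta = list(p0 = 0.14, p1 = 0.50, f0 = 2.40, fslope = 0.25, fsd = 0.8,
                 cuts = c(1, 2, 3),
                 bins = c("delta_le1", "delta_1_2", "delta_2_3", "delta_3_4")),
    theta = list(p0 = 0.29, p1 = 0.30, f0 = 6.05, fslope = 0.35, fsd = 1.0,
                 cuts = c(5, 6),
                 bins = c("theta_4_5", "theta_5_6", "theta_6_8")),
    alpha = list(p0 = -0.20, p1 = -0.35, f0 = 9.00, fslope = 0.35, fsd = 1.0,
                 cuts = c(8, 9),
                 bins = c("alpha_le8", "alpha_8_9", "alpha_ge9"))
  )
}

#' Specify a synthetic CAR-T EEG cohort
#'
#' The generator emulates the structure of the study cohort: ~120 monitored
#' subjects with 1--14 EEG days each (mean about 3, truncated-geometric), a
#' slowly evolving ordinal ICANS grade per subject (Metropolis birth-death
#' chain whose stationary law is `grade_dist`, so the marginal grade mix is
#' stated, with `persistence` the probability of not even proposing a move
#' between consecutive days), a latent daily severity equal to the grade plus
#' Gaussian noise, and conditionally independent feature emissions given that
#' severity (which induces the observed feature co-occurrence). The default
#' `grade_dist` puts probability 0.50 on grades > 2, matching the 50/50
#' severe/non-severe day split of the source cohort. Severe EEG patterns are
#' emitted only on grade-4 days with small probability, and the seizure
#' indicator only on days of grade >= 3.
#'
#' @param n_subjects number of subjects (default 120).
#' @param day_geom_p geometric parameter for days per subject (truncated to
#'   `1..max_days`; 0.32 gives mean ~3).
#' @param max_days maximum EEG days per subject.
#' @param grade_dist probabilities over grades 0--4 (stationary law of the
#'   trajectory).
#' @param persistence day-to-day probability of keeping yesterday's grade
#'   without proposing a change, in \[0, 1\].
#' @param severity_sd SD of the latent severity noise around the grade.
#' @param table generating scoring table (used by recovery experiments as
#'   ground truth).
#' @param emissions non-band feature emission parameters, see
#'   [default_emissions()].
#' @param bands slowing-band emission parameters.
#' @param severe_prob per-severe-feature emission probability on grade-4 days.
#' @param seizure_prob seizure probability on days of grade >= 3.
#' @return list of class `veicans_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120, day_geom_p = 0.32, max_days = 14,
                        grade_dist = c(0.12, 0.18, 0.20, 0.32, 0.18),
                        persistence = 0.8, severity_sd = 0.5,
                        table = default_table(),
                        emissions = default_emissions(),
                        bands = default_bands(),
                        severe_prob = 0.02, seizure_prob = 0.06) {
  if (length(grade_dist) != 5 || any(grade_dist < 0) || sum(grade_dist) <= 0) {
    stop("grade_dist must be 5 non-negative probabilities", call. = FALSE)
  }
  if (persistence < 0 || persistence > 1 || severe_prob < 0 || severe_prob > 1 ||
      seizure_prob < 0 || seizure_prob > 1 || day_geom_p <= 0 || day_geom_p >= 1) {
    stop("invalid probability parameter", call. = FALSE)
  }
  bad <- dplyr::left_join(emissions, eeg_vocabulary(), by = "feature")
  if (any(bad$polarity == "abnormal" & bad$loading < 0) ||
      any(bad$polarity == "normal" & bad$loading > 0)) {
    stop("emission loadings must be >= 0 for abnormal and <= 0 for normal features",
         call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, day_geom_p = day_geom_p,
                 max_days = max_days, grade_dist = grade_dist / sum(grade_dist),
                 persistence = persistence, severity_sd = severity_sd,
                 table = table, emissions = emissions, bands = bands,
                 severe_prob = severe_prob, seizure_prob = seizure_prob),
            class = "veicans_cohort_spec")
}

#' Sample a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the same seed always yields an identical cohort.
#' @param n_records optional: keep sampling subjects beyond
#'   `spec$n_subjects` if needed and truncate so the cohort has exactly this
#'   many patient-day records.
#' @return list of class `veicans_cohort`: `records` (a valid feature table
#'   with `subject_id`, `day`, all vocabulary columns, `seizure`, `icans`),
#'   `latent` (tibble with the latent severity per day), `spec`.
#' @examples
#' cohort <- sample_cohort(cohort_spec(n_subjects = 10), seed = 1)
#' head(cohort$records)
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = 1, n_records = NULL) {
  stopifnot(inherits(spec, "veicans_cohort_spec"))
  vocab <- eeg_vocabulary()
  with_seed_(seed, {
    rows <- list()
    latent <- list()
    total <- 0L
    s <- 0L
    target <- n_records %||% Inf
    while ((is.null(n_records) && s < spec$n_subjects) ||
           (!is.null(n_records) && total < target)) {
      s <- s + 1L
      sid <- sprintf("S%03d", s)
      n_days <- min(spec$max_days, 1L + stats::rgeom(1, spec$day_geom_p))
      g <- integer(n_days)
      g[1] <- sample(0:4, 1, prob = spec$grade_dist)
      if (n_days > 1) for (d in 2:n_days) {
        g[d] <- g[d - 1]
        if (stats::runif(1) >= spec$persistence) {
          cand <- g[d - 1] + sample(c(-1L, 1L), 1)
          if (cand >= 0 && cand <= 4 &&
              stats::runif(1) < spec$grade_dist[cand + 1] / spec$grade_dist[g[d - 1] + 1]) {
            g[d] <- cand
          }
        }
      }
      sev <- g + stats::rnorm(n_days, 0, spec$severity_sd)
      m <- matrix(0L, nrow = n_days, ncol = nrow(vocab),
                  dimnames = list(NULL, vocab$feature))
      for (band in spec$bands) {
        present <- stats::runif(n_days) < stats::plogis(band$p0 + band$p1 * sev)
        if (any(present)) {
          f <- band$f0 - band$fslope * sev[present] +
            stats::rnorm(sum(present), 0, band$fsd)
          bin <- 1L + rowSums(outer(f, band$cuts, `>`))
          m[cbind(which(present), match(band$bins[bin], colnames(m)))] <- 1L
        }
      }
      for (i in seq_len(nrow(spec$emissions))) {
        e <- spec$emissions[i, ]
        m[, e$feature] <- as.integer(
          stats::runif(n_days) < stats::plogis(e$b0 + e$loading * sev))
      }
      for (f in severe_features()) {
        m[, f] <- as.integer(g == 4 & stats::runif(n_days) < spec$severe_prob)
      }
      seiz <- as.integer(g >= 3 & stats::runif(n_days) < spec$seizure_prob)
      rows[[s]] <- tibble::tibble(subject_id = sid, day = seq_len(n_days),
                                  tibble::as_tibble(m), seizure = seiz, icans = g)
      latent[[s]] <- tibble::tibble(subject_id = sid, day = seq_len(n_days),
                                    severity = sev)
      total <- total + n_days
    }
    records <- dplyr::bind_rows(rows)
    latent <- dplyr::bind_rows(latent)
    if (!is.null(n_records)) {
      records <- records[seq_len(n_records), , drop = FALSE]
      latent <- latent[seq_len(n_records), , drop = FALSE]
    }
    validate_feature_table(records)
    structure(list(records = records, latent = latent, spec = spec),
              class = "veicans_cohort")
  })
}

#' @export
print.veicans_cohort <- function(x, ...) {
  cat(sprintf("<veicans_cohort> %d records, %d subjects; grades >2: %.0f%%\n",
              nrow(x$records), length(unique(x$records$subject_id)),
              100 * mean(x$records$icans > 2)))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Samples a training cohort from the spec, trains a scoring table on it, and
#' compares the trained table to the generating table: sign compatibility of
#' the coefficients (a contradiction is a trained and generating coefficient
#' of strictly opposite sign; a zero is compatible with either), admissibility
#' violations of the trained table, and the held-out pairwise ranking
#' accuracy of both tables on an independently sampled cohort (gap =
#' generating accuracy - trained accuracy).
#'
#' @param spec a [cohort_spec()]; its `table` is the ground truth.
#' @param config a [train_config()].
#' @param seed integer seed (the held-out cohort uses a fixed offset of it).
#' @param n_records training cohort size in patient-days (default 315).
#' @param n_holdout held-out cohort size.
#' @return one-row tibble: `sign_match_rate`, `n_sign_contradictions`,
#'   `ordinal_violations`, `acc_generating`, `acc_trained`, `accuracy_gap`,
#'   `n_train`, `n_holdout_pairs`.
#' @export
recovery_experiment <- function(spec = cohort_spec(), config = train_config(),
                                seed = 1, n_records = 315, n_holdout = 315) {
  stopifnot(nrow(validate_table(spec$table)) == 0)
  train_cohort <- sample_cohort(spec, seed = seed, n_records = n_records)
  holdout <- sample_cohort(spec, seed = seed + 100003L, n_records = n_holdout)
  fit <- train_veicans(train_cohort$records, config)
  gen <- spec$table$coefficients
  got <- fit$table$coefficients[names(gen)]
  contra <- sum(sign(gen) * sign(got) < 0)
  ho <- holdout$records
  s_gen <- score_features(ho, spec$table)$ve_icans
  s_fit <- score_features(ho, fit$table)$ve_icans
  pr <- make_pairs(ho, features = character(0))
  acc_gen <- margin_accuracy(s_gen[pr$hi] - s_gen[pr$lo])
  acc_fit <- margin_accuracy(s_fit[pr$hi] - s_fit[pr$lo])
  tibble::tibble(
    sign_match_rate = 1 - contra / length(gen),
    n_sign_contradictions = contra,
    ordinal_violations = nrow(validate_table(fit$table)),
    acc_generating = acc_gen,
    acc_trained = acc_fit,
    accuracy_gap = acc_gen - acc_fit,
    n_train = nrow(train_cohort$records),
    n_holdout_pairs = pr$n_pairs
  )
}
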