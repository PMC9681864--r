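test_that("same seed reproduces the cohort exactly", {
  a <- sample_cohort(cohort_spec(n_subjects = 25), seed = 42)
  b <- sample_cohort(cohort_spec(n_subjects = 25), seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$latent, b$latent)
  c <- sample_cohort(cohort_spec(n_subjects = 25), seed = 43)
  expect_false(identical(a$records, c$records))
})

test_that("persistence 1 freezes each subject's grade trajectory", {
  co <- sample_cohort(cohort_spec(n_subjects = 30, persistence = 1), seed = 2)
  per_subj <- tapply(co$records$icans, co$records$subject_id,
                     function(g) length(unique(g)))
  expect_true(all(per_subj == 1))
})

test_that("generated cohorts satisfy the feature-table schema", {
  for (s in 1:3) {
    co <- sample_cohort(cohort_spec(n_subjects = 20), seed = s)
    expect_silent(validate_feature_table(co$records, require_icans = TRUE))
    expect_true(all(co$records$day >= 1 & co$records$day <= 14))
  }
})

test_that("zero severity loadings reproduce the baseline prevalences", {
  # emissions decouple from severity; prevalence must match plogis(b0)
  em <- default_emissions()
  em$loading <- 0
  bands <- default_bands()
  for (b in names(bands)) bands[[b]]$p1 <- 0
  spec <- cohort_spec(emissions = em, bands = bands)
  co <- sample_cohort(spec, seed = 77, n_records = 10000)
  for (i in seq_len(nrow(em))) {
    p <- plogis(em$b0[i])
    got <- mean(co$records[[em$feature[i]]])
    expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / 10000) + 1e-9)
  }
  for (b in names(bands)) {
    p <- plogis(bands[[b]]$p0)
    got <- mean(rowSums(co$records[bands[[b]]$bins]))
    expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("feature prevalence is monotone in the severity loading", {
  em_lo <- default_emissions()
  em_hi <- default_emissions()
  em_hi$loading[em_hi$feature == "gpds"] <- 1.6  # vs default 0.8
  p_lo <- mean(sample_cohort(cohort_spec(emissions = em_lo), seed = 5,
                             n_records = 10000)$records$gpds)
  p_hi <- mean(sample_cohort(cohort_spec(emissions = em_hi), seed = 5,
                             n_records = 10000)$records$gpds)
  expect_gt(p_hi, p_lo)
})

test_that("the default world reproduces the cohort's gross structure", {
  co <- sample_cohort(cohort_spec(), seed = 1, n_records = 315)
  expect_equal(nrow(co$records), 315)
  # about half the days severe (grade > 2), within +/- 10 points
  expect_lt(abs(mean(co$records$icans > 2) - 0.5), 0.10)
  # days per subject within the stated 1-14 range, mean around 3
  days <- table(co$records$subject_id)
  expect_true(all(days >= 1 & days <= 14))
  expect_lt(abs(mean(days) - 3), 1)
  # severe patterns only on grade-4 days, seizures only at grade >= 3
  sev <- rowSums(co$records[severe_features()]) > 0
  expect_true(all(co$records$icans[sev] == 4))
  expect_true(all(co$records$icans[co$records$seizure == 1] >= 3))
})

test_that("a signal-free world trains to a grade-uncorrelated table", {
  em <- default_emissions()
  em$loading <- 0
  bands <- default_bands()
  for (b in names(bands)) { bands[[b]]$p1 <- 0; bands[[b]]$fslope <- 0 }
  zero_tab <- scoring_table(c(gpds = 0))
  spec <- cohort_spec(emissions = em, bands = bands, table = zero_tab,
                      severe_prob = 0)
  co <- sample_cohort(spec, seed = 8, n_records = 250)
  fit <- train_veicans(co$records, train_config(lambda = 0.05))
  scores <- score_features(co$records, fit$table)$ve_icans
  r <- if (sd(scores) == 0) 0 else cor(scores, co$records$icans)
  expect_lt(abs(r), 0.25)
})

test_that("recovery experiment output is deterministic and well-formed", {
  r1 <- recovery_experiment(cohort_spec(n_subjects = 40),
                            train_config(lambda = 0.01), seed = 12,
                            n_records = 120, n_holdout = 120)
  r2 <- recovery_experiment(cohort_spec(n_subjects = 40),
                            train_config(lambda = 0.01), seed = 12,
                            n_records = 120, n_holdout = 120)
  expect_identical(r1, r2)
  expect_equal(r1$ordinal_violations, 0)
  expect_gte(r1$sign_match_rate, 0)
  expect_lte(r1$sign_match_rate, 1)
})
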