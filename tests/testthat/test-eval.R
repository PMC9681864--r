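test_that("fold assignment keeps subjects whole and balances sizes", {
  rec <- tibble::tibble(subject_id = rep(sprintf("S%02d", 1:10), each = 2),
                        day = rep(1:2, 10), gpds = 0,
                        icans = rep(c(0, 1, 2, 3, 4), 4))
  folds <- assign_folds(rec, k = 5, seed = 1)
  expect_equal(as.integer(table(folds$subjects$fold)), rep(2L, 5))
  # a subject with 14 records stays in one fold
  big <- dplyr::bind_rows(rec, tibble::tibble(
    subject_id = "BIG", day = 1:14, gpds = 0, icans = rep(2, 14)))
  fb <- assign_folds(big, k = 5, seed = 1)
  big_folds <- fb$records$fold[fb$records$subject_id == "BIG"]
  expect_equal(length(unique(big_folds)), 1)
  expect_error(assign_folds(rec[rec$subject_id %in% sprintf("S%02d", 1:3), ], k = 5),
               "fewer subjects")
})

test_that("stratified assignment beats random groupings on grade balance", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 40), seed = 13)
  rec <- cohort$records
  folds <- assign_folds(rec, k = 5, seed = 2)
  spread <- function(fold_of) {
    means <- tapply(rec$icans, fold_of, mean)
    max(means) - min(means)
  }
  ours <- spread(folds$records$fold)
  subjects <- unique(rec$subject_id)
  rand <- withr::with_seed(99, replicate(1000, {
    f <- sample(rep(1:5, length.out = length(subjects)))
    spread(f[match(rec$subject_id, subjects)])
  }))
  expect_lte(ours, quantile(rand, 0.10))
})

test_that("Pearson bootstrap handles exact and degenerate cases", {
  x <- 1:20
  p <- pearson_bootstrap(x, 2 * x + 1, n_boot = 200, seed = 1)
  expect_equal(p$r, 1)
  expect_equal(p$conf_low, 1)
  expect_equal(p$conf_high, 1)
  expect_equal(pearson_bootstrap(x, -x, n_boot = 50, seed = 1)$r, -1)
  expect_error(pearson_bootstrap(rep(1, 10), 1:10), "constant")
  expect_error(pearson_bootstrap(1:2, 1:2), "at least 3")
})

test_that("bootstrap CI covers the true correlation at nominal rate", {
  # replications of n = 50 bivariate normal with rho = 0.6; the observed
  # coverage is a binomial estimate, so the 93% criterion is tested with a
  # one-sided two-standard-error Monte-Carlo allowance
  rho <- 0.6
  reps <- 500
  cover <- withr::with_seed(2024, {
    replicate(reps, {
      x <- rnorm(50)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(50)
      ci <- pearson_bootstrap(x, y, n_boot = 1000, seed = sample.int(1e6, 1))
      ci$conf_low <= rho && rho <= ci$conf_high
    })
  })
  expect_gte(mean(cover), 0.93 - 2 * sqrt(0.93 * 0.07 / reps))
})

test_that("bootstrap CIs are monotone in confidence level at fixed seed", {
  withr::with_seed(5, { x <- rnorm(40); y <- x + rnorm(40) })
  ci95 <- pearson_bootstrap(x, y, n_boot = 500, seed = 7, conf = 0.95)
  ci99 <- pearson_bootstrap(x, y, n_boot = 500, seed = 7, conf = 0.99)
  expect_lte(ci99$conf_low, ci95$conf_low)
  expect_gte(ci99$conf_high, ci95$conf_high)
})

test_that("AUC equals the brute-force Mann-Whitney pair count", {
  # perfect separation and the null
  s <- c(1:5, 11:15); g <- c(rep(0, 5), rep(3, 5))
  expect_equal(auc_by_level(s, g, 2, n_boot = 50)$auc, 1)
  withr::with_seed(31, {
    s0 <- rnorm(2000); g0 <- sample(c(0, 3), 2000, replace = TRUE)
  })
  expect_equal(auc_by_level(s0, g0, 1, n_boot = 50)$auc, 0.5, tolerance = 0.05)
  # oracle equivalence on 100 random small instances
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(6:20, 1)
      scores <- sample(-3:10, n, replace = TRUE)  # many ties
      grades <- sample(c(0, 1, 2, 3, 4), n, replace = TRUE)
      x <- sample(1:4, 1)
      if (!any(grades == 0) || !any(grades >= x)) next
      keep <- grades == 0 | grades >= x
      s1 <- scores[keep][grades[keep] >= x]
      s0 <- scores[keep][grades[keep] == 0]
      u <- 0
      for (a in s1) for (b in s0) u <- u + (a > b) + 0.5 * (a == b)
      expect_equal(auc_by_level(scores, grades, x, n_boot = 2)$auc,
                   u / (length(s1) * length(s0)))
    }
  })
  expect_error(auc_by_level(1:5, rep(0, 5), 2), "non-empty")
})

test_that("AUC complements under score negation for tie-free scores", {
  withr::with_seed(23, {
    s <- rnorm(60)
    g <- sample(c(0, 2, 3), 60, replace = TRUE)
  })
  a1 <- auc_by_level(s, g, 2, n_boot = 2)$auc
  a2 <- auc_by_level(-s, g, 2, n_boot = 2)$auc
  expect_equal(a1, 1 - a2)
})

test_that("continuity-corrected chi-square matches the closed-form oracle", {
  r <- chi2_yates(2, 156, 14, 159)
  expect_equal(round(r$p_value, 4), 0.0054)
  # no correction: perfectly proportional table gives statistic 0, p 1
  r0 <- chi2_yates(10, 100, 20, 200, correct = FALSE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  withr::with_seed(41, {
    for (i in 1:50) {
      n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
      a <- sample(0:n1, 1); c <- sample(0:n2, 1)
      if ((a + c) == 0 || (a + c) == (n1 + n2)) next
      got <- chi2_yates(a, n1, c, n2)
      want <- chi2_cellwise(a, n1, c, n2)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
      # invariance under swapping groups and present/absent
      expect_equal(chi2_yates(c, n2, a, n1)$statistic, got$statistic)
      expect_equal(chi2_yates(n1 - a, n1, n2 - c, n2)$statistic, got$statistic)
    }
  })
  expect_error(chi2_yates(0, 50, 0, 60), "zero expected")
})

test_that("Mann-Whitney U matches brute force and handles ties", {
  expect_equal(mann_whitney(1:10, 1:10)$p_value, 1)
  sep <- mann_whitney(1:20, 101:120)
  expect_lt(sep$p_value, 1e-6)
  withr::with_seed(53, {
    for (i in 1:20) {
      x <- sample(0:5, sample(4:12, 1), replace = TRUE)
      y <- sample(0:5, sample(4:12, 1), replace = TRUE)
      u <- 0
      for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
      got <- mann_whitney(x, y)
      expect_equal(got$u, u)
      # independent implementation of the tie-corrected normal approximation
      ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("Spearman matrix flags constants and matches binary rank oracle", {
  rec <- tibble::tibble(subject_id = as.character(1:8), day = 1,
                        gpds = c(1, 1, 0, 0, 1, 0, 1, 0),
                        grda = c(1, 1, 0, 0, 1, 0, 1, 0),   # duplicate
                        pdr  = c(0, 0, 1, 1, 0, 1, 0, 1),   # complement
                        lpds = rep(0, 8))                   # constant
  rho <- spearman_features(rec)
  expect_equal(rho["gpds", "grda"], 1)
  expect_equal(rho["gpds", "pdr"], -1)
  expect_true(is.na(rho["gpds", "lpds"]))
  expect_equal(attr(rho, "constant_features"), "lpds")
  expect_equal(diag(rho), setNames(rep(1, 4), colnames(rho)))
  # phi coefficient oracle for binary features
  phi <- function(x, y) {
    n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y); n00 <- sum(!x & !y)
    (n11 * n00 - n10 * n01) /
      sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  }
  withr::with_seed(61, {
    rec2 <- tibble::tibble(subject_id = as.character(1:30), day = 1,
                           gpds = rbinom(30, 1, 0.4), pdr = rbinom(30, 1, 0.5),
                           grda = rbinom(30, 1, 0.3))
    rho2 <- spearman_features(rec2)
    expect_equal(rho2["gpds", "pdr"], phi(rec2$gpds, rec2$pdr), tolerance = 1e-12)
    expect_equal(rho2["grda", "pdr"], phi(rec2$grda, rec2$pdr), tolerance = 1e-12)
  })
})

test_that("nested CV pools each record once with no subject leakage", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 30), seed = 3)
  oracle <- function(train_records, config) function(new) new$icans
  ev <- nested_cv(cohort$records, k = 5, seed = 4, n_boot = 100,
                  train_fn = oracle)
  expect_equal(nrow(ev$predictions), nrow(cohort$records))
  expect_equal(sort(ev$predictions$row), seq_len(nrow(cohort$records)))
  expect_equal(ev$pearson$r, 1)
  # each subject's fold in predictions matches the grouped assignment
  by_subj <- tapply(ev$predictions$fold, ev$predictions$subject_id,
                    function(f) length(unique(f)))
  expect_true(all(by_subj == 1))
})

test_that("grade-independent random scores yield near-zero correlation", {
  cohort <- sample_cohort(cohort_spec(), seed = 6, n_records = 315)
  rs <- vapply(1:5, function(s) {
    noise_fn <- function(train_records, config) {
      function(new) withr::with_seed(s * 1000 + nrow(new), runif(nrow(new)))
    }
    ev <- nested_cv(cohort$records, k = 5, seed = s, n_boot = 10,
                    train_fn = noise_fn)
    abs(ev$pearson$r)
  }, numeric(1))
  expect_gte(mean(rs < 0.2), 0.8)
})

test_that("cohort contingency dichotomizes at grade 2 and runs the test", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 60), seed = 9)
  ct <- cohort_contingency(cohort$records)
  expect_equal(ct$n1[1] + ct$n2[1], nrow(cohort$records))
  expect_equal(ct$n1[1], sum(cohort$records$icans <= 2))
  pdr_row <- ct[ct$feature == "pdr", ]
  manual <- chi2_yates(pdr_row$a, pdr_row$n1, pdr_row$c, pdr_row$n2)
  expect_equal(pdr_row$p_value, manual$p_value)
})
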