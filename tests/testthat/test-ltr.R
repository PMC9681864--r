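test_that("minimum-prevalence filter applies the boundary and a-priori rules", {
  base <- tiny_records()[rep(1, 20), ]
  base$subject_id <- sprintf("S%02d", 1:20)
  base[feature_names()[!feature_names() %in% names(base)]] <- 0
  base$gpds <- c(rep(1, 4), rep(0, 16))       # 4 instances: below threshold
  base$theta_4_5 <- c(rep(1, 5), rep(0, 15))  # exactly 5: retained
  base$burst_suppression <- c(1, rep(0, 19))
  base$seizure <- 0
  flt <- filter_features(base, min_count = 5)
  expect_false("gpds" %in% flt$retained)
  expect_true("theta_4_5" %in% flt$retained)
  expect_match(flt$excluded$reason[flt$excluded$feature == "gpds"], "prevalence 4 < 5")
  expect_equal(flt$excluded$reason[flt$excluded$feature == "burst_suppression"],
               "severe a-priori")
  expect_equal(flt$excluded$reason[flt$excluded$feature == "seizure"],
               "seizure indicator")
})

test_that("pair expansion keeps strictly ordered pairs, higher grade first", {
  rec <- tibble::tibble(subject_id = c("a", "b", "c"), day = 1,
                        gpds = c(0, 1, 0), icans = c(0, 1, 1))
  p <- make_pairs(rec)
  expect_equal(p$n_pairs, 2)  # C(3,2) - C(2,2)
  expect_true(all(rec$icans[p$hi] > rec$icans[p$lo]))
  expect_true(all(p$diff %in% c(-1, 0, 1)))
  tied <- tibble::tibble(subject_id = letters[1:3], day = 1, gpds = 0:2 %% 2,
                         icans = 2)
  expect_warning(p0 <- make_pairs(tied), "all grades equal")
  expect_equal(p0$n_pairs, 0)
  # half-grades are ordered pairs; only exact ties are dropped
  half <- tibble::tibble(subject_id = c("a", "b"), day = 1, gpds = c(0, 1),
                         icans = c(2, 2.5))
  expect_equal(make_pairs(half)$n_pairs, 1)
})

test_that("pair count identity matches brute-force enumeration", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(20:100, 1)
      g <- sample(seq(0, 4, 0.5), n, replace = TRUE,
                  prob = c(4, 1, 3, 1, 3, 1, 3, 1, 2))
      rec <- tibble::tibble(subject_id = as.character(1:n), day = 1,
                            gpds = rbinom(n, 1, 0.3), icans = g)
      p <- make_pairs(rec)
      brute <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n) brute <- brute + (g[i] != g[j])
      expect_equal(p$n_pairs, brute)
      ng <- table(g)
      expect_equal(p$n_pairs, choose(n, 2) - sum(choose(ng, 2)))
    }
  })
})

test_that("pair expansion is invariant to translating all grades", {
  rec <- tiny_records()
  p1 <- make_pairs(rec)
  rec$icans <- rec$icans + 1.5
  p2 <- make_pairs(rec)
  expect_identical(p1$hi, p2$hi)
  expect_identical(p1$lo, p2$lo)
  expect_identical(p1$diff, p2$diff)
})

test_that("ranking fit respects signs and the penalty-dominated limit", {
  d <- matrix(1, nrow = 1, ncol = 1, dimnames = list(NULL, "gpds"))
  f <- fit_ranker(d, lambda = 0.01)
  expect_gt(f$w[["gpds"]], 0)
  f_inf <- fit_ranker(d, lambda = 1e6)
  expect_equal(unname(f_inf$w), 0)
})

test_that("two-feature fit matches a grid-search brute-force minimizer", {
  withr::with_seed(3, {
    d <- cbind(gpds = sample(c(-1, 0, 1), 30, replace = TRUE, prob = c(1, 2, 3)),
               grda = sample(c(-1, 0, 1), 30, replace = TRUE, prob = c(2, 2, 2)))
  })
  lambda <- 0.05; alpha <- 0.5
  obj <- function(w1, w2) {
    z <- d[, 1] * w1 + d[, 2] * w2
    mean(log1p(exp(-z))) + lambda * (alpha * (abs(w1) + abs(w2)) +
                                       (1 - alpha) / 2 * (w1^2 + w2^2))
  }
  # coarse-to-fine grid search (independent of the solver)
  grid <- seq(0, 3, by = 0.01)
  vals <- outer(grid, grid, Vectorize(obj))
  ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  fine1 <- seq(max(0, grid[ix[1]] - 0.01), grid[ix[1]] + 0.01, by = 1e-4)
  fine2 <- seq(max(0, grid[ix[2]] - 0.01), grid[ix[2]] + 0.01, by = 1e-4)
  vals2 <- outer(fine1, fine2, Vectorize(obj))
  ix2 <- which(vals2 == min(vals2), arr.ind = TRUE)[1, ]
  f <- fit_ranker(d, lambda = lambda, alpha = alpha, tol = 1e-10)
  expect_equal(unname(f$w[1]), fine1[ix2[1]], tolerance = 1e-3)
  expect_equal(unname(f$w[2]), fine2[ix2[2]], tolerance = 1e-3)
  expect_lte(obj(f$w[1], f$w[2]), min(vals2) + 1e-6)
})

test_that("integerization is a feasible fixed point and beats naive rounding", {
  # already-integer feasible vector is unchanged
  d <- cbind(delta_le1 = c(1, 0, -1, 1), delta_1_2 = c(0, 1, 0, -1))
  w <- c(delta_le1 = 10, delta_1_2 = 6)
  expect_equal(integerize(w, d, target_max_points = 10), c(delta_le1 = 10L, delta_1_2 = 6L))
  # ordinal constraint holds after rounding
  w2 <- c(delta_le1 = 2.4, delta_1_2 = 1.6)
  wi2 <- integerize(w2, d, target_max_points = 2.4)
  expect_gte(wi2[["delta_le1"]], wi2[["delta_1_2"]])
  expect_equal(wi2, round(wi2))
})

test_that("local search never does worse than rounding, vs exhaustive oracle", {
  feats <- c("delta_le1", "delta_1_2", "gpds", "pdr")
  withr::with_seed(19, {
    d <- matrix(sample(c(-1, 0, 1), 80, replace = TRUE), ncol = 4,
                dimnames = list(NULL, feats))
    w <- c(delta_le1 = 3.7, delta_1_2 = 2.2, gpds = 1.4, pdr = -0.8)
  })
  radius <- 2
  wi <- integerize(w, d, search_radius = radius, target_max_points = 4)
  acc <- function(v) {
    m <- as.vector(d %*% v)
    (sum(m > 0) + 0.5 * sum(m == 0)) / length(m)
  }
  rounded <- round(w * 4 / max(abs(w)))
  expect_gte(acc(wi), acc(rounded))
  # exhaustive enumeration of the feasible search box around the rounding
  cands <- expand.grid(lapply(seq_along(rounded), function(j) {
    rounded[j] + seq(-radius, radius)
  }))
  ok <- apply(cands, 1, function(v) {
    v[1] >= 0 && v[2] >= 0 && v[3] >= 0 && v[4] <= 0 && v[1] >= v[2]
  })
  best <- max(apply(cands[ok, ], 1, acc))
  expect_lte(acc(wi), best)  # sanity: cannot beat the exhaustive box optimum
})

test_that("training assembles an admissible table and handles degenerate input", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 40), seed = 8)
  fit <- train_veicans(cohort$records, train_config(lambda = 0.01))
  expect_s3_class(fit$table, "veicans_table")
  expect_equal(nrow(validate_table(fit$table)), 0)
  expect_true(all(fit$w_int == round(fit$w_int)))
  # a feature appearing 3 times is absent from the trained table
  rec <- cohort$records
  rec$lpds <- 0
  rec$lpds[1:3] <- 1
  fit3 <- train_veicans(rec, train_config(lambda = 0.01))
  expect_false("lpds" %in% fit3$retained)
  expect_equal(fit3$table$coefficients[["lpds"]], 0)
  # all one grade: no informative pairs
  flat <- dplyr::mutate(tiny_records(), icans = 0)
  expect_error(train_veicans(flat), "no informative pairs")
})

test_that("trained tables are reproducible given the seed", {
  cohort <- sample_cohort(cohort_spec(n_subjects = 30), seed = 21)
  cfg <- train_config(lambda = c(0.03, 0.01), seed = 5)
  f1 <- train_veicans(cohort$records, cfg)
  f2 <- train_veicans(cohort$records, cfg)
  expect_identical(f1$w_int, f2$w_int)
  expect_identical(f1$lambda, f2$lambda)
})
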