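#' Grouped stratified fold assignment
#'
#' Assigns whole subjects to folds (so no subject's records are ever split
#' across folds) while keeping the grade distribution of each fold as close
#' as possible to the overall distribution. Subjects are taken in decreasing
#' order of record count and greedily placed in the fold that minimizes the
#' spread of per-grade counts across folds; exact ties are broken first
#' toward the smallest fold and then by a seed-controlled shuffle, so the
#' assignment is deterministic given the seed.
#'
#' @param records patient-day table with `subject_id` and `icans` columns.
#' @param k number of folds.
#' @param seed integer seed for tie-breaking.
#' @return list of class `veicans_folds`: `subjects` (tibble `subject_id`,
#'   `fold`) and `records` (tibble `row`, `subject_id`, `fold`, one row per
#'   input record).
#' @export
assign_folds <- function(records, k = 5, seed = 1) {
  subjects <- unique(records$subject_id)
  if (length(subjects) < k) {
    stop("fewer subjects (", length(subjects), ") than folds (", k, ")", call. = FALSE)
  }
  levels_g <- sort(unique(records$icans))
  prof <- t(vapply(subjects, function(s) {
    tabulate(match(records$icans[records$subject_id == s], levels_g),
             nbins = length(levels_g))
  }, numeric(length(levels_g))))
  n_rec <- rowSums(prof)
  ord <- with_seed_(seed, {
    shuffle <- sample.int(length(subjects))
    shuffle[order(-n_rec[shuffle], shuffle)]
  })
  fold_counts <- matrix(0, nrow = k, ncol = length(levels_g))
  fold_sizes <- numeric(k)
  fold_subjects <- integer(k)
  cap <- ceiling(length(subjects) / k)  # keeps fold subject counts balanced
  fold_of <- stats::setNames(integer(length(subjects)), subjects)
  for (si in ord) {
    open <- which(fold_subjects < cap)
    cost <- vapply(open, function(f) {
      fc <- fold_counts
      fc[f, ] <- fc[f, ] + prof[si, ]
      mean(apply(fc, 2, stats::sd))
    }, numeric(1))
    best <- open[cost == min(cost)]
    if (length(best) > 1) best <- best[fold_sizes[best] == min(fold_sizes[best])]
    fold_of[si] <- best[1]
    fold_subjects[best[1]] <- fold_subjects[best[1]] + 1L
    fold_counts[best[1], ] <- fold_counts[best[1], ] + prof[si, ]
    fold_sizes[best[1]] <- fold_sizes[best[1]] + n_rec[si]
  }
  structure(list(
    subjects = tibble::tibble(subject_id = subjects, fold = unname(fold_of)),
    records = tibble::tibble(row = seq_len(nrow(records)),
                             subject_id = records$subject_id,
                             fold = unname(fold_of[match(records$subject_id, subjects)]))
  ), class = "veicans_folds")
}

#' Pearson correlation with percentile bootstrap confidence interval
#'
#' @param x,y equal-length numeric vectors (n >= 3, neither constant).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return one-row tibble: `r`, `conf_low`, `conf_high`, `n`, `n_boot`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  boots <- with_seed_(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
    else stats::cor(x[idx], y[idx])
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(r = r, conf_low = unname(qs[1]), conf_high = unname(qs[2]),
                 n = n, n_boot = n_boot)
}

#' Discrimination AUC at one severity level
#'
#' Area under the ROC curve for discriminating days without neurotoxicity
#' (grade 0) from days at or above severity `level` (grade >= level); days
#' with 0 < grade < level are excluded from the comparison. The AUC is the
#' Mann-Whitney rank statistic U/(n1*n0) with ties counted half; the CI is a
#' percentile bootstrap over the included records.
#'
#' @param scores numeric predicted scores.
#' @param grades ICANS grades aligned with `scores`.
#' @param level severity threshold x in (0, 4\].
#' @param n_boot,seed,conf bootstrap settings as in [pearson_bootstrap()].
#' @return one-row tibble: `level`, `auc`, `conf_low`, `conf_high`,
#'   `n_cases`, `n_controls`.
#' @export
auc_by_level <- function(scores, grades, level, n_boot = 1000, seed = 1,
                         conf = 0.95) {
  stopifnot(length(scores) == length(grades))
  keep <- grades == 0 | grades >= level
  s <- scores[keep]
  pos <- grades[keep] >= level
  if (!any(pos) || !any(!pos)) {
    stop("both classes (grade 0 and grade >= ", level, ") must be non-empty",
         call. = FALSE)
  }
  auc_stat <- function(s, pos) {
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(s)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_stat(s, pos)
  n <- length(s)
  boots <- with_seed_(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(pos[idx]) || !any(!pos[idx])) NA_real_
    else auc_stat(s[idx], pos[idx])
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(level = level, auc = auc,
                 conf_low = unname(qs[1]), conf_high = unname(qs[2]),
                 n_cases = sum(pos), n_controls = sum(!pos))
}

#' Nested grouped stratified cross-validation
#'
#' The outer loop splits subjects into `k` folds ([assign_folds()]); for each
#' outer fold an inner grouped CV over the penalty grid selects the penalty
#' strength on the training folds, the model is retrained at the selected
#' value, and the held-out fold is scored with the resulting integer table
#' (severe-pattern days receive the maximal score). Out-of-sample
#' performance is measured on the pooled held-out predictions: Pearson
#' correlation with the clinical grades (bootstrap CI) and per-level
#' discrimination AUC (grade 0 vs >= x for x = 1..4 where both classes
#' exist), plus the Spearman correlation matrix of the input features.
#'
#' @param records graded patient-day table.
#' @param config [train_config()]; its `lambda` grid drives the inner loop.
#' @param k number of outer folds (default 5).
#' @param seed integer seed (fold assignment and bootstrap).
#' @param n_boot bootstrap replicates for CIs.
#' @param train_fn optional model override for diagnostics: a
#'   `function(train_records, config)` returning a scoring function
#'   `function(new_records) -> numeric`. When supplied, it replaces the
#'   learning-to-rank training in every fold (e.g. an oracle that returns the
#'   grade itself, to validate the harness).
#' @param vocab feature vocabulary.
#' @return object of class `veicans_eval`: list with `predictions` (tibble
#'   `row`, `subject_id`, `day`, `icans`, `score`, `fold`, `lambda`),
#'   `pearson`, `auc`, `spearman`, `folds`, `fits` (per-fold `veicans_fit`s,
#'   or `NULL` under `train_fn`), `config`.
#' @export
nested_cv <- function(records, config = train_config(), k = 5, seed = 1,
                      n_boot = 1000, train_fn = NULL, vocab = eeg_vocabulary()) {
  records <- validate_feature_table(records, require_icans = TRUE, vocab = vocab)
  folds <- assign_folds(records, k = k, seed = seed)
  fold_of <- folds$records$fold
  score <- rep(NA_real_, nrow(records))
  lambda_used <- rep(NA_real_, nrow(records))
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- records[fold_of != f, , drop = FALSE]
    te <- records[fold_of == f, , drop = FALSE]
    if (length(intersect(tr$subject_id, te$subject_id))) {
      stop("internal error: subject leakage across folds", call. = FALSE)
    }
    if (is.null(train_fn)) {
      cfg <- config
      cfg$seed <- config$seed + f  # independent inner-fold tie-breaking
      fit <- train_veicans(tr, cfg, vocab = vocab)
      fits[[f]] <- fit
      score[fold_of == f] <- score_features(te, fit$table, vocab)$ve_icans
      lambda_used[fold_of == f] <- fit$lambda
    } else {
      scorer <- train_fn(tr, config)
      score[fold_of == f] <- scorer(te)
    }
  }
  stopifnot(!anyNA(score))
  preds <- tibble::tibble(row = seq_len(nrow(records)),
                          subject_id = records$subject_id, day = records$day,
                          icans = records$icans, score = score,
                          fold = fold_of, lambda = lambda_used)
  pearson <- pearson_bootstrap(preds$score, preds$icans, n_boot = n_boot,
                               seed = seed)
  auc <- dplyr::bind_rows(lapply(1:4, function(x) {
    ok <- any(preds$icans >= x) && any(preds$icans == 0)
    if (!ok) return(NULL)
    auc_by_level(preds$score, preds$icans, x, n_boot = n_boot, seed = seed + x)
  }))
  structure(list(predictions = preds, pearson = pearson, auc = auc,
                 spearman = spearman_features(records, vocab = vocab),
                 folds = folds,
                 fits = if (is.null(train_fn)) fits else NULL,
                 config = config),
            class = "veicans_eval")
}

#' @export
print.veicans_eval <- function(x, ...) {
  cat("<veicans_eval>\n")
  cat(sprintf("  %d out-of-sample predictions over %d folds\n",
              nrow(x$predictions), max(x$predictions$fold)))
  cat(sprintf("  Pearson r = %.2f [%.2f-%.2f]\n",
              x$pearson$r, x$pearson$conf_low, x$pearson$conf_high))
  for (i in seq_len(nrow(x$auc))) {
    cat(sprintf("  AUC (0 vs >= %d) = %.2f [%.2f-%.2f]\n", x$auc$level[i],
                x$auc$auc[i], x$auc$conf_low[i], x$auc$conf_high[i]))
  }
  invisible(x)
}

#' Spearman correlation matrix of EEG features
#'
#' Pairwise Spearman rank correlations between the binary feature indicators
#' across records (for binary variables this coincides with the phi
#' coefficient). Constant features yield undefined (NA) off-diagonal entries
#' and are listed in the `constant_features` attribute rather than being
#' silently zeroed; the diagonal is set to 1.
#'
#' @param records feature table.
#' @param vocab feature vocabulary.
#' @return symmetric numeric matrix with attribute `constant_features`.
#' @export
spearman_features <- function(records, vocab = eeg_vocabulary()) {
  feats <- intersect(vocab$feature, names(records))
  if (nrow(records) < 2) stop("need at least 2 records", call. = FALSE)
  m <- as.matrix(records[feats])
  const <- feats[apply(m, 2, function(v) length(unique(v)) == 1)]
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(rho) <- 1
  attr(rho, "constant_features") <- const
  rho
}

#' Continuity-corrected chi-square test on 2x2 contingency counts
#'
#' Tests association between a binary feature and a two-group split given
#' feature-present counts `a` (of `n1` in group 1) and `c` (of `n2` in group
#' 2). The Yates continuity term (|O - E| - 0.5 per cell, i.e.
#' |ad - bc| - N/2) is applied *without* flooring at zero, the convention
#' used by common scientific Python routines; with small effects the
#' corrected term can overshoot zero, which this convention retains.
#' Vectorized over rows.
#'
#' @param a,c feature-present counts in groups 1 and 2.
#' @param n1,n2 group sizes.
#' @param correct apply the continuity correction (default TRUE).
#' @return tibble with columns `statistic` (df = 1) and `p_value` (two-sided).
#' @examples
#' chi2_yates(2, 156, 14, 159)$p_value  # 0.0054
#' @export
chi2_yates <- function(a, n1, c, n2, correct = TRUE) {
  b <- n1 - a
  d <- n2 - c
  if (any(n1 <= 0 | n2 <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (any(a < 0 | c < 0 | b < 0 | d < 0)) {
    stop("counts must lie within their group sizes", call. = FALSE)
  }
  N <- n1 + n2
  if (any((a + c) == 0 | (b + d) == 0)) {
    stop("a zero expected count: feature absent (or universal) in both groups",
         call. = FALSE)
  }
  term <- abs(a * d - b * c) - if (correct) N / 2 else 0
  stat <- N * term^2 / (as.numeric(a + b) * (c + d) * (a + c) * (b + d))
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' @param x,y numeric samples (both non-empty).
#' @return tibble with `u` (the U statistic for `x`, ties counted half) and
#'   `p_value` (two-sided, normal approximation with tie-corrected variance).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(tibble::tibble(u = u, p_value = 1))
  }
  z <- (u - n * m / 2) / sqrt(sigma2)
  tibble::tibble(u = u, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Cohort contingency statistics (severe vs non-severe days)
#'
#' Dichotomizes patient-days at ICANS grade 2 (group 1: grade <= 2, group 2:
#' grade > 2; half-grades compare numerically) and tests each EEG feature's
#' prevalence difference with the continuity-corrected chi-square. Features
#' absent from both groups are reported with NA statistics.
#'
#' @param records graded feature table.
#' @param threshold dichotomization grade (default 2).
#' @param vocab feature vocabulary.
#' @return tibble `feature`, `a`, `n1`, `c`, `n2`, `statistic`, `p_value`.
#' @export
cohort_contingency <- function(records, threshold = 2, vocab = eeg_vocabulary()) {
  records <- validate_feature_table(records, require_icans = TRUE, vocab = vocab)
  feats <- intersect(c(vocab$feature, seizure_column), names(records))
  g2 <- records$icans > threshold
  n1 <- sum(!g2); n2 <- sum(g2)
  purrr::map_dfr(feats, function(f) {
    a <- sum(records[[f]][!g2]); cc <- sum(records[[f]][g2])
    res <- if ((a + cc) == 0 || (a + cc) == n1 + n2) {
      tibble::tibble(statistic = NA_real_, p_value = NA_real_)
    } else {
      chi2_yates(a, n1, cc, n2)
    }
    tibble::tibble(feature = f, a = a, n1 = n1, c = cc, n2 = n2,
                   statistic = res$statistic, p_value = res$p_value)
  })
}

#' Read a 2x2 contingency file
#'
#' Delimited text with columns `feature`, `a`, `n1`, `c`, `n2` (feature
#' present in `a` of `n1` group-1 days and `c` of `n2` group-2 days); extra
#' columns are carried through.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_contingency <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("feature", "a", "n1", "c", "n2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("contingency file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x
}
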