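#' Training configuration for the learning-to-rank model
#'
#' @param lambda ElasticNet penalty strength; a vector is treated as a grid
#'   and the value maximizing grouped cross-validated pairwise ranking
#'   accuracy is selected.
#' @param alpha L1/L2 mixing parameter in \[0, 1\] (1 = pure LASSO).
#' @param min_count minimum number of records a feature must appear in to be
#'   eligible for training.
#' @param search_radius box radius (in points) for the local search around the
#'   rounded integer solution.
#' @param target_max_points point value the largest real coefficient is scaled
#'   to before rounding.
#' @param maxit,tol optimizer iteration cap and convergence tolerance.
#' @param seed integer seed governing fold-assignment tie-breaking during
#'   penalty selection (the fit itself is deterministic).
#' @return A list of class `veicans_config`.
#' @export
train_config <- function(lambda = c(0.1, 0.03, 0.01, 0.003), alpha = 0.5,
                         min_count = 5, search_radius = 2,
                         target_max_points = 10, maxit = 5000, tol = 1e-8,
                         seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, all(lambda >= 0), min_count >= 0)
  structure(list(lambda = lambda, alpha = alpha, min_count = min_count,
                 search_radius = search_radius,
                 target_max_points = target_max_points,
                 maxit = maxit, tol = tol, seed = as.integer(seed)),
            class = "veicans_config")
}

#' Minimum-prevalence feature filter
#'
#' A feature is retained for training iff it appears in at least `min_count`
#' records, is not a severe pattern (severe patterns bypass training and are
#' assigned the maximal score a priori), and is not the seizure indicator
#' (excluded because seizures directly determine the clinical grade).
#'
#' @param records patient-day feature table (tibble with 0/1 feature columns).
#' @param min_count minimum presence count (default 5).
#' @param vocab feature vocabulary.
#' @return list with `retained` (character vector, canonical order) and
#'   `excluded` (tibble `feature`, `count`, `reason`).
#' @export
filter_features <- function(records, min_count = 5, vocab = eeg_vocabulary()) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  feats <- vocab$feature
  counts <- vapply(feats, function(f) {
    if (f %in% names(records)) sum(records[[f]]) else 0
  }, numeric(1))
  severe <- vocab$severe[match(feats, vocab$feature)]
  reason <- dplyr::case_when(
    severe ~ "severe a-priori",
    counts < min_count ~ sprintf("prevalence %d < %d", as.integer(counts), min_count),
    TRUE ~ NA_character_
  )
  excl <- tibble::tibble(feature = feats, count = as.integer(counts), reason = reason)
  if (seizure_column %in% names(records)) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      feature = seizure_column,
      count = as.integer(sum(records[[seizure_column]])),
      reason = "seizure indicator"))
  }
  list(retained = feats[is.na(reason)],
       excluded = excl[!is.na(excl$reason), ])
}

#' Expand graded records into ranked pairs
#'
#' Every unordered pair of records with strictly unequal ICANS grades becomes
#' one training pair, oriented with the higher-grade record first; pairs with
#' equal grades are ignored (half-grades are compared numerically, so 2 vs
#' 2.5 is an ordered pair). The pair count therefore equals
#' C(n,2) - sum_g C(n_g,2) over grade multiplicities n_g, which turns a few
#' hundred patient-days into tens of thousands of training pairs.
#'
#' @param records tibble with an `icans` column and 0/1 feature columns.
#' @param features feature columns to difference (default: all vocabulary
#'   columns present).
#' @param vocab feature vocabulary.
#' @return list of class `veicans_pairs`: `hi`, `lo` (record row indices),
#'   `diff` (matrix of feature differences, higher minus lower, entries in
#'   \{-1, 0, 1\}), `n_pairs`, `features`.
#' @export
make_pairs <- function(records, features = NULL, vocab = eeg_vocabulary()) {
  n <- nrow(records)
  if (n < 2) stop("need at least two records to form pairs", call. = FALSE)
  if (!"icans" %in% names(records)) stop("records must carry an icans column", call. = FALSE)
  features <- features %||% intersect(vocab$feature, names(records))
  g <- records$icans
  cmb <- utils::combn(n, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  keep <- g[i] != g[j]
  if (!any(keep)) {
    warning("all grades equal: no ranked pairs", call. = FALSE)
    return(structure(list(hi = integer(), lo = integer(),
                          diff = matrix(0, 0, length(features),
                                        dimnames = list(NULL, features)),
                          n_pairs = 0L, features = features),
                     class = "veicans_pairs"))
  }
  i <- i[keep]; j <- j[keep]
  hi <- ifelse(g[i] > g[j], i, j)
  lo <- ifelse(g[i] > g[j], j, i)
  X <- as.matrix(records[features])
  structure(list(hi = hi, lo = lo,
                 diff = X[hi, , drop = FALSE] - X[lo, , drop = FALSE],
                 n_pairs = length(hi), features = features),
            class = "veicans_pairs")
}

# Penalised logistic ranking objective on the constraint cone. Within the
# cone each coefficient's sign is fixed by its polarity, so the L1 term is
# linear and the whole objective is smooth there.
rank_objective <- function(w, diff, sgn, lambda, alpha) {
  z <- as.vector(diff %*% w)
  -mean(stats::plogis(z, log.p = TRUE)) +
    lambda * (alpha * sum(sgn * w) + (1 - alpha) / 2 * sum(w^2))
}

#' Fit the constrained ranking model
#'
#' Minimizes the average logistic ranking loss over pairs,
#' `mean(log(1 + exp(-w . dx)))`, plus an ElasticNet penalty
#' `lambda * (alpha * |w|_1 + (1 - alpha)/2 * |w|_2^2)`, subject to the sign
#' constraints (abnormal features >= 0, normal features <= 0) and the ordinal
#' constraints (within each slowing band, lower-frequency bins get
#' coefficients >= higher-frequency bins). There is no intercept: the model
#' acts on pair differences. On the feasible cone the L1 term is linear, so
#' the problem is smooth and is solved by accelerated projected gradient
#' descent with an exact Lipschitz step; the solver is deterministic.
#'
#' @param pairs a `veicans_pairs` object (or a bare difference matrix).
#' @param lambda,alpha penalty strength and L1/L2 mixing.
#' @param vocab feature vocabulary (supplies polarity and ordinal groups).
#' @param maxit,tol iteration cap and convergence tolerance on the maximum
#'   coefficient change.
#' @return list of class `veicans_ranker`: `w` (named coefficient vector),
#'   `loss`, `accuracy` (training pairwise accuracy, ties half),
#'   `iterations`, `converged`.
#' @export
fit_ranker <- function(pairs, lambda = 0.03, alpha = 0.5,
                       vocab = eeg_vocabulary(), maxit = 5000, tol = 1e-8) {
  diff <- if (inherits(pairs, "veicans_pairs")) pairs$diff else as.matrix(pairs)
  features <- colnames(diff)
  if (is.null(features)) stop("pair difference matrix must have feature names", call. = FALSE)
  N <- nrow(diff)
  if (!N) stop("no pairs to fit", call. = FALSE)
  p <- ncol(diff)
  meta <- constraint_meta(features, vocab)
  if (!p) {
    return(structure(list(w = stats::setNames(numeric(0), character(0)),
                          loss = log(2), accuracy = NA_real_,
                          iterations = 0L, converged = TRUE),
                     class = "veicans_ranker"))
  }
  L <- max(eigen(crossprod(diff), symmetric = TRUE, only.values = TRUE)$values) /
    (4 * N) + lambda * (1 - alpha)
  step <- 1 / max(L, .Machine$double.eps)
  w <- y <- numeric(p)
  tk <- 1
  it <- 0L
  delta <- Inf
  while (it < maxit) {
    it <- it + 1L
    z <- as.vector(diff %*% y)
    grad <- -as.vector(crossprod(diff, stats::plogis(-z))) / N +
      lambda * alpha * meta$sign + lambda * (1 - alpha) * y
    w_new <- project_cone(y - step * grad, meta)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- w_new + ((tk - 1) / t_new) * (w_new - w)
    delta <- max(abs(w_new - w))
    w <- w_new
    tk <- t_new
    if (delta < tol) break
  }
  converged <- delta < max(tol, 1e-6) * (1 + max(abs(w)))
  if (!converged) {
    stop(sprintf(paste0("ranking fit did not converge in %d iterations ",
                        "(last step %.3g, lambda = %g); increase maxit"),
                 maxit, delta, lambda), call. = FALSE)
  }
  margins <- as.vector(diff %*% w)
  structure(list(
    w = stats::setNames(w, features),
    loss = rank_objective(w, diff, meta$sign, lambda, alpha),
    accuracy = margin_accuracy(margins),
    iterations = it, converged = TRUE
  ), class = "veicans_ranker")
}

#' Convert real coefficients to admissible integer point values
#'
#' Scales the real coefficient vector so its largest magnitude equals
#' `target_max_points`, rounds (rounding a feasible vector preserves the sign
#' and ordinal constraints), then hill-climbs over +/-1 perturbations inside a
#' box of radius `search_radius` around the rounded solution, accepting only
#' moves that strictly increase pairwise ranking accuracy on the training
#' pairs; when the two directions improve equally, the tie breaks toward the
#' smaller point value. Feasible integer vectors are thus fixed points, and
#' the procedure is deterministic.
#'
#' @param w named real coefficient vector satisfying the constraints.
#' @param pairs `veicans_pairs` (training pairs) used to evaluate accuracy.
#' @param vocab feature vocabulary.
#' @param search_radius box radius for the local search.
#' @param target_max_points scaling target for the largest coefficient.
#' @return named integer vector over the same features.
#' @export
integerize <- function(w, pairs, vocab = eeg_vocabulary(), search_radius = 2,
                       target_max_points = 10) {
  diff <- if (inherits(pairs, "veicans_pairs")) pairs$diff else as.matrix(pairs)
  features <- names(w)
  stopifnot(identical(colnames(diff), features))
  meta <- constraint_meta(features, vocab)
  if (!length(w) || max(abs(w)) == 0) {
    return(stats::setNames(integer(length(w)), features))
  }
  wi <- round(w * target_max_points / max(abs(w)))
  # safety repair (rounding should already be feasible)
  wi <- round(project_cone(wi, meta))
  base <- wi
  margins <- as.vector(diff %*% wi)
  acc <- margin_accuracy(margins)
  feasible_value <- function(j, cand) {
    if (abs(cand - base[j]) > search_radius) return(FALSE)
    if (meta$sign[j] > 0 && cand < 0) return(FALSE)
    if (meta$sign[j] < 0 && cand > 0) return(FALSE)
    for (idx in meta$chains) {
      k <- match(j, idx)
      if (is.na(k)) next
      if (k > 1 && cand > wi[idx[k - 1]]) return(FALSE)
      if (k < length(idx) && cand < wi[idx[k + 1]]) return(FALSE)
    }
    TRUE
  }
  for (pass in seq_len(50)) {
    improved <- FALSE
    for (j in seq_along(wi)) {
      best <- NULL
      for (d in c(1, -1)) {
        cand <- wi[j] + d
        if (!feasible_value(j, cand)) next
        acc2 <- margin_accuracy(margins + d * diff[, j])
        # strict improvement only; among equally good moves prefer the
        # smaller point value, so feasible integer vectors are fixed points
        if (acc2 > acc &&
            (is.null(best) || acc2 > best$acc ||
             (acc2 == best$acc && abs(cand) < abs(best$cand)))) {
          best <- list(cand = cand, d = d, acc = acc2)
        }
      }
      if (!is.null(best)) {
        margins <- margins + best$d * diff[, j]
        wi[j] <- best$cand
        acc <- best$acc
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  stats::setNames(as.integer(wi), features)
}

#' Train a VE-ICANS-style scoring table from graded patient-days
#'
#' End-to-end derivation of an integer scoring table: minimum-prevalence
#' feature filtering, expansion of graded records into ranked pairs (records
#' exhibiting a severe pattern are excluded from pair construction since
#' their score is assigned a priori), constrained ElasticNet logistic ranking
#' fit (with the penalty strength selected by grouped cross-validation when
#' `config$lambda` is a grid), integerization, and assembly into a
#' [scoring_table()] with the severe set attached and the maximal score
#' computed from the result. Reproducible given `config$seed`.
#'
#' @param records patient-day feature table with `subject_id`, `day`, 0/1
#'   feature columns and `icans` grades.
#' @param config a [train_config()].
#' @param vocab feature vocabulary.
#' @return An object of class `veicans_fit`: list with `table` (the trained
#'   `veicans_table`), `w_real`, `w_int`, `retained`, `excluded`, `lambda`
#'   (selected value), `lambda_cv` (selection table or `NULL`), `config`, and
#'   `diagnostics` (one-row tibble: records, pairs, training accuracy of real
#'   and integer coefficients, loss).
#' @examples
#' \donttest{
#' cohort <- sample_cohort(cohort_spec(n_subjects = 40), seed = 7)
#' fit <- train_veicans(cohort$records, train_config(lambda = 0.01))
#' fit$table
#' }
#' @export
train_veicans <- function(records, config = train_config(), vocab = eeg_vocabulary()) {
  records <- validate_feature_table(records, require_icans = TRUE, vocab = vocab)
  flt <- filter_features(records, config$min_count, vocab)
  sev_cols <- intersect(severe_features(), names(records))
  is_severe <- if (length(sev_cols)) rowSums(records[sev_cols]) > 0 else
    rep(FALSE, nrow(records))
  train_rec <- records[!is_severe, , drop = FALSE]
  if (nrow(train_rec) < 2 || length(unique(train_rec$icans)) < 2) {
    stop("no informative pairs: need non-severe records at >= 2 distinct grades",
         call. = FALSE)
  }
  lambda <- config$lambda
  lambda_cv <- NULL
  if (length(lambda) > 1) {
    sel <- select_lambda(train_rec, flt$retained, config, vocab)
    lambda <- sel$best
    lambda_cv <- sel$table
  }
  pairs <- make_pairs(train_rec, features = flt$retained, vocab = vocab)
  if (!pairs$n_pairs) stop("no informative pairs", call. = FALSE)
  ranker <- fit_ranker(pairs, lambda = lambda, alpha = config$alpha,
                       vocab = vocab, maxit = config$maxit, tol = config$tol)
  w_int <- integerize(ranker$w, pairs, vocab = vocab,
                      search_radius = config$search_radius,
                      target_max_points = config$target_max_points)
  table <- scoring_table(w_int, severe = severe_features(), max_score = "auto",
                         note = sprintf("trained table (lambda = %g, alpha = %g)",
                                        lambda, config$alpha),
                         vocab = vocab)
  structure(list(
    table = table,
    w_real = ranker$w,
    w_int = w_int,
    retained = flt$retained,
    excluded = flt$excluded,
    lambda = lambda,
    lambda_cv = lambda_cv,
    config = config,
    diagnostics = tibble::tibble(
      n_records = nrow(train_rec), n_severe_excluded = sum(is_severe),
      n_pairs = pairs$n_pairs,
      accuracy_real = ranker$accuracy,
      accuracy_int = margin_accuracy(as.vector(pairs$diff %*% w_int)),
      loss = ranker$loss, iterations = ranker$iterations)
  ), class = "veicans_fit")
}

# Grouped CV over the lambda grid: real-valued fits on each training split,
# pairwise accuracy on the held-out split's pairs; ties prefer the stronger
# penalty.
select_lambda <- function(records, features, config, vocab = eeg_vocabulary()) {
  k <- min(5L, length(unique(records$subject_id)))
  if (k < 2) {
    return(list(best = max(config$lambda), table = NULL))
  }
  folds <- assign_folds(records, k = k, seed = config$seed)
  fold_of <- folds$records$fold
  acc <- matrix(NA_real_, nrow = k, ncol = length(config$lambda))
  for (f in seq_len(k)) {
    tr <- records[fold_of != f, , drop = FALSE]
    te <- records[fold_of == f, , drop = FALSE]
    if (length(unique(tr$icans)) < 2 || nrow(te) < 2 ||
        length(unique(te$icans)) < 2) next
    p_tr <- make_pairs(tr, features = features, vocab = vocab)
    p_te <- make_pairs(te, features = features, vocab = vocab)
    if (!p_tr$n_pairs || !p_te$n_pairs) next
    for (li in seq_along(config$lambda)) {
      fit <- fit_ranker(p_tr, lambda = config$lambda[li], alpha = config$alpha,
                        vocab = vocab, maxit = config$maxit, tol = config$tol)
      acc[f, li] <- margin_accuracy(as.vector(p_te$diff %*% fit$w))
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  if (all(!is.finite(mean_acc))) {
    return(list(best = max(config$lambda), table = NULL))
  }
  best_idx <- which(mean_acc == max(mean_acc, na.rm = TRUE))
  best <- max(config$lambda[best_idx])
  list(best = best,
       table = tibble::tibble(lambda = config$lambda, cv_accuracy = mean_acc))
}

#' @export
print.veicans_fit <- function(x, ...) {
  cat("<veicans_fit>\n")
  d <- x$diagnostics
  cat(sprintf("  %d records (%d severe excluded), %d pairs, lambda = %g\n",
              d$n_records, d$n_severe_excluded, d$n_pairs, x$lambda))
  cat(sprintf("  training pairwise accuracy: %.3f (real), %.3f (integer)\n",
              d$accuracy_real, d$accuracy_int))
  print(x$table)
  invisible(x)
}
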