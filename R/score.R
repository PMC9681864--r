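#' Score a single feature set
#'
#' Computes the VE-ICANS score for one patient-day given the set of EEG
#' features present. If any severe pattern is present the maximal score is
#' assigned (override); otherwise the score is the sum of the point values of
#' the present features.
#'
#' @param present character vector of feature ids present (may be empty), or a
#'   named logical/0-1 vector over the vocabulary.
#' @param table scoring table, default the published one.
#' @param vocab feature vocabulary.
#' @return A list of class `veicans_score` with elements `score` (integer),
#'   `severe_override` (logical), and `contributions` (tibble `feature`,
#'   `points` for the present scoring features, or the severe features if the
#'   override fired).
#' @examples
#' score_one(c("delta_1_2", "gpds", "theta_4_5"))$score  # 6 + 2 + 2 = 10
#' score_one(character())$score                          # 0
#' @export
score_one <- function(present, table = default_table(), vocab = eeg_vocabulary()) {
  if (is.logical(present) || is.numeric(present)) {
    present <- names(present)[as.logical(present)]
  }
  unknown <- setdiff(present, vocab$feature)
  if (length(unknown)) {
    stop("feature id(s) not in vocabulary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sev <- intersect(present, table$severe)
  if (length(sev)) {
    return(structure(list(
      score = table$max_score, severe_override = TRUE,
      contributions = tibble::tibble(feature = sev, points = NA_real_)
    ), class = "veicans_score"))
  }
  scored <- intersect(present, names(table$coefficients))
  pts <- table$coefficients[scored]
  structure(list(
    score = sum(pts), severe_override = FALSE,
    contributions = tibble::tibble(feature = scored, points = unname(pts))
  ), class = "veicans_score")
}

#' @export
print.veicans_score <- function(x, ...) {
  cat(sprintf("VE-ICANS score: %g%s\n", x$score,
              if (x$severe_override) " (severe pattern: maximal score)" else ""))
  if (!x$severe_override && nrow(x$contributions)) {
    for (i in seq_len(nrow(x$contributions))) {
      cat(sprintf("  %-22s %+d\n", x$contributions$feature[i],
                  as.integer(x$contributions$points[i])))
    }
  }
  invisible(x)
}

#' Score a table of patient-days
#'
#' Applies the scoring table to every row of a patient-day feature table
#' (columns of 0/1 indicators named after the vocabulary; extra columns such
#' as `subject_id`, `day`, `icans` and `seizure` are carried through
#' unchanged; `seizure` is never scored).
#'
#' @param data data frame with one row per patient-day.
#' @param table scoring table.
#' @param vocab feature vocabulary.
#' @return `data` as a tibble with columns `ve_icans` (numeric score) and
#'   `severe_override` (logical) appended.
#' @examples
#' df <- tibble::tibble(subject_id = "s1", day = 1, delta_le1 = 1, gpds = 0)
#' score_features(df)$ve_icans  # 10
#' @export
score_features <- function(data, table = default_table(), vocab = eeg_vocabulary()) {
  data <- tibble::as_tibble(data)
  feats <- intersect(names(data), vocab$feature)
  if (!length(feats)) stop("no vocabulary feature columns found", call. = FALSE)
  m <- as.matrix(data[feats])
  if (!all(m %in% c(0, 1))) {
    stop("feature indicator columns must be 0/1", call. = FALSE)
  }
  sev <- intersect(feats, table$severe)
  override <- if (length(sev)) rowSums(m[, sev, drop = FALSE]) > 0 else rep(FALSE, nrow(m))
  scored <- intersect(feats, names(table$coefficients))
  base <- as.numeric(m[, scored, drop = FALSE] %*% table$coefficients[scored])
  data$ve_icans <- ifelse(override, table$max_score, base)
  data$severe_override <- override
  data
}
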