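#' Read, validate and write patient-day feature tables
#'
#' The delimited interchange format is comma-separated UTF-8 text with a
#' mandatory header: `subject_id`, `day`, one 0/1 column per vocabulary
#' feature (a subset is allowed; missing features are treated as absent when
#' scoring), an optional 0/1 `seizure` column, and an optional `icans` column
#' with the clinical grade (0--4 in half steps; required for training and
#' evaluation, optional for scoring-only use).
#'
#' `validate_feature_table()` enforces the schema: recognised column names,
#' 0/1 indicators, at most one frequency bin set per slowing band on any row,
#' one row per subject-day, and grades in \{0, 0.5, ..., 4\}.
#'
#' @param path file path.
#' @param data data frame of patient-day records.
#' @param require_icans logical; demand the `icans` column (training and
#'   evaluation need grades).
#' @param vocab feature vocabulary.
#' @return `read_feature_table()` returns a validated tibble;
#'   `validate_feature_table()` returns its input invisibly or stops with a
#'   message naming the offending column/row; `write_feature_table()` returns
#'   `path` invisibly.
#' @export
read_feature_table <- function(path, require_icans = FALSE, vocab = eeg_vocabulary()) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_table(data, require_icans = require_icans, vocab = vocab)
  data
}

#' @rdname read_feature_table
#' @export
validate_feature_table <- function(data, require_icans = FALSE,
                                   vocab = eeg_vocabulary()) {
  data <- tibble::as_tibble(data)
  allowed <- c("subject_id", "day", vocab$feature, seizure_column, "icans",
               "ve_icans", "severe_override")
  unknown <- setdiff(names(data), allowed)
  if (length(unknown)) {
    stop("unrecognised column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in c("subject_id", "day")) {
    if (!col %in% names(data)) stop("missing required column: ", col, call. = FALSE)
  }
  if (require_icans && !"icans" %in% names(data)) {
    stop("missing required column: icans", call. = FALSE)
  }
  feats <- intersect(names(data), c(vocab$feature, seizure_column))
  if (!length(feats)) stop("no feature indicator columns present", call. = FALSE)
  for (col in feats) {
    v <- data[[col]]
    if (!all(v %in% c(0, 1))) {
      stop("column '", col, "' must contain only 0/1 (row ",
           which(!v %in% c(0, 1))[1], ")", call. = FALSE)
    }
  }
  for (band in names(ordinal_groups(vocab))) {
    bins <- intersect(ordinal_groups(vocab)[[band]], names(data))
    if (length(bins) > 1) {
      k <- rowSums(data[bins])
      if (any(k > 1)) {
        stop("row ", which(k > 1)[1], " sets more than one ", band,
             " frequency bin", call. = FALSE)
      }
    }
  }
  if ("icans" %in% names(data)) {
    ok <- is.na(data$icans) | data$icans %in% seq(0, 4, by = 0.5)
    if (!all(ok)) {
      stop("icans grades must lie in {0, 0.5, ..., 4} (row ", which(!ok)[1], ")",
           call. = FALSE)
    }
  }
  key <- paste(data$subject_id, data$day)
  if (anyDuplicated(key)) {
    stop("duplicate subject-day record: ", key[duplicated(key)][1], call. = FALSE)
  }
  invisible(data)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}
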