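#' Construct a scoring table
#'
#' A scoring table maps each (non-severe) EEG feature to an integer point
#' value; severe features carry no coefficient and instead trigger the
#' maximal score. A day's score is the sum of the points of the features
#' present, or the maximal score if any severe pattern is present.
#'
#' @param coefficients named numeric vector or list, feature id -> integer
#'   coefficient. Features omitted default to 0.
#' @param severe character vector of severe feature ids (maximal-score
#'   override). Defaults to the canonical severe set.
#' @param max_score integer maximal score, or `"auto"` (the default) to use
#'   the largest score achievable without severe features under the
#'   one-bin-per-band rule.
#' @param note free-text provenance note.
#' @param vocab feature vocabulary tibble, see [eeg_vocabulary()].
#' @return An object of class `veicans_table`: a list with elements
#'   `coefficients` (named integer vector over the full non-severe
#'   vocabulary), `severe`, `max_score`, `note`, `vocabulary_version`.
#' @seealso [default_table()], [validate_table()], [score_features()]
#' @export
scoring_table <- function(coefficients, severe = severe_features(),
                          max_score = "auto", note = "",
                          vocab = eeg_vocabulary()) {
  check_vocabulary(vocab)
  coefficients <- unlist(coefficients)
  unknown <- setdiff(names(coefficients), vocab$feature)
  if (length(unknown)) {
    stop("unknown feature id(s) in coefficients: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(severe, vocab$feature)
  if (length(unknown)) {
    stop("unknown feature id(s) in severe set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(names(coefficients) %in% severe)) {
    stop("severe features carry no coefficient", call. = FALSE)
  }
  scored <- setdiff(vocab$feature, severe)
  coef_full <- stats::setNames(numeric(length(scored)), scored)
  coef_full[names(coefficients)] <- coefficients
  tab <- structure(
    list(
      coefficients = coef_full,
      severe = severe,
      max_score = NA_real_,
      note = note,
      vocabulary_version = "table2-1hz-bins-v1"
    ),
    class = "veicans_table"
  )
  tab$max_score <- if (identical(max_score, "auto")) {
    max_achievable_score(tab, vocab)
  } else {
    as.numeric(max_score)
  }
  tab
}

#' The published VE-ICANS scoring table
#'
#' Point values: delta slowing <= 1 Hz +10, 1--2 Hz +6, 2--3 Hz +5,
#' 3--4 Hz +3; moderately low voltage +2; GRDA +2; GPDs +2; theta 4--5 Hz +2;
#' theta 5--8 Hz +1 (the 5--6 and 6--8 Hz input bins were merged after
#' training because their coefficients agreed); alpha >= 9 Hz -1; PDR -1.
#' Features dropped by regularization (slow alpha bins, beta, awake signs,
#' LPDs, LRDA, intermittent brief attenuation) score 0. NCSE, extreme low
#' voltage / ECS, burst suppression and an unreactive EEG trigger the maximal
#' score.
#'
#' @return A `veicans_table`, see [scoring_table()].
#' @examples
#' tab <- default_table()
#' tab$coefficients[["delta_le1"]]  # 10
#' tab$coefficients[["pdr"]]        # -1
#' @export
default_table <- function() {
  scoring_table(
    c(delta_le1 = 10, delta_1_2 = 6, delta_2_3 = 5, delta_3_4 = 3,
      low_voltage_moderate = 2, grda = 2, gpds = 2,
      theta_4_5 = 2, theta_5_6 = 1, theta_6_8 = 1,
      alpha_ge9 = -1, pdr = -1),
    note = "Published VE-ICANS grading system"
  )
}

#' Largest achievable non-severe score
#'
#' Computes the maximum of the additive score over feature vectors that obey
#' the one-frequency-bin-per-band rule and contain no severe pattern: the
#' best single bin per slowing band plus every positive non-band coefficient.
#' Used as the default maximal score assigned to severe patterns, so that a
#' severe EEG always ranks at least as high as any non-severe EEG.
#'
#' @param table a `veicans_table`
#' @param vocab feature vocabulary
#' @return integer scalar
#' @export
max_achievable_score <- function(table, vocab = eeg_vocabulary()) {
  coefs <- table$coefficients
  groups <- ordinal_groups(vocab)
  grouped <- unlist(groups, use.names = FALSE)
  band_part <- sum(vapply(groups, function(g) {
    max(0, coefs[intersect(g, names(coefs))])
  }, numeric(1)))
  single <- setdiff(names(coefs), grouped)
  band_part + sum(pmax(0, coefs[single]))
}

#' Check a scoring table against the admissibility constraints
#'
#' The constraints mirror those imposed during training: coefficients must be
#' integers; abnormal features must have coefficient >= 0 and normal features
#' <= 0; within each slowing band, the coefficient of a lower-frequency (more
#' severe) bin must be >= that of any higher-frequency bin; severe features
#' must not carry a coefficient.
#'
#' @param table a `veicans_table`
#' @param vocab feature vocabulary
#' @return A tibble of violations with columns `constraint`, `feature`,
#'   `detail`; zero rows iff the table is admissible.
#' @examples
#' nrow(validate_table(default_table()))  # 0
#' @export
validate_table <- function(table, vocab = eeg_vocabulary()) {
  check_vocabulary(vocab)
  coefs <- table$coefficients
  out <- list()
  bad <- names(coefs)[coefs != round(coefs)]
  for (f in bad) {
    out[[length(out) + 1L]] <- tibble::tibble(
      constraint = "integer", feature = f,
      detail = sprintf("coefficient %g is not an integer", coefs[[f]]))
  }
  pol <- stats::setNames(vocab$polarity, vocab$feature)
  for (f in names(coefs)) {
    if (pol[[f]] == "abnormal" && coefs[[f]] < 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        constraint = "sign", feature = f,
        detail = sprintf("abnormal feature has negative coefficient %g", coefs[[f]]))
    }
    if (pol[[f]] == "normal" && coefs[[f]] > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        constraint = "sign", feature = f,
        detail = sprintf("normal feature has positive coefficient %g", coefs[[f]]))
    }
  }
  for (band in names(ordinal_groups(vocab))) {
    g <- intersect(ordinal_groups(vocab)[[band]], names(coefs))
    cg <- coefs[g]
    if (any(diff(cg) > 0)) {
      i <- which(diff(cg) > 0)[1]
      out[[length(out) + 1L]] <- tibble::tibble(
        constraint = "ordinal", feature = g[i + 1],
        detail = sprintf("%s (%g) exceeds lower-frequency bin %s (%g)",
                         g[i + 1], cg[i + 1], g[i], cg[i]))
    }
  }
  sev_with_coef <- intersect(table$severe, names(coefs))
  for (f in sev_with_coef) {
    out[[length(out) + 1L]] <- tibble::tibble(
      constraint = "severe", feature = f,
      detail = "severe feature carries a coefficient")
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(constraint = character(), feature = character(), detail = character())
}

#' @export
print.veicans_table <- function(x, ...) {
  cat("<veicans_table>", if (nzchar(x$note)) paste0(" ", x$note), "\n", sep = "")
  nz <- x$coefficients[x$coefficients != 0]
  nz <- nz[order(-nz)]
  for (f in names(nz)) cat(sprintf("  %-22s %+d\n", f, as.integer(nz[[f]])))
  cat(sprintf("  severe (score %g): %s\n", x$max_score,
              paste(x$severe, collapse = ", ")))
  invisible(x)
}

#' Read or write a scoring table as JSON
#'
#' The on-disk format has fields `features` (id -> integer coefficient),
#' `severe` (list of ids), `max_score` (integer or `"auto"`),
#' `vocabulary_version`, and `note`. Round-trips exactly.
#'
#' @param path file path
#' @param table a `veicans_table`
#' @return `read_scoring_table()` returns a `veicans_table`;
#'   `write_scoring_table()` returns `path` invisibly.
#' @export
read_scoring_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- scoring_table(
    coefficients = unlist(x$features),
    severe = x$severe,
    max_score = if (identical(x$max_score, "auto")) "auto" else as.numeric(x$max_score),
    note = if (is.null(x$note)) "" else x$note
  )
  if (!is.null(x$vocabulary_version) &&
      !identical(x$vocabulary_version, tab$vocabulary_version)) {
    stop("scoring table vocabulary_version '", x$vocabulary_version,
         "' does not match this package ('", tab$vocabulary_version, "')",
         call. = FALSE)
  }
  tab
}

#' @rdname read_scoring_table
#' @export
write_scoring_table <- function(table, path) {
  jsonlite::write_json(
    list(
      features = as.list(table$coefficients[table$coefficients != 0]),
      severe = table$severe,
      max_score = table$max_score,
      vocabulary_version = table$vocabulary_version,
      note = table$note
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
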