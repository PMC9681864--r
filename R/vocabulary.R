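#' Canonical EEG feature vocabulary
#'
#' The qualitative EEG features used by the VE-ICANS grading system, as a
#' tibble with one row per binary feature. Background slowing is subdivided
#' into 1 Hz frequency bins within each band (delta <= 1, 1--2, 2--3, 3--4 Hz;
#' theta 4--5, 5--6, 6--8 Hz; alpha <= 8, 8--9, >= 9 Hz), so each band forms
#' an ordered ("ordinal") group in which lower frequency means more severe
#' encephalopathy. Four rare patterns (NCSE, extreme low voltage /
#' electrocerebral silence, burst suppression, unreactive EEG) indicate severe
#' encephalopathy and are flagged `severe`: a day exhibiting any of them is
#' assigned the maximal score a priori rather than a learned coefficient.
#'
#' @return A tibble with columns:
#'   \describe{
#'     \item{feature}{unique identifier, used as column name in feature tables}
#'     \item{label}{human-readable description}
#'     \item{band}{`"delta"`, `"theta"`, `"alpha"` or `"other"`}
#'     \item{lo_hz, hi_hz}{frequency bin bounds in Hz (`NA` for non-slowing
#'       features; `Inf`/0 for open-ended bins)}
#'     \item{polarity}{`"abnormal"` (expected to raise the score) or
#'       `"normal"` (expected to lower it)}
#'     \item{severe}{logical; triggers the maximal-score override}
#'     \item{group}{ordinal group key (the band) for slowing bins, else `NA`}
#'     \item{group_order}{rank within the ordinal group by increasing lower
#'       frequency bound, else `NA`}
#'   }
#' @examples
#' eeg_vocabulary()
#' @export
eeg_vocabulary <- function() {
  vocab <- tibble::tribble(
    ~feature,               ~label,                                          ~band,   ~lo_hz, ~hi_hz, ~polarity,  ~severe,
    "delta_le1",            "Delta frequency 1 Hz or less",                  "delta",      0,      1, "abnormal", FALSE,
    "delta_1_2",            "Delta frequency 1-2 Hz",                        "delta",      1,      2, "abnormal", FALSE,
    "delta_2_3",            "Delta frequency 2-3 Hz",                        "delta",      2,      3, "abnormal", FALSE,
    "delta_3_4",            "Delta frequency 3-4 Hz",                        "delta",      3,      4, "abnormal", FALSE,
    "theta_4_5",            "Theta frequency 4-5 Hz",                        "theta",      4,      5, "abnormal", FALSE,
    "theta_5_6",            "Theta frequency 5-6 Hz",                        "theta",      5,      6, "abnormal", FALSE,
    "theta_6_8",            "Theta frequency 6-8 Hz",                        "theta",      6,      8, "abnormal", FALSE,
    "alpha_le8",            "Alpha frequency 8 Hz or less",                  "alpha",      0,      8, "abnormal", FALSE,
    "alpha_8_9",            "Alpha frequency 8-9 Hz",                        "alpha",      8,      9, "abnormal", FALSE,
    "alpha_ge9",            "Alpha frequency greater than 9 Hz",             "alpha",      9,    Inf, "normal",   FALSE,
    "beta",                 "Beta oscillations present",                     "other",     NA,     NA, "normal",   FALSE,
    "pdr",                  "Posterior dominant rhythm (PDR) present",       "other",     NA,     NA, "normal",   FALSE,
    "awake_signs",          "Signs of being awake",                          "other",     NA,     NA, "normal",   FALSE,
    "grda",                 "Generalized rhythmic delta activity (GRDA)",    "other",     NA,     NA, "abnormal", FALSE,
    "gpds",                 "Generalized periodic discharges (GPDs)",        "other",     NA,     NA, "abnormal", FALSE,
    "lpds",                 "Lateralized periodic discharges (LPDs)",        "other",     NA,     NA, "abnormal", FALSE,
    "lrda",                 "Lateralized rhythmic delta activity (LRDA)",    "other",     NA,     NA, "abnormal", FALSE,
    "low_voltage_moderate", "Moderately low voltage (< 20 uV)",              "other",     NA,     NA, "abnormal", FALSE,
    "attenuation_brief",    "Intermittent brief attenuation",                "other",     NA,     NA, "abnormal", FALSE,
    "ncse",                 "Nonconvulsive status epilepticus (NCSE)",       "other",     NA,     NA, "abnormal", TRUE,
    "low_voltage_extreme",  "Extreme low voltage / electrocerebral silence", "other",     NA,     NA, "abnormal", TRUE,
    "burst_suppression",    "Burst suppression",                             "other",     NA,     NA, "abnormal", TRUE,
    "unreactive_eeg",       "Unreactive EEG",                                "other",     NA,     NA, "abnormal", TRUE
  )
  vocab$group <- ifelse(vocab$band %in% c("delta", "theta", "alpha"), vocab$band, NA_character_)
  vocab <- dplyr::group_by(vocab, .data$group)
  vocab <- dplyr::mutate(
    vocab,
    group_order = ifelse(is.na(.data$group), NA_integer_, rank(.data$lo_hz))
  )
  dplyr::ungroup(vocab)
}

#' @rdname eeg_vocabulary
#' @format NULL
#' @details `feature_names()` returns just the identifiers, in canonical
#'   order; `severe_features()` the identifiers of the severe patterns.
#' @export
feature_names <- function() eeg_vocabulary()$feature

#' @rdname eeg_vocabulary
#' @export
severe_features <- function() {
  v <- eeg_vocabulary()
  v$feature[v$severe]
}

# Seizure activity is recorded in feature tables for completeness but is never
# scored or trained on: clinically it forces ICANS >= 3 directly, so it is
# excluded to avoid target leakage.
seizure_column <- "seizure"

ordinal_groups <- function(vocab = eeg_vocabulary()) {
  v <- vocab[!is.na(vocab$group), ]
  split(v$feature[order(v$group, v$group_order)], v$group[order(v$group, v$group_order)])
}

check_vocabulary <- function(vocab) {
  stopifnot(is.data.frame(vocab))
  if (anyDuplicated(vocab$feature) > 0) {
    stop("vocabulary feature identifiers must be unique", call. = FALSE)
  }
  if (any(vocab$severe & vocab$polarity != "abnormal")) {
    stop("severe features must have polarity 'abnormal'", call. = FALSE)
  }
  for (g in ordinal_groups(vocab)) {
    lo <- vocab$lo_hz[match(g, vocab$feature)]
    hi <- vocab$hi_hz[match(g, vocab$feature)]
    if (any(diff(lo) <= 0) || any(lo[-1] < hi[-length(hi)])) {
      stop("ordinal group bins must be non-overlapping and ordered", call. = FALSE)
    }
  }
  invisible(vocab)
}
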