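#' ICE score components and total
#'
#' The Immune Effector Cell-Associated Encephalopathy (ICE) score is a 0--10
#' bedside cognitive assessment: naming of 3 objects (0--3 points),
#' orientation to year/month/city/hospital (0--4), following commands (0--1),
#' attention (0--1), and writing a sentence (0--1); 10 reflects a normal
#' exam. When chart review rather than a bedside exam is the source, accepted
#' substitutions (months/days of the week or WORLD backward for attention;
#' state/president/senator or "fully alert and oriented" for orientation;
#' fluent speech without paraphasic errors for naming; absence of aphasia and
#' tremor for the writing point) are applied upstream when the chart findings
#' are mapped to components; the free-text `note` field records them.
#'
#' @param naming,orientation,command,attention,writing integer component
#'   points within their ranges (3, 4, 1, 1, 1 maxima).
#' @param note optional character note recording substitutions used.
#' @return `ice_assessment()` returns a list of class `ice_assessment`;
#'   `ice_total()` returns the integer component sum in 0--10.
#' @examples
#' ice_total(ice_assessment(3, 4, 1, 1, 1))  # 10, a normal exam
#' ice_total(ice_assessment(3, 4, 1, 0, 1))  # 9
#' @export
ice_assessment <- function(naming, orientation, command, attention, writing,
                           note = "") {
  comp <- c(naming = naming, orientation = orientation, command = command,
            attention = attention, writing = writing)
  maxima <- c(naming = 3, orientation = 4, command = 1, attention = 1, writing = 1)
  for (k in names(comp)) {
    v <- comp[[k]]
    if (is.na(v) || v < 0 || v > maxima[[k]] || v != round(v)) {
      stop("ICE component '", k, "' must be an integer in [0, ", maxima[[k]], "]",
           call. = FALSE)
    }
  }
  structure(list(components = comp, note = note), class = "ice_assessment")
}

#' @rdname ice_assessment
#' @param a an `ice_assessment`
#' @export
ice_total <- function(a) {
  stopifnot(inherits(a, "ice_assessment"))
  sum(a$components)
}

#' Default ICE-band to ICANS-grade mapping
#'
#' The consensus encephalopathy bands: ICE 10 contributes grade 0, ICE 7--9
#' grade 1, ICE 3--6 grade 2, ICE 0--2 grade 3. Grade 4 is reached through
#' the level-of-consciousness domain (unarousable patient, unable to perform
#' ICE), not through the ICE band itself. This mapping is external consensus
#' knowledge shipped as editable configuration, not a quantity estimated in
#' this package.
#'
#' @return tibble with columns `ice_min`, `ice_max`, `grade`.
#' @export
astct_ice_bands <- function() {
  tibble::tibble(
    ice_min = c(10, 7, 3, 0),
    ice_max = c(10, 9, 6, 2),
    grade   = c(0, 1, 2, 3)
  )
}

#' ICANS grade from ICE total and neurological domains
#'
#' The overall ICANS grade (0--4, 4 most severe) is the worst (maximum) of
#' the encephalopathy grade implied by the ICE total and the grades of the
#' four other neurological domains: depressed level of consciousness, motor
#' symptoms, seizures, and signs of cerebral edema.
#'
#' @param ice integer ICE total in 0--10.
#' @param loc,motor,seizure,edema per-domain ordinal contributions, each in
#'   0--4.
#' @param bands ICE-band configuration, see [astct_ice_bands()].
#' @return numeric grade in 0--4.
#' @examples
#' icans_grade(10)               # 0: normal exam, no domain findings
#' icans_grade(10, seizure = 3)  # 3: a seizure forces grade >= 3
#' icans_grade(0, loc = 4)       # 4: unarousable
#' @export
icans_grade <- function(ice, loc = 0, motor = 0, seizure = 0, edema = 0,
                        bands = astct_ice_bands()) {
  if (is.null(bands) || !all(c("ice_min", "ice_max", "grade") %in% names(bands))) {
    stop("ICE band configuration missing or malformed", call. = FALSE)
  }
  if (any(ice < 0 | ice > 10)) stop("ice must lie in [0, 10]", call. = FALSE)
  domains <- cbind(loc, motor, seizure, edema)
  if (any(!domains %in% 0:4)) stop("domain grades must lie in {0,...,4}", call. = FALSE)
  band_grade <- vapply(ice, function(i) {
    hit <- bands$grade[bands$ice_min <= i & i <= bands$ice_max]
    if (!length(hit)) stop("no ICE band covers total ", i, call. = FALSE)
    max(hit)
  }, numeric(1))
  pmax(band_grade, apply(domains, 1, max))
}

#' Reconcile grades from multiple reviewers
#'
#' Identical grades pass through; discrepant grades are averaged (the
#' arithmetic mean), which with two reviewers yields half-grades such as 2.5.
#'
#' @param grades numeric vector of per-reviewer ICANS grades (length >= 1).
#' @return list with `value` (the reconciled grade) and `source`
#'   (`"single"` if all reviewers agreed or only one reviewed,
#'   `"reconciled"` if averaging occurred).
#' @examples
#' reconcile_grades(c(2, 3))$value  # 2.5
#' @export
reconcile_grades <- function(grades) {
  if (!length(grades)) stop("at least one reviewer grade required", call. = FALSE)
  if (any(is.na(grades))) stop("grades must not be NA", call. = FALSE)
  if (length(unique(grades)) == 1) {
    list(value = grades[1], source = "single")
  } else {
    list(value = mean(grades), source = "reconciled")
  }
}

#' Grade exam-findings records and reconcile reviewers
#'
#' `grade_exams()` takes one row per patient-day-reviewer with ICE component
#' columns (`naming`, `orientation`, `command`, `attention`, `writing`) and
#' domain columns (`loc`, `motor`, `seizure_domain`, `edema`; absent domain
#' columns default to 0) and appends `ice_total` and `icans`.
#' `reconcile_reviews()` collapses to one row per subject-day with the
#' reconciled grade.
#'
#' @param data data frame of exam findings.
#' @param bands ICE-band configuration.
#' @return A tibble; see Details.
#' @export
grade_exams <- function(data, bands = astct_ice_bands()) {
  data <- tibble::as_tibble(data)
  comp <- c("naming", "orientation", "command", "attention", "writing")
  miss <- setdiff(comp, names(data))
  if (length(miss)) stop("missing ICE component column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  data$ice_total <- purrr::pmap_dbl(data[comp], function(naming, orientation,
                                                         command, attention, writing) {
    ice_total(ice_assessment(naming, orientation, command, attention, writing))
  })
  dom <- function(col) if (col %in% names(data)) data[[col]] else 0
  data$icans <- icans_grade(data$ice_total, loc = dom("loc"), motor = dom("motor"),
                            seizure = dom("seizure_domain"), edema = dom("edema"),
                            bands = bands)
  data
}

#' @rdname grade_exams
#' @export
reconcile_reviews <- function(data) {
  data <- tibble::as_tibble(data)
  for (col in c("subject_id", "day", "icans")) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  out <- dplyr::group_by(data, .data$subject_id, .data$day)
  out <- dplyr::summarise(
    out,
    n_reviewers = dplyr::n(),
    source = if (length(unique(.data$icans)) == 1) "single" else "reconciled",
    icans = mean(.data$icans),
    .groups = "drop"
  )
  dplyr::relocate(out, "icans", .after = "day")
}

#' Inter-rater agreement statistics
#'
#' Quantifies agreement between raters scoring the same items (e.g. several
#' epileptologists assigning VE-ICANS scores to the same EEG images): the
#' mean and standard deviation of absolute score deviations, and the percent
#' of comparisons differing by 0, by 1, and by 2 or more points.
#'
#' @param scores numeric matrix, raters in rows, items in columns.
#' @param basis `"pairwise"` (default): absolute differences over all rater
#'   pairs per item; `"consensus"`: absolute deviations from the per-item
#'   rater mean.
#' @return tibble with columns `mad`, `sd_ad`, `pct_diff_0`, `pct_diff_1`,
#'   `pct_diff_ge2` (percentages summing to 100), and `n_comparisons`.
#' @examples
#' m <- rbind(r1 = c(3, 5, 2), r2 = c(3, 6, 2))
#' agreement_stats(m)
#' @export
agreement_stats <- function(scores, basis = c("pairwise", "consensus")) {
  basis <- match.arg(basis)
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("at least two raters required", call. = FALSE)
  if (ncol(scores) < 1) stop("at least one item required", call. = FALSE)
  devs <- if (basis == "pairwise") {
    pairs <- utils::combn(nrow(scores), 2)
    as.vector(abs(scores[pairs[1, ], , drop = FALSE] -
                  scores[pairs[2, ], , drop = FALSE]))
  } else {
    as.vector(abs(sweep(scores, 2, colMeans(scores))))
  }
  tibble::tibble(
    mad = mean(devs),
    sd_ad = stats::sd(devs),
    pct_diff_0 = 100 * mean(devs < 0.5),
    pct_diff_1 = 100 * mean(devs >= 0.5 & devs < 1.5),
    pct_diff_ge2 = 100 * mean(devs >= 1.5),
    n_comparisons = length(devs)
  )
}
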