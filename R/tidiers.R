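#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained scoring fit
#'
#' One row per vocabulary feature: the real-valued and integer coefficients,
#' whether the feature was retained for training, and the exclusion reason if
#' not.
#'
#' @param x a `veicans_fit`.
#' @param ... unused.
#' @return tibble `feature`, `estimate`, `points`, `retained`, `reason`.
#' @export
tidy.veicans_fit <- function(x, ...) {
  vocab <- eeg_vocabulary()
  tibble::tibble(
    feature = vocab$feature,
    estimate = unname(x$w_real[vocab$feature]),
    points = unname(x$w_int[vocab$feature]),
    retained = vocab$feature %in% x$retained,
    reason = x$excluded$reason[match(vocab$feature, x$excluded$feature)]
  )
}

#' @rdname tidy.veicans_fit
#' @export
glance.veicans_fit <- function(x, ...) {
  dplyr::mutate(x$diagnostics, lambda = x$lambda, alpha = x$config$alpha)
}

#' Tidy a cross-validation report
#'
#' `tidy()` returns the per-level AUC table; `glance()` the headline
#' out-of-sample summary (Pearson r with CI, mean AUC across levels).
#'
#' @param x a `veicans_eval`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.veicans_eval <- function(x, ...) x$auc

#' @rdname tidy.veicans_eval
#' @export
glance.veicans_eval <- function(x, ...) {
  tibble::tibble(
    r = x$pearson$r, conf_low = x$pearson$conf_low,
    conf_high = x$pearson$conf_high,
    mean_auc = mean(x$auc$auc), n = nrow(x$predictions),
    k = max(x$predictions$fold)
  )
}

#' Tidy a scoring table
#'
#' @param x a `veicans_table`.
#' @param ... unused.
#' @return tibble `feature`, `points`, `severe`.
#' @export
tidy.veicans_table <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature = names(x$coefficients),
                   points = unname(x$coefficients), severe = FALSE),
    tibble::tibble(feature = x$severe, points = x$max_score, severe = TRUE)
  )
}
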