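#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per class with the one-vs-rest metrics underlying the macro
#' average.
#'
#' @param x An `ll_report`.
#' @param ... Unused.
#' @return A tibble with `class`, `precision`, `f1`, `sensitivity`,
#'   `specificity`, `degenerate`.
#' @export
tidy.ll_report <- function(x, ...) {
  per_class <- attr(x$metrics, "per_class")
  if (is.null(per_class)) x$metrics else per_class
}

#' Glance at an evaluation report
#'
#' A one-row summary: scheme, model family, feature count and the four
#' macro metrics.
#'
#' @param x An `ll_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ll_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scheme = x$scheme$type, model = x$model,
                   n_features = length(x$features_used)),
    dplyr::select(x$metrics, dplyr::any_of(c("precision", "f1", "sensitivity",
                                             "specificity"))))
}

#' Tidy a score battery
#'
#' Long format: one row per battery variable.
#'
#' @param x An `ll_battery`.
#' @param ... Unused.
#' @return A tibble with `variable` and `value`.
#' @export
tidy.ll_battery <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      dplyr::everything(), names_to = "variable",
                      values_to = "value",
                      values_transform = as.numeric)
}

#' Serialize an evaluation report to JSON
#'
#' @param x An `ll_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- list(scheme = x$scheme, model = x$model,
                  features_used = x$features_used,
                  metrics = as.list(x$metrics),
                  predictions = x$predictions)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
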