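#' Contrast <-> decibel conversion
#'
#' The contrast literature's convention: `dB = 20 * log10(C)`, so 100%
#' contrast is 40 dB and a factor of 2 in contrast is about 6.02 dB.
#'
#' @param C Contrast in percent (> 0).
#' @param db Level in dB.
#' @return `to_db()`: dB; `contrast_from_db()`: percent.
#' @examples
#' to_db(100)               # 40
#' contrast_from_db(20)     # 10
#' @export
to_db <- function(C) {
  if (any(C <= 0)) abort("contrast must be positive to express in dB")
  20 * log10(C)
}

#' @rdname to_db
#' @export
contrast_from_db <- function(db) 10^(db / 20)

#' RMS error between predicted and reference PSEs, in dB
#'
#' `sqrt(mean((20 * log10(pred / ref))^2))` over aligned conditions: the
#' summary statistic used to score each model's matching predictions against a
#' reference (human or simulated) matching function.
#'
#' @param pred,ref Positive PSE vectors of equal length, percent, aligned by
#'   condition.
#' @return RMS error in dB (scalar, >= 0).
#' @examples
#' rms_error_db(c(8, 16), c(8, 16))        # 0
#' rms_error_db(2 * c(8, 16), c(8, 16))    # ~6.02
#' @export
rms_error_db <- function(pred, ref) {
  if (length(pred) != length(ref))
    abort(sprintf("prediction (%d) and reference (%d) tables are misaligned",
                  length(pred), length(ref)))
  if (length(pred) == 0) abort("empty PSE tables")
  if (any(!is.finite(pred)) || any(!is.finite(ref)) ||
      any(pred <= 0) || any(ref <= 0))
    abort("all PSEs must be finite and positive")
  sqrt(mean((20 * log10(pred / ref))^2))
}

#' Compare global-contrast models against a reference matching function
#'
#' Runs [matching_curve()] for each model over the reference's conditions,
#' scores each model by [rms_error_db()] against the reference PSEs, and ranks
#' them.  The reference is never bundled: supply either a simulated-observer
#' table from [observer_matching_curve()] or your own measured PSEs as a data
#' frame with columns `A`, `B`, `j`, `match_mode`, `pse`.
#'
#' @param reference Data frame of reference PSEs (columns `A`, `pse`, and
#'   optionally `B`, `j`, `match_mode`).
#' @param models Character vector of model ids to compare.
#' @param granularity,filtered,params,... Pipeline options passed to
#'   [matching_curve()].
#' @return A `model_comparison`: `summary` (per-model RMS dB error and rank),
#'   `table` (per-condition predictions joined to the reference), and the
#'   reference itself.  `tidy()` returns the summary, `glance()` the winner,
#'   `autoplot()` the matching-curve figure.
#' @export
compare_models <- function(reference,
                           models = c("max", "linsum", "energy", "lf", "ms"),
                           granularity = "toy", filtered = FALSE,
                           params = model_params(), ...) {
  reference <- as_tibble(reference)
  if (!all(c("A", "pse") %in% names(reference)))
    abort("reference must have columns `A` and `pse`")
  for (nm in c("B", "j", "match_mode"))
    if (!nm %in% names(reference))
      reference[[nm]] <- switch(nm, B = 8, j = 1, match_mode = "single")
  cond <- reference[, c("A", "B", "j", "match_mode")]
  per_model <- lapply(models, function(mod) {
    pred <- matching_curve(conditions = cond, model = mod,
                           granularity = granularity, filtered = filtered,
                           params = params, ...)
    dplyr::bind_cols(cond, tibble(model = mod, pse_pred = pred$pse,
                                  pse_ref = reference$pse))
  })
  table <- dplyr::bind_rows(per_model)
  summary <- table |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(rms_error_db = rms_error_db(.data$pse_pred, .data$pse_ref),
                     .groups = "drop") |>
    dplyr::arrange(.data$rms_error_db) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(summary = summary, table = table, reference = reference,
                 granularity = granularity, filtered = filtered),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d conditions (%s granularity%s):\n",
              nrow(x$reference), x$granularity,
              if (x$filtered) ", log-Gabor filtered" else ""))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.model_comparison <- function(x, ...) {
  best <- x$summary[1, ]
  tibble(best_model = best$model, best_rms_error_db = best$rms_error_db,
         n_models = nrow(x$summary), n_conditions = nrow(x$reference))
}
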