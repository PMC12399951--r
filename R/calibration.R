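#' Call-threshold calibration
#'
#' Sweeping the call threshold over a grid trades call rate against
#' hierarchical PPV on the called subset: raising the threshold silences
#' low-confidence calls (call rate falls) while the surviving calls become
#' more precise. The production operating point of 0.55 was chosen on this
#' trade-off for metastatic cases.
#'
#' @name too_calibration
NULL

#' Sweep the call threshold over a grid
#'
#' @param trees Score matrix (samples x hierarchy codes) as produced by
#'   [predict_cohort()] (`$trees`), or a list of named score vectors.
#' @param truth Data frame `(sample_id, truth_code)`.
#' @param h A `too_hierarchy`.
#' @param grid Thresholds, all in `(0.5, 1]` (default `seq(0.51, 0.99, 0.02)`).
#' @param stratum Optional logical vector over samples (e.g. metastatic
#'   cases); the sweep is restricted to it.
#' @return A `too_calibration` tibble: `threshold`, `n`, `n_called`,
#'   `call_rate`, `hppv`, `hsens`.
#' @export
sweep_threshold <- function(trees, truth, h,
                            grid = seq(0.51, 0.99, by = 0.02),
                            stratum = NULL) {
  stopifnot(all(grid > 0.5), all(grid <= 1), !is.unsorted(grid, strictly = TRUE))
  if (is.list(trees)) trees <- do.call(rbind, trees)
  if (!is.null(stratum)) {
    if (!any(stratum)) too_abort("empty calibration stratum",
                                 "too_error_empty_stratum")
    trees <- trees[stratum, , drop = FALSE]
  }
  truth <- tibble::as_tibble(truth)
  ids <- rownames(trees)
  rows <- purrr::map_dfr(grid, function(th) {
    calls <- dplyr::bind_rows(lapply(seq_len(nrow(trees)), function(i) {
      call_scores(trees[i, ], h, th, sample_id = ids[i])
    }))
    m <- evaluate_cohort(calls, truth, h)
    tibble::tibble(threshold = th, n = m$summary$n,
                   n_called = m$summary$n_called,
                   call_rate = m$summary$call_rate,
                   hppv = m$summary$hppv_mean, hsens = m$summary$hsens_mean)
  })
  structure(rows, class = c("too_calibration", class(rows)))
}

#' Select an operating threshold from a calibration curve
#'
#' @param curve A `too_calibration` tibble from [sweep_threshold()].
#' @param rule `"harmonic"` (default) maximizes the harmonic mean of call
#'   rate and hPPV; `"min_hppv"` returns the lowest threshold whose hPPV is
#'   at least `min_hppv`; `"knee"` picks the threshold before the largest
#'   drop in call rate.
#' @param min_hppv Constraint for `rule = "min_hppv"` (default 0.9).
#' @return A single threshold. Ties resolve to the lower threshold
#'   (maximizing calls).
#' @export
select_threshold <- function(curve, rule = c("harmonic", "min_hppv", "knee"),
                             min_hppv = 0.9) {
  rule <- match.arg(rule)
  cr <- curve$call_rate
  hp <- dplyr::coalesce(curve$hppv, 0)
  crit <- switch(rule,
    harmonic = ifelse(cr + hp > 0, 2 * cr * hp / (cr + hp), 0),
    min_hppv = ifelse(hp >= min_hppv, 1, 0) - curve$threshold * 1e-9,
    knee = c(-diff(cr), 0))
  if (all(crit <= 0)) {
    too_abort("degenerate calibration curve: no threshold satisfies the rule",
              "too_error_degenerate_curve")
  }
  curve$threshold[which.max(crit)]  # which.max takes the first (lowest) tie
}

#' Plot a calibration curve
#'
#' Call rate and hPPV against threshold, with the shipped 0.55 operating
#' point dashed.
#'
#' @param object A `too_calibration` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.too_calibration <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("call_rate", "hppv"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0.55, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(call_rate = "#1b9e77", hppv = "#377eb8"),
      labels = c(call_rate = "Call rate", hppv = "hPPV")) +
    ggplot2::labs(x = "Call threshold", y = "Fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
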