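#' Hierarchical evaluation metrics
#'
#' Per-sample hierarchical PPV and sensitivity compare the predicted and true
#' label paths (root excluded) as node sets, then average over called samples.
#' A prediction that is *more* granular than the truth but stays inside the
#' truth terminal's subtree is fully credited, matching how specimens
#' submitted without a subtype (e.g. "metastatic carcinoma, consistent with
#' known breast primary") are scored.
#'
#' @name too_metrics
NULL

#' Per-sample hierarchical positive predictive value
#'
#' `|P intersect C(T)| / |P|` where `P` is the set of predicted-path nodes,
#' `T` the truth-path nodes, and `C(T)` the truth closure: `T` plus all
#' descendants of the truth terminal node.
#'
#' @param pred_path,truth_path Character vectors of codes ordered major-first,
#'   root excluded (as returned by [path_to_root()]).
#' @param h A `too_hierarchy`.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' h <- as_hierarchy(data.frame(
#'   code = c("R", "A", "A1", "A1a", "A1b"),
#'   parent = c(NA, "R", "A", "A1", "A1")))
#' sample_hppv(c("A", "A1", "A1a"), c("A", "A1", "A1b"), h)  # 2/3
sample_hppv <- function(pred_path, truth_path, h) {
  if (!length(pred_path)) {
    too_abort("empty prediction path: hPPV undefined for no-call samples",
              "too_error_empty_path")
  }
  closure <- c(truth_path, descendants(h, truth_path[length(truth_path)]))
  length(intersect(pred_path, closure)) / length(pred_path)
}

#' Per-sample hierarchical sensitivity
#'
#' `|T intersect P| / |T|` over the same root-excluded path sets as
#' [sample_hppv()].
#'
#' @inheritParams sample_hppv
#' @return A fraction in `[0, 1]`.
#' @export
sample_hsens <- function(pred_path, truth_path, h) {
  if (!length(truth_path)) {
    too_abort("empty truth path: hSens undefined", "too_error_empty_path")
  }
  length(intersect(truth_path, pred_path)) / length(truth_path)
}

split_path <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "/", fixed = TRUE)[[1]]
}

#' Call rate of a cohort
#'
#' @param calls A calls tibble (from [call_scores()]), with `no_call` logical.
#' @param strata Optional vector (same length) to stratify by, e.g. CUP
#'   status or primary/metastatic site class.
#' @return A tibble with `stratum` (`"all"` when unstratified), `n`,
#'   `n_called`, `call_rate`.
#' @export
call_rate <- function(calls, strata = NULL) {
  if (!nrow(calls)) too_abort("empty cohort", "too_error_empty_cohort")
  if (is.null(strata)) strata <- rep("all", nrow(calls))
  tibble::tibble(stratum = as.character(strata), no_call = calls$no_call) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_called = sum(!.data$no_call),
      call_rate = .data$n_called / .data$n,
      .groups = "drop")
}

#' Evaluate a cohort of hierarchical calls against truth labels
#'
#' Hierarchical PPV/sensitivity and top-1/top-2 major-category PPV are
#' averaged over *called* samples with a mapped (non-CUP) truth; no-call
#' samples contribute to the call rate only. The depth-1 confusion matrix and
#' per-major PPV/sensitivity are computed over the same called subset.
#'
#' @param calls A calls tibble from [call_scores()] (columns `sample_id`,
#'   `no_call`, `called_path`, `top1_major`, `top2_major`).
#' @param truth A data frame `(sample_id, truth_code)`; use [cup_marker()]
#'   for CUP samples, which are excluded from accuracy metrics.
#' @param h A `too_hierarchy`.
#' @return A `too_metrics` object: list with `summary` (one-row tibble:
#'   `n`, `n_called`, `call_rate`, `hppv_mean`, `hsens_mean`, `top1_ppv`,
#'   `top2_ppv`), `per_major` (tibble `major`, `ppv`, `sensitivity`, `n`) and
#'   `confusion` (tibble `pred_major`, `truth_major`, `n`).
#' @export
evaluate_cohort <- function(calls, truth, h) {
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("sample_id", "truth_code") %in% names(truth)))
  known <- truth$truth_code != cup_marker() & truth$truth_code != unmapped_marker()
  assert_code(h, truth$truth_code[known])

  df <- dplyr::inner_join(calls, truth, by = "sample_id")
  rates <- call_rate(df)
  scored <- df[!df$no_call &
                 df$truth_code != cup_marker() &
                 df$truth_code != unmapped_marker(), , drop = FALSE]

  if (nrow(scored)) {
    pred_paths <- lapply(scored$called_path, split_path)
    truth_paths <- lapply(scored$truth_code, path_to_root, h = h)
    hppv <- purrr::map2_dbl(pred_paths, truth_paths, sample_hppv, h = h)
    hsens <- purrr::map2_dbl(pred_paths, truth_paths, sample_hsens, h = h)
    truth_major <- vapply(truth_paths, `[`, character(1), 1L)
    top1 <- mean(scored$top1_major == truth_major)
    top2 <- mean(scored$top1_major == truth_major |
                   scored$top2_major == truth_major)
    confusion <- tibble::tibble(pred_major = scored$top1_major,
                                truth_major = truth_major) |>
      dplyr::count(.data$pred_major, .data$truth_major, name = "n")
    per_major <- dplyr::full_join(
      confusion |> dplyr::group_by(major = .data$pred_major) |>
        dplyr::summarise(ppv = sum(n[.data$truth_major == .data$major]) / sum(n),
                         n_pred = sum(n), .groups = "drop"),
      confusion |> dplyr::group_by(major = .data$truth_major) |>
        dplyr::summarise(sensitivity = sum(n[.data$pred_major == .data$major]) / sum(n),
                         n = sum(n), .groups = "drop"),
      by = "major") |>
      dplyr::arrange(.data$major)
  } else {
    hppv <- hsens <- numeric(0)
    top1 <- top2 <- NA_real_
    confusion <- tibble::tibble(pred_major = character(0),
                                truth_major = character(0), n = integer(0))
    per_major <- tibble::tibble(major = character(0), ppv = numeric(0),
                                n_pred = integer(0), sensitivity = numeric(0),
                                n = integer(0))
  }

  structure(list(
    summary = tibble::tibble(
      n = rates$n, n_called = rates$n_called, call_rate = rates$call_rate,
      n_scored = nrow(scored),
      hppv_mean = if (nrow(scored)) mean(hppv) else NA_real_,
      hsens_mean = if (nrow(scored)) mean(hsens) else NA_real_,
      top1_ppv = top1, top2_ppv = top2),
    per_major = per_major,
    confusion = confusion),
    class = "too_metrics")
}

#' @export
print.too_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<too_metrics> n=%d, call rate %.1f%% (%d called)\n",
           "  hPPV %.1f%%  hSens %.1f%%  top-1 PPV %.1f%%  top-2 PPV %.1f%%\n"),
    s$n, 100 * s$call_rate, s$n_called, 100 * s$hppv_mean, 100 * s$hsens_mean,
    100 * s$top1_ppv, 100 * s$top2_ppv))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-major-category metrics as a tibble
#' @param x A `too_metrics` object.
#' @param ... Unused.
#' @return The `per_major` tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.too_metrics <- function(x, ...) x$per_major

#' One-row cohort-level metric summary
#' @param x A `too_metrics` object.
#' @param ... Unused.
#' @return The one-row `summary` tibble.
#' @export
#' @exportS3Method generics::glance
glance.too_metrics <- function(x, ...) x$summary

#' Write a metrics report to JSON (+ confusion matrix TSV)
#' @param metrics A `too_metrics` object.
#' @param path Output JSON path; the confusion matrix goes to
#'   `sub(".json", "_confusion.tsv", path)`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(
    list(summary = as.list(metrics$summary),
         per_major = metrics$per_major),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  readr::write_tsv(metrics$confusion,
                   sub("\\.json$", "_confusion.tsv", path))
  invisible(path)
}
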