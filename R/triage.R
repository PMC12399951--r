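#' Clinical triage rule engine
#'
#' Encodes the pathology-review procedure applied to model results. A
#' "critical value discrepancy" is a review flag opened when a
#' high-confidence prediction labels a CUP case or contradicts the submitted
#' diagnosis (flag threshold ~0.90, configurable: in practice it is at the
#' reviewing pathologist's discretion). The action then depends on CUP
#' status, score, orthogonal evidence (IHC, hallmark fusions, viral reads,
#' mutational signatures, imaging/history - curated flags, never model
#' inputs), and the propagated score of the submitted diagnosis.
#'
#' @name too_triage
NULL

evidence_fields <- c("ihc_support", "hallmark_fusion", "viral_reads",
                     "mutational_signature", "imaging_or_history")
evidence_states <- c("supports_call", "contradicts_call", "absent")

triage_actions <- c("no_action", "report_only", "discretionary_lineage_change",
                    "diagnosis_change_eligible", "confirmatory_testing")

#' Orthogonal evidence flags for one case
#'
#' @param ihc_support,hallmark_fusion,viral_reads,mutational_signature,imaging_or_history
#'   Each one of `"supports_call"`, `"contradicts_call"`, `"absent"`.
#' @return A one-row tibble of validated tri-state flags.
#' @export
orthogonal_evidence <- function(ihc_support = "absent",
                                hallmark_fusion = "absent",
                                viral_reads = "absent",
                                mutational_signature = "absent",
                                imaging_or_history = "absent") {
  ev <- tibble::tibble(ihc_support, hallmark_fusion, viral_reads,
                       mutational_signature, imaging_or_history)
  bad <- setdiff(unlist(ev), evidence_states)
  if (length(bad)) {
    too_abort(paste0("invalid evidence state(s): ", paste(bad, collapse = ", ")),
              "too_error_evidence")
  }
  ev
}

#' Triage one case through the review rules
#'
#' Rules, applied in order (all matched rules are recorded in `rationale`):
#' \enumerate{
#'   \item No call: no action.
#'   \item Non-CUP and the called major category matches the submitted
#'     diagnosis' major category: concordant, no action.
#'   \item Discrepancy candidate (CUP called, or non-CUP mismatch) with call
#'     score at or above `discrepancy_threshold`: a critical value
#'     discrepancy is opened.
#'   \item CUP, score at or above `discrepancy_threshold`, and at least one
#'     evidence field supports the call: eligible for diagnosis change.
#'   \item CUP, score at or above `discrepancy_threshold`, no supporting
#'     evidence: reported with discretionary lineage change.
#'   \item Non-CUP discrepancy where the submitted label's propagated score
#'     is 0 or the call score is at or above `discrepancy_threshold`:
#'     confirmatory testing is ordered.
#'   \item Otherwise: result reported, discretionary change offered.
#' }
#'
#' @param call One-row calls tibble for the sample (see [call_scores()]).
#' @param tree Named propagated score vector for the same sample.
#' @param submitted Submitted diagnosis: hierarchy code or [cup_marker()].
#' @param evidence A one-row [orthogonal_evidence()] tibble.
#' @param h A `too_hierarchy`.
#' @param call_threshold Call threshold (default 0.55).
#' @param discrepancy_threshold Score needed to open a discrepancy and to
#'   qualify for diagnosis change / confirmatory testing (default 0.90).
#' @return One-row tibble: `sample_id`, `discrepancy_opened`, `action`,
#'   `rationale` (comma-separated fired rule ids).
#' @export
triage_case <- function(call, tree, submitted, evidence = orthogonal_evidence(),
                        h, call_threshold = 0.55,
                        discrepancy_threshold = 0.90) {
  is_cup <- submitted == cup_marker()
  if (!is_cup) assert_code(h, submitted)
  fired <- character(0)
  decide <- function(action, opened) {
    tibble::tibble(sample_id = call$sample_id, discrepancy_opened = opened,
                   action = action, rationale = paste(fired, collapse = ","))
  }

  if (call$no_call) {
    fired <- "R1_no_call"
    return(decide("no_action", FALSE))
  }
  called_major <- split_path(call$called_path)[1L]
  submitted_major <- if (!is_cup) path_to_root(h, submitted)[1L] else NA_character_
  if (!is_cup && identical(called_major, submitted_major)) {
    fired <- "R2_concordant"
    return(decide("no_action", FALSE))
  }

  # from here on the case is a discrepancy candidate
  high_score <- call$call_score >= discrepancy_threshold
  opened <- high_score
  if (opened) fired <- c(fired, "R3_discrepancy_opened")

  if (is_cup && high_score) {
    supported <- any(unlist(evidence[1, evidence_fields]) == "supports_call")
    if (supported) {
      fired <- c(fired, "R4_cup_supported_change")
      return(decide("diagnosis_change_eligible", opened))
    }
    fired <- c(fired, "R5_cup_unsupported")
    return(decide("discretionary_lineage_change", opened))
  }
  if (!is_cup) {
    submitted_score <- unname(tree[submitted])
    if (submitted_score == 0 || high_score) {
      fired <- c(fired, "R6_confirmatory_testing")
      return(decide("confirmatory_testing", opened))
    }
  }
  fired <- c(fired, "R7_report_only")
  decide("report_only", opened)
}

#' Triage a cohort
#'
#' @param pred A `too_predictions` object.
#' @param meta Metadata tibble with `sample_id` and `submitted_label`.
#' @param evidence Optional tibble: `sample_id` plus the five tri-state
#'   evidence columns; missing samples get all-absent evidence.
#' @param ... Passed to [triage_case()] (`h` is taken from `pred`).
#' @return Tibble of per-sample triage decisions.
#' @export
triage_cohort <- function(pred, meta, evidence = NULL, ...) {
  stopifnot(inherits(pred, "too_predictions"))
  meta <- tibble::as_tibble(meta)
  rows <- lapply(seq_len(nrow(pred$calls)), function(i) {
    id <- pred$calls$sample_id[i]
    sub <- meta$submitted_label[match(id, meta$sample_id)]
    ev <- if (!is.null(evidence) && id %in% evidence$sample_id) {
      do.call(orthogonal_evidence,
              as.list(evidence[match(id, evidence$sample_id), evidence_fields]))
    } else {
      orthogonal_evidence()
    }
    triage_case(pred$calls[i, ], pred$trees[i, ], sub, ev,
                h = pred$hierarchy, ...)
  })
  dplyr::bind_rows(rows)
}

#' Summarize triage decisions, stratified CUP vs non-CUP
#'
#' @param decisions Tibble from [triage_cohort()].
#' @param meta Metadata tibble (`sample_id`, `submitted_label`).
#' @return Tibble of counts and cohort fractions per (stratum, action), plus
#'   discrepancy counts.
#' @export
cohort_triage_summary <- function(decisions, meta) {
  if (!nrow(decisions)) too_abort("empty cohort", "too_error_empty_cohort")
  meta <- tibble::as_tibble(meta)
  decisions |>
    dplyr::mutate(stratum = ifelse(
      meta$submitted_label[match(.data$sample_id, meta$sample_id)] ==
        cup_marker(), "CUP", "non-CUP")) |>
    dplyr::group_by(.data$stratum, .data$action) |>
    dplyr::summarise(n = dplyr::n(),
                     n_discrepancy = sum(.data$discrepancy_opened),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n / nrow(decisions))
}
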