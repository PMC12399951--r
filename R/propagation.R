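#' Hierarchy-consistent score propagation and call logic
#'
#' Each branch classifier emits child scores that sum to one. Propagation
#' nests them: walking the hierarchy top-down, every child score is
#' multiplied by its parent's propagated score, so subcategory scores always
#' sum to the parent category score and terminal scores sum to 1. A call is
#' then a greedy descent kept only while the score stays at or above the
#' call threshold; because major scores sum to one and the threshold exceeds
#' 0.5, at most one major category can ever be called.
#'
#' @name too_scores
NULL

#' Propagate per-branch score maps into a score tree
#'
#' @param branch_outputs Named list: `parent_code` -> named numeric vector of
#'   child scores (a probability vector over the branch's children). Branches
#'   absent from the list (e.g. untrained) get uniform scores.
#' @param h A `too_hierarchy`.
#' @return A named numeric vector over all hierarchy codes (a "score tree"):
#'   root = 1; each child = parent score x branch score; single-child nodes
#'   inherit their parent's score unchanged.
#' @export
#' @examples
#' h <- as_hierarchy(data.frame(code = c("R", "A", "B", "A1", "A2"),
#'                              parent = c(NA, "R", "R", "A", "A")))
#' propagate(list(R = c(A = 0.8, B = 0.2), A = c(A1 = 0.75, A2 = 0.25)), h)
propagate <- function(branch_outputs, h) {
  scores <- stats::setNames(rep(NA_real_, nrow(h$nodes)), h$nodes$code)
  scores[h$root] <- 1
  # nodes tibble is depth-ordered, so parents are always resolved first
  for (parent in h$nodes$code) {
    ch <- hierarchy_children(h, parent)
    if (!length(ch)) next
    if (length(ch) == 1L) {
      scores[ch] <- scores[parent]
      next
    }
    vec <- branch_outputs[[parent]]
    if (is.null(vec)) {
      vec <- stats::setNames(rep(1 / length(ch), length(ch)), ch)
    }
    if (!setequal(names(vec), ch)) {
      too_abort(sprintf("branch '%s': scores do not cover its children", parent),
                "too_error_branch_mismatch")
    }
    if (any(vec < 0) || abs(sum(vec) - 1) > 1e-4) {
      too_abort(sprintf(
        "branch '%s': scores must be a probability vector (sum %.6f)",
        parent, sum(vec)), "too_error_branch_invalid")
    }
    scores[ch] <- scores[parent] * vec[ch] / sum(vec)
  }
  scores
}

#' Threshold a score tree into a hierarchical call
#'
#' Greedy descent from the root: at each node take the highest-scoring child
#' (ties broken lexicographically) and keep descending while the child score
#' is at or above the threshold. The call is the deepest node retained; if
#' even the best major category is below threshold the sample is a no-call.
#' Top-1/top-2 major categories are reported regardless of call status.
#'
#' @param tree Named score vector from [propagate()].
#' @param h A `too_hierarchy`.
#' @param threshold Call threshold in `(0.5, 1]`; the shipped operating point
#'   is 0.55 (inclusive comparison). Values at or below 0.5 are rejected
#'   because they could admit two simultaneous major calls.
#' @param sample_id Identifier copied into the output row.
#' @return One-row tibble: `sample_id`, `no_call`, `called_path`
#'   (slash-separated codes, `NA` for no-call), `call_code`, `call_score`,
#'   `top1_major`, `top2_major`, `threshold`.
#' @export
call_scores <- function(tree, h, threshold = 0.55, sample_id = NA_character_) {
  if (threshold <= 0.5 || threshold > 1) {
    too_abort("call threshold must be in (0.5, 1]", "too_error_threshold")
  }
  majors <- h$nodes$code[h$nodes$depth == 1L]
  ms <- sort(tree[majors], decreasing = TRUE)
  # names() of a sorted vector breaks ties lexicographically after sort();
  # enforce explicitly for determinism
  ord <- order(-tree[majors], majors)
  top <- majors[ord]

  path <- character(0)
  node <- h$root
  repeat {
    ch <- hierarchy_children(h, node)
    if (!length(ch)) break
    best <- ch[order(-tree[ch], ch)][1L]
    if (tree[best] < threshold) break
    path <- c(path, best)
    node <- best
  }

  tibble::tibble(
    sample_id = sample_id,
    no_call = length(path) == 0L,
    called_path = if (length(path)) paste(path, collapse = "/") else NA_character_,
    call_code = if (length(path)) path[length(path)] else NA_character_,
    call_score = if (length(path)) unname(tree[path[length(path)]]) else NA_real_,
    top1_major = top[1L],
    top2_major = if (length(top) > 1L) top[2L] else NA_character_,
    threshold = threshold)
}

#' Score and call a cohort with a trained ensemble
#'
#' Runs every branch network on every sample, propagates branch outputs into
#' score trees, and applies the call threshold.
#'
#' @param model A `too_ensemble` from [train_ensemble()].
#' @param features Feature matrix from [encode_cohort()] (samples x features).
#' @param threshold Call threshold; defaults to the model's stored threshold.
#' @return A `too_predictions` object: list with `calls` (tibble, one row per
#'   sample as in [call_scores()]) and `trees` (samples x codes score matrix).
#' @export
predict_cohort <- function(model, features, threshold = NULL) {
  stopifnot(inherits(model, "too_ensemble"))
  threshold <- threshold %||% model$call_threshold
  h <- model$hierarchy
  branch_mats <- lapply(model$networks, function(net) {
    branch_scores_matrix(net, features)
  })
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  trees <- matrix(NA_real_, nrow(features), nrow(h$nodes),
                  dimnames = list(ids, h$nodes$code))
  calls <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    outputs <- lapply(branch_mats, function(m) m[i, ])
    tree <- propagate(outputs, h)
    trees[i, ] <- tree[colnames(trees)]
    calls[[i]] <- call_scores(tree, h, threshold, sample_id = ids[i])
  }
  structure(list(calls = dplyr::bind_rows(calls), trees = trees,
                 hierarchy = h, threshold = threshold),
            class = "too_predictions")
}

#' @export
print.too_predictions <- function(x, ...) {
  cat(sprintf("<too_predictions> %d samples, %d called (threshold %.2f)\n",
              nrow(x$calls), sum(!x$calls$no_call), x$threshold))
  invisible(x)
}

#' Predictions as a tidy per-sample tibble
#' @param x A `too_predictions` object.
#' @param ... Unused.
#' @return The calls tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.too_predictions <- function(x, ...) x$calls

#' Write per-sample scores and calls to TSV
#'
#' One row per sample: the call columns followed by one propagated-score
#' column per hierarchy code.
#'
#' @param pred A `too_predictions` object.
#' @param path Output TSV path.
#' @param seed,config_hash Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scores <- function(pred, path, seed = NULL, config_hash = NULL) {
  out <- dplyr::bind_cols(pred$calls,
                          tibble::as_tibble(pred$trees))
  write_tsv_provenance(out, path, seed = seed, config_hash = config_hash)
}
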