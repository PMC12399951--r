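test_that("the four canonical worked examples give the documented metric values", {
  fx <- worked_example_fixtures()
  h <- fx$hierarchy
  got_hppv <- purrr::map2_dbl(fx$cases$pred_path, fx$cases$truth_path,
                              sample_hppv, h = h)
  got_hsens <- purrr::map2_dbl(fx$cases$pred_path, fx$cases$truth_path,
                               sample_hsens, h = h)
  expect_equal(got_hppv, c(1, 1, 2 / 3, 1))
  expect_equal(got_hsens, c(1, 2 / 3, 2 / 3, 1))
  expect_equal(got_hppv, fx$cases$hppv)
  expect_equal(got_hsens, fx$cases$hsens)
})

test_that("disjoint majors score zero; empty paths are rejected", {
  h <- h_three_major()
  expect_equal(sample_hppv("A", "B", h), 0)
  expect_equal(sample_hsens("A", "B", h), 0)
  expect_error(sample_hppv(character(0), "A", h), class = "too_error_empty_path")
  expect_error(sample_hsens("A", character(0), h), class = "too_error_empty_path")
})

test_that("hierarchical metrics agree with a brute-force set oracle on random paths", {
  withr::local_seed(99)
  for (i in 1:60) {
    h <- random_hierarchy()
    if (!any(h$nodes$depth == 1)) next
    nodes <- h$nodes
    for (j in 1:5) {
      pred <- random_path(h)
      truth <- random_path(h)
      expect_equal(sample_hppv(pred, truth, h), oracle_hppv(pred, truth, nodes))
      expect_equal(sample_hsens(pred, truth, h), oracle_hsens(pred, truth, nodes))
      # both metrics hit 1 simultaneously iff the prediction covers the truth
      # within its subtree
      both_one <- sample_hppv(pred, truth, h) == 1 && sample_hsens(pred, truth, h) == 1
      covers <- all(truth %in% pred) &&
        all(pred %in% union(truth, oracle_descendants(nodes, truth[length(truth)])))
      expect_equal(both_one, covers)
    }
  }
})

make_calls <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(sample_id = r[[1]], no_call = is.na(r[[2]]),
                   called_path = r[[2]],
                   call_code = NA_character_, call_score = NA_real_,
                   top1_major = r[[3]], top2_major = r[[4]], threshold = 0.55)
  }))
}

test_that("cohort evaluation averages per-sample metrics over called samples only", {
  h <- h_depth3()
  # the three classic cases (exact, prefix, wrong terminal) plus one no-call
  calls <- make_calls(
    list("s1", "A/A1/A1a", "A", "B"),
    list("s2", "A/A1", "A", "B"),
    list("s3", "A/A1/A1b", "A", "B"),
    list("s4", NA_character_, "B", "A"))
  truth <- tibble::tibble(sample_id = paste0("s", 1:4),
                          truth_code = c("A1a", "A1a", "A1a", "A1a"))
  m <- evaluate_cohort(calls, truth, h)
  expect_equal(m$summary$call_rate, 3 / 4)
  expect_equal(m$summary$hppv_mean, (1 + 1 + 2 / 3) / 3)  # 8/9
  expect_equal(m$summary$hsens_mean, (1 + 2 / 3 + 2 / 3) / 3)
  expect_equal(m$summary$top1_ppv, 1)
  expect_equal(glance(m), m$summary)
})

test_that("top-2 PPV credits second-ranked majors and dominates top-1", {
  h <- h_three_major()
  calls <- make_calls(
    list("s1", "B", "B", "A"),   # truth A: top1 wrong, top2 right
    list("s2", "A", "A", "B"))   # truth A: top1 right
  truth <- tibble::tibble(sample_id = c("s1", "s2"), truth_code = c("A", "A"))
  m <- evaluate_cohort(calls, truth, h)
  expect_equal(m$summary$top1_ppv, 1 / 2)
  expect_equal(m$summary$top2_ppv, 1)
  expect_gte(m$summary$top2_ppv, m$summary$top1_ppv)
})

test_that("on a flat hierarchy mean hPPV equals top-1 PPV exactly", {
  h <- as_hierarchy(data.frame(code = c("R", "A", "B", "C"),
                               parent = c(NA, "R", "R", "R")))
  withr::local_seed(1)
  n <- 50
  pred <- sample(c("A", "B", "C"), n, replace = TRUE)
  truth_code <- sample(c("A", "B", "C"), n, replace = TRUE)
  calls <- tibble::tibble(sample_id = paste0("s", 1:n), no_call = FALSE,
                          called_path = pred, call_code = pred,
                          call_score = 0.9, top1_major = pred,
                          top2_major = NA_character_, threshold = 0.55)
  m <- evaluate_cohort(calls, tibble::tibble(sample_id = paste0("s", 1:n),
                                             truth_code = truth_code), h)
  expect_equal(m$summary$hppv_mean, m$summary$top1_ppv)
})

test_that("call_rate handles strata, perfect and empty-call cohorts", {
  calls <- tibble::tibble(no_call = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(call_rate(calls)$call_rate, 3 / 4)
  by_stratum <- call_rate(calls, strata = c("CUP", "CUP", "CUP", "nonCUP"))
  expect_equal(by_stratum$call_rate[by_stratum$stratum == "CUP"], 2 / 3)
  expect_equal(call_rate(tibble::tibble(no_call = rep(TRUE, 3)))$call_rate, 0)
  expect_equal(call_rate(tibble::tibble(no_call = rep(FALSE, 5)))$call_rate, 1)
  expect_error(call_rate(tibble::tibble(no_call = logical(0))),
               class = "too_error_empty_cohort")
})

test_that("truth codes absent from the hierarchy are rejected", {
  h <- h_three_major()
  calls <- make_calls(list("s1", "A", "A", "B"))
  expect_error(
    evaluate_cohort(calls, tibble::tibble(sample_id = "s1", truth_code = "ZZ"), h),
    class = "too_error_unknown_code")
})
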