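test_that("propagation multiplies child scores through the parent score", {
  h <- h_three_major()
  tree <- propagate(list(ROOT = c(A = 0.8, B = 0.15, C = 0.05),
                         A = c(A1 = 0.75, A2 = 0.25),
                         B = c(B1 = 0.5, B2 = 0.5),
                         C = c(C1 = 0.9, C2 = 0.1)), h)
  expect_equal(unname(tree[c("A1", "A2")]), c(0.60, 0.20))
  expect_equal(unname(tree["ROOT"]), 1)
  expect_equal(sum(tree[terminal_labels(h)]), 1, tolerance = 1e-9)
})

test_that("single-child nodes pass the parent score through; missing branches go uniform", {
  h <- as_hierarchy(data.frame(
    code   = c("R", "A", "B", "A1", "A1a", "A1b"),
    parent = c(NA, "R", "R", "A", "A1", "A1")))
  tree <- propagate(list(R = c(A = 0.7, B = 0.3)), h)  # A1 pass-through, A1 branch missing
  expect_equal(unname(tree["A1"]), 0.7)
  expect_equal(unname(tree[c("A1a", "A1b")]), c(0.35, 0.35))

  single <- as_hierarchy(data.frame(code = c("R", "A"), parent = c(NA, "R")))
  expect_equal(unname(propagate(list(), single)["A"]), 1)
})

test_that("invalid branch vectors are rejected", {
  h <- h_three_major()
  good <- list(ROOT = c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
  expect_error(propagate(utils::modifyList(good, list(ROOT = c(A = 0.9, B = 0.9, C = 0.9))), h),
               class = "too_error_branch_invalid")
  expect_error(propagate(list(ROOT = c(A = 0.5, X = 0.5)), h),
               class = "too_error_branch_mismatch")
})

test_that("conservation and monotonicity hold on random hierarchies (property)", {
  withr::local_seed(2024)
  for (i in 1:100) {
    h <- random_hierarchy()
    tree <- propagate(random_branch_outputs(h), h)
    expect_true(all(tree >= 0))
    # every internal node equals the sum of its children
    for (p in names(h$children)) {
      expect_equal(sum(tree[h$children[[p]]]), unname(tree[p]),
                   tolerance = 1e-6)
    }
    expect_equal(sum(tree[terminal_labels(h)]), 1, tolerance = 1e-6)
    # scores never increase along any root-to-leaf path
    for (leaf in terminal_labels(h)) {
      p <- path_to_root(h, leaf)
      expect_true(all(diff(tree[c(h$root, p)]) <= 1e-12))
    }
  }
})

test_that("greedy thresholded calling stops at the deepest confident node", {
  h <- h_three_major()
  tree <- propagate(list(ROOT = c(A = 0.9, B = 0.06, C = 0.04),
                         A = c(A1 = 5 / 9, A2 = 4 / 9),
                         B = c(B1 = 0.5, B2 = 0.5),
                         C = c(C1 = 0.5, C2 = 0.5)), h)
  # A = 0.90 called; A1 = 0.50 below threshold: call terminates at the major
  res <- call_scores(tree, h, threshold = 0.55, sample_id = "s")
  expect_false(res$no_call)
  expect_equal(res$called_path, "A")
  expect_equal(res$call_score, 0.9)
  expect_equal(res$top1_major, "A")
  expect_equal(res$top2_major, "B")

  # with a confident subcategory the call descends
  tree2 <- propagate(list(ROOT = c(A = 0.9, B = 0.06, C = 0.04),
                          A = c(A1 = 0.9, A2 = 0.1),
                          B = c(B1 = 0.5, B2 = 0.5),
                          C = c(C1 = 0.5, C2 = 0.5)), h)
  expect_equal(call_scores(tree2, h, 0.55)$called_path, "A/A1")
  expect_equal(call_scores(tree2, h, 0.55)$call_score, 0.81)
})

test_that("a best major below threshold is a no-call; threshold is inclusive", {
  h <- h_three_major()
  tree <- propagate(list(ROOT = c(A = 0.54, B = 0.26, C = 0.20),
                         A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 0.5, B2 = 0.5),
                         C = c(C1 = 0.5, C2 = 0.5)), h)
  expect_true(call_scores(tree, h, 0.55)$no_call)
  tree2 <- propagate(list(ROOT = c(A = 0.55, B = 0.25, C = 0.20),
                          A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 0.5, B2 = 0.5),
                          C = c(C1 = 0.5, C2 = 0.5)), h)
  expect_false(call_scores(tree2, h, 0.55)$no_call)  # >= is inclusive
  expect_error(call_scores(tree, h, 0.5), class = "too_error_threshold")
})

test_that("equal child scores break ties lexicographically", {
  h <- h_three_major()
  tree <- propagate(list(ROOT = c(A = 0.2, B = 0.4, C = 0.4),
                         A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 0.5, B2 = 0.5),
                         C = c(C1 = 0.5, C2 = 0.5)), h)
  res <- call_scores(tree, h, 0.51)
  expect_equal(res$top1_major, "B")
  expect_equal(res$top2_major, "C")
})

test_that("raising the threshold never lengthens the called path (property)", {
  withr::local_seed(7)
  for (i in 1:40) {
    h <- random_hierarchy()
    if (!any(h$nodes$depth == 1)) next
    tree <- propagate(random_branch_outputs(h), h)
    depths <- vapply(seq(0.51, 0.99, 0.04), function(th) {
      r <- call_scores(tree, h, th)
      if (r$no_call) 0L else length(strsplit(r$called_path, "/")[[1]])
    }, integer(1))
    expect_true(all(diff(depths) <= 0))
  }
})

test_that("label-order permutations permute branch outputs consistently", {
  # equivariance at the propagation level: feeding a permuted branch vector
  # yields identical per-node scores
  h <- h_three_major()
  out <- list(ROOT = c(A = 0.6, B = 0.3, C = 0.1), A = c(A1 = 0.7, A2 = 0.3),
              B = c(B1 = 0.2, B2 = 0.8), C = c(C1 = 0.5, C2 = 0.5))
  perm <- lapply(out, function(v) v[rev(seq_along(v))])
  expect_equal(propagate(perm, h), propagate(out, h))
})
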