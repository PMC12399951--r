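test_that("branch routing follows subtree membership and excludes parent-level truths", {
  h <- as_hierarchy(data.frame(
    code   = c("R", "A", "B", "A1", "A2", "A1a", "A1b"),
    parent = c(NA, "R", "R", "A", "A", "A1", "A1")))
  truth <- c("A1a", "A", "B", "A2", "A1")
  routed <- assign_branch_training_set("A", c("A1", "A2"), truth, h)
  # truth A1a -> child A1 (grandchild routing); truth A excluded (is the
  # parent); truth B excluded (other major); A2 and A1 route directly
  expect_equal(routed$index, c(1L, 4L, 5L))
  expect_equal(routed$child, c("A1", "A2", "A1"))

  root_routed <- assign_branch_training_set("R", c("A", "B"), truth, h)
  expect_equal(root_routed$index, 1:5)  # everyone trains the root branch
})

test_that("branch training is reproducible and rejects degenerate data", {
  withr::local_seed(1)
  x <- rbind(matrix(rnorm(100 * 8, -1), 100, 8), matrix(rnorm(100 * 8, 1), 100, 8))
  colnames(x) <- paste0("f", 1:8)
  child <- rep(c("L", "R"), each = 100)
  cfg <- fast_config(seed = 42)
  n1 <- train_branch(x, child, c("L", "R"), cfg)
  n2 <- train_branch(x, child, c("L", "R"), cfg)
  expect_identical(n1$layers, n2$layers)  # bit-identical given the seed

  expect_error(train_branch(x[0, , drop = FALSE], character(0), c("L", "R"), cfg),
               class = "too_error_empty_branch")
  expect_error(train_branch(x, rep("L", 200), c("L", "R"), cfg),
               class = "too_error_degenerate_branch")
})

test_that("branch scores are probability vectors and separate clear clusters", {
  withr::local_seed(8)
  n <- 100
  x <- rbind(matrix(rnorm(n * 10, -2), n, 10), matrix(rnorm(n * 10, 2), n, 10))
  colnames(x) <- paste0("f", 1:10)
  child <- rep(c("L", "R"), each = n)
  holdout <- sample.int(2 * n, 40)
  net <- train_branch(x[-holdout, ], child[-holdout], c("L", "R"), fast_config())

  p <- vapply(holdout, function(i) branch_scores(net, x[i, ]), numeric(2))
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 40), tolerance = 1e-6)
  acc <- mean(c("L", "R")[apply(p, 2, which.max)] == child[holdout])
  expect_gte(acc, 0.95)

  # the centroid of each training cluster is scored to its own side
  expect_equal(names(which.max(branch_scores(net, colMeans(x[1:n, ])))), "L")
  expect_equal(names(which.max(branch_scores(net, colMeans(x[(n + 1):(2 * n), ])))), "R")
  expect_error(branch_scores(net, rnorm(3)), class = "too_error_dimension")
})

test_that("a zeroed final layer yields uniform scores", {
  withr::local_seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6)
  net <- train_branch(x, rep(c("a", "b", "c"), length.out = 40), c("a", "b", "c"),
                      fast_config(epochs = 1))
  net$layers[[length(net$layers)]]$W[] <- 0
  net$layers[[length(net$layers)]]$b[] <- 0
  expect_equal(unname(branch_scores(net, x[1, ])), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("ensemble training covers represented branches and flags the rest", {
  fx <- encoded_cohort(n = 250, seed = 21)
  cfg <- fast_config()
  m <- train_ensemble(fx$features, fx$cohort$truth$truth_code,
                      h_three_major(), fx$encoder, cfg)
  expect_s3_class(m, "too_ensemble")
  expect_equal(sort(names(m$networks)), c("A", "B", "C", "ROOT"))
  expect_equal(glance(m)$n_trained, 4L)
  expect_equal(nrow(tidy(m)), 4L)

  # all samples from one major: subtype branches of the others untrained
  one_major <- rep(c("A1", "A2"), length.out = nrow(fx$features))
  expect_warning(
    m2 <- train_ensemble(fx$features, one_major, h_three_major(), fx$encoder, cfg),
    "uniform at inference")
  expect_setequal(m2$untrained, c("B", "C", "ROOT"))
  expect_true("A" %in% names(m2$networks))

  # nothing trainable at all
  expect_error(
    suppressWarnings(train_ensemble(fx$features, rep("A1", nrow(fx$features)),
                                    h_three_major(), fx$encoder, cfg)),
    class = "too_error_no_trainable_branch")
})

test_that("end-to-end predictions are reproducible and accurate on separable data", {
  fx <- encoded_cohort(n = 400, seed = 31, node_effect_size = 3,
                       within_class_sd = 0.8)
  h <- h_three_major()
  tr <- 1:300; te <- 301:400
  cfg <- fast_config(seed = 5)
  m1 <- train_ensemble(fx$features[tr, ], fx$cohort$truth$truth_code[tr], h,
                       fx$encoder, cfg)
  m2 <- train_ensemble(fx$features[tr, ], fx$cohort$truth$truth_code[tr], h,
                       fx$encoder, cfg)
  p1 <- predict_cohort(m1, fx$features[te, ])
  p2 <- predict_cohort(m2, fx$features[te, ])
  expect_identical(p1$calls, p2$calls)

  met <- evaluate_cohort(p1$calls, fx$cohort$truth[te, ], h)
  expect_gte(met$summary$top1_ppv, 0.95)
  expect_identical(tidy(p1), p1$calls)
})

test_that("trained ensembles round-trip through the model directory format", {
  fx <- encoded_cohort(n = 150, seed = 13)
  h <- h_three_major()
  m <- train_ensemble(fx$features, fx$cohort$truth$truth_code, h,
                      fx$encoder, fast_config(epochs = 5))
  dir <- withr::local_tempdir()
  write_ensemble(m, dir)
  m2 <- read_ensemble(dir)
  expect_equal(m2$call_threshold, m$call_threshold)
  p1 <- predict_cohort(m, fx$features)
  p2 <- predict_cohort(m2, fx$features)
  expect_equal(p2$trees, p1$trees, tolerance = 1e-12)
  expect_equal(p2$calls, p1$calls)
})
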