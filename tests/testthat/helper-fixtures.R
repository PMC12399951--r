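# Shared fixtures and independent oracles. All fixtures are built in code.

# three-major hierarchy, two subcategories under each major
h_three_major <- function() {
  as_hierarchy(data.frame(
    code   = c("ROOT", "A", "B", "C", "A1", "A2", "B1", "B2", "C1", "C2"),
    parent = c(NA, "ROOT", "ROOT", "ROOT", "A", "A", "B", "B", "C", "C")))
}

# depth-3 toy hierarchy used by the worked metric examples
h_depth3 <- function() {
  as_hierarchy(data.frame(
    code   = c("ROOT", "A", "B", "A1", "A2", "A1a", "A1b"),
    parent = c(NA, "ROOT", "ROOT", "A", "A", "A1", "A1")))
}

# random rooted tree with <= 3 levels; every node gets 0-3 children
random_hierarchy <- function(max_nodes = 30) {
  codes <- "ROOT"
  parent <- NA_character_
  frontier <- "ROOT"
  depth <- 0L
  while (length(frontier) && depth < 3L && length(codes) < max_nodes) {
    nxt <- character(0)
    for (p in frontier) {
      k <- sample(0:3, 1)
      if (!k) next
      kids <- paste0("N", length(codes) + seq_len(k))
      codes <- c(codes, kids)
      parent <- c(parent, rep(p, k))
      nxt <- c(nxt, kids)
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  if (length(codes) == 1L) {  # force at least one child
    codes <- c(codes, "N1")
    parent <- c(parent, "ROOT")
  }
  as_hierarchy(data.frame(code = codes, parent = parent))
}

# random valid branch outputs for a hierarchy (normalized gamma draws)
random_branch_outputs <- function(h) {
  br <- branches(h)
  out <- lapply(br$child_codes, function(kids) {
    g <- stats::rgamma(length(kids), shape = 1)
    stats::setNames(g / sum(g), kids)
  })
  stats::setNames(out, br$parent_code)
}

# random root-excluded path: walk down from a random depth-1 node
random_path <- function(h) {
  majors <- h$nodes$code[h$nodes$depth == 1L]
  node <- sample(majors, 1)
  path <- node
  repeat {
    kids <- h$children[[node]]
    if (is.null(kids) || stats::runif(1) < 0.4) break
    node <- sample(kids, 1)
    path <- c(path, node)
  }
  path
}

# independent brute-force oracles for the hierarchical metrics: ancestor and
# descendant sets recomputed from the raw node table by exhaustive scanning,
# no calls into the package's path machinery
oracle_descendants <- function(nodes, code) {
  out <- character(0)
  frontier <- code
  repeat {
    kids <- nodes$code[!is.na(nodes$parent) & nodes$parent %in% frontier]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

oracle_hppv <- function(pred_path, truth_path, nodes) {
  terminal <- truth_path[length(truth_path)]
  closure <- union(truth_path, oracle_descendants(nodes, terminal))
  sum(pred_path %in% closure) / length(pred_path)
}

oracle_hsens <- function(pred_path, truth_path, nodes) {
  sum(truth_path %in% pred_path) / length(truth_path)
}

# small simulated cohort, encoded; shared across classifier tests
encoded_cohort <- function(h = h_three_major(), n = 300, seed = 11, ...) {
  cfg <- sim_config(h, n_samples = n, n_genes = 60, seed = seed,
                    cup_fraction = 0, ...)
  co <- simulate_cohort(cfg)
  enc <- fit_encoder(co$expression, co$platforms,
                     variant_panel = cfg$variant_panel, n_genes = 50)
  fe <- encode_cohort(co$meta, co$variants, co$expression, co$platforms, enc)
  list(cohort = co, encoder = enc, features = fe$features, qc = fe$qc,
       config = cfg)
}

fast_config <- function(seed = 3, epochs = 25, ...) {
  training_config(hidden_dim = 32, epochs = epochs, batch_size = 64,
                  seed = seed, ...)
}

# hand-built score trees on the three-major hierarchy for rule fixtures
triage_tree <- function(h, major, major_score, sub_split = c(0.5, 0.5),
                        zero_major = NULL) {
  majors <- c("A", "B", "C")
  rest <- setdiff(majors, c(major, zero_major))
  out <- stats::setNames(numeric(3), majors)
  out[major] <- major_score
  out[rest] <- (1 - major_score) / length(rest)
  branch <- lapply(stats::setNames(nm = majors), function(mjr) {
    kids <- h$children[[mjr]]
    stats::setNames(if (mjr == major) sub_split else rep(0.5, 2), kids)
  })
  propagate(c(list(ROOT = out), branch), h)
}

triage_fixture_case <- function(h, submitted, major, major_score,
                                evidence = orthogonal_evidence(),
                                threshold = 0.55, zero_major = NULL,
                                discrepancy_threshold = 0.90) {
  tree <- triage_tree(h, major, major_score, zero_major = zero_major)
  call <- call_scores(tree, h, threshold, sample_id = "case")
  triage_case(call, tree, submitted, evidence, h,
              call_threshold = threshold,
              discrepancy_threshold = discrepancy_threshold)
}

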