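#' Per-branch classifier ensemble
#'
#' One softmax network per hierarchy branch (internal node with two or more
#' children). Each network sees every training sample whose truth path passes
#' through the branch parent and continues at least one level below it, and
#' learns which child subtree the sample belongs to. At inference all
#' networks run on the sample and their child-score maps are combined by
#' [propagate()].
#'
#' @name too_ensemble
NULL

#' Training configuration for branch networks
#'
#' @param hidden_dim Hidden-layer width (default 256).
#' @param n_layers Total number of dense layers including the output
#'   layer (default 4, i.e. three hidden layers).
#' @param dropout_rate Dropout on hidden activations (default 0.25).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed; all training randomness derives from it.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 10).
#' @param val_fraction Fraction of the routed set held out to monitor
#'   early stopping (default 0.1).
#' @param class_weighting Weight classes inversely to their frequency
#'   (default `FALSE`).
#' @return A `too_training_config` list.
#' @export
training_config <- function(hidden_dim = 256L, n_layers = 4L,
                            dropout_rate = 0.25, learning_rate = 0.005,
                            epochs = 100L, batch_size = 256L, seed = 1L,
                            early_stop_patience = 10L, val_fraction = 0.1,
                            class_weighting = FALSE) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            n_layers >= 2L, epochs >= 1L, batch_size >= 1L)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 class_weighting = isTRUE(class_weighting)),
            class = "too_training_config")
}

#' Route training samples to a branch
#'
#' A sample trains a branch iff its truth path contains the branch parent
#' and extends at least one level below it; the class label is the child
#' whose subtree contains the truth label. Samples whose truth *is* the
#' branch parent carry no child information and are excluded (they still
#' train ancestor branches).
#'
#' @param parent_code Branch parent (may be the root).
#' @param child_codes The branch's children.
#' @param truth_codes Character vector of truth labels, one per sample.
#' @param h A `too_hierarchy`.
#' @return A tibble with `index` (row in the sample set) and `child`
#'   (factor level = position in `child_codes`).
#' @export
assign_branch_training_set <- function(parent_code, child_codes,
                                       truth_codes, h) {
  assert_code(h, unique(truth_codes))
  paths <- lapply(truth_codes, path_to_root, h = h)
  routed <- purrr::imap(paths, function(p, i) {
    pos <- if (parent_code == h$root) 0L else match(parent_code, p)
    if (is.na(pos) || length(p) < pos + 1L) return(NULL)
    tibble::tibble(index = i, child = p[pos + 1L])
  })
  out <- dplyr::bind_rows(routed)
  if (!nrow(out)) return(tibble::tibble(index = integer(0), child = character(0)))
  stopifnot(all(out$child %in% child_codes))
  out
}

#' Train one branch network
#'
#' @param x Feature matrix (samples x features) of the routed samples.
#' @param child Character vector of child codes, one per row of `x`.
#' @param child_codes The branch's full (lexicographic) child list; output
#'   units follow this order.
#' @param cfg A [training_config()].
#' @param parent_code Stored on the network for bookkeeping.
#' @return A `too_branch_network`. Training is deterministic given `cfg$seed`.
#' @export
train_branch <- function(x, child, child_codes, cfg = training_config(),
                         parent_code = NA_character_) {
  if (!nrow(x)) too_abort("no training samples routed to this branch",
                          "too_error_empty_branch")
  present <- unique(child)
  if (length(present) < 2L) {
    too_abort(paste0(
      "only one child label present in the routed data; a one-class branch ",
      "cannot be trained - treat it as pass-through/uniform instead"),
      "too_error_degenerate_branch")
  }
  y <- match(child, child_codes)
  stopifnot(!anyNA(y))
  cw <- if (cfg$class_weighting) {
    tab <- tabulate(y, nbins = length(child_codes))
    w <- length(y) / (sum(tab > 0) * pmax(tab, 1))
    w[tab == 0] <- 0
    w
  } else NULL
  fit <- mlp_fit(x, y, length(child_codes), cfg, class_weights = cw)
  structure(list(parent_code = parent_code, child_codes = child_codes,
                 layers = fit$layers, val_loss = fit$val_loss,
                 epochs_run = fit$epochs_run, n_train = nrow(x),
                 feature_names = colnames(x)),
            class = "too_branch_network")
}

#' @export
print.too_branch_network <- function(x, ...) {
  cat(sprintf("<too_branch_network> %s -> {%s}; %d training samples, %d epochs\n",
              x$parent_code, paste(x$child_codes, collapse = ", "),
              x$n_train, x$epochs_run))
  invisible(x)
}

branch_scores_matrix <- function(net, x) {
  if (ncol(x) != nrow(net$layers[[1]]$W)) {
    too_abort(sprintf("feature dimension %d does not match network input %d",
                      ncol(x), nrow(net$layers[[1]]$W)),
              "too_error_dimension")
  }
  p <- mlp_predict_probs(net$layers, x)
  colnames(p) <- net$child_codes
  p
}

#' Score a sample with one branch network
#'
#' Inference mode: dropout off, fixed batch-normalization statistics.
#'
#' @param net A `too_branch_network`.
#' @param x Numeric feature vector (or single-row matrix).
#' @return Named score vector over the branch children: nonnegative, summing
#'   to 1 (softmax output), deterministic for fixed parameters and input.
#' @export
branch_scores <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  branch_scores_matrix(net, x)[1, ]
}

#' Train the full branch ensemble
#'
#' @param features Feature matrix from [encode_cohort()].
#' @param truth_codes Truth label per row of `features` (mapped, non-CUP).
#' @param h A `too_hierarchy`.
#' @param encoder The fitted `too_encoder` (stored on the model).
#' @param cfg A [training_config()]; branch `b` trains with seed
#'   `cfg$seed + b` so branches are independent but jointly reproducible.
#' @param call_threshold Operating call threshold stored on the model
#'   (default 0.55).
#' @return A `too_ensemble`. Branches whose routed data contain fewer than
#'   two child classes are recorded in `$untrained` and score uniformly at
#'   inference (with a warning at training time).
#' @export
train_ensemble <- function(features, truth_codes, h, encoder = NULL,
                           cfg = training_config(), call_threshold = 0.55) {
  br <- branches(h)
  networks <- list()
  untrained <- character(0)
  for (i in seq_len(nrow(br))) {
    parent <- br$parent_code[i]
    kids <- br$child_codes[[i]]
    routed <- assign_branch_training_set(parent, kids, truth_codes, h)
    if (nrow(routed) == 0L || length(unique(routed$child)) < 2L) {
      untrained <- c(untrained, parent)
      next
    }
    bcfg <- cfg
    bcfg$seed <- cfg$seed + i
    networks[[parent]] <- train_branch(
      features[routed$index, , drop = FALSE], routed$child, kids, bcfg,
      parent_code = parent)
  }
  if (!length(networks)) {
    too_abort("no branch has two or more represented children: nothing to train",
              "too_error_no_trainable_branch")
  }
  if (length(untrained)) {
    warning(sprintf("branch(es) with insufficient data treated as uniform at inference: %s",
                    paste(untrained, collapse = ", ")))
  }
  structure(list(hierarchy = h, encoder = encoder, networks = networks,
                 untrained = untrained, config = cfg,
                 call_threshold = call_threshold),
            class = "too_ensemble")
}

#' @export
print.too_ensemble <- function(x, ...) {
  cat(sprintf("<too_ensemble> %d trained branch network(s) over %d labels; threshold %.2f\n",
              length(x$networks), sum(x$hierarchy$nodes$depth > 0),
              x$call_threshold))
  if (length(x$untrained))
    cat("  untrained (uniform) branches:", paste(x$untrained, collapse = ", "), "\n")
  invisible(x)
}

#' Branch-level view of a trained ensemble
#' @param x A `too_ensemble`.
#' @param ... Unused.
#' @return Tibble: `parent_code`, `n_children`, `trained`, `n_train`,
#'   `epochs_run`, `val_loss`.
#' @export
#' @exportS3Method generics::tidy
tidy.too_ensemble <- function(x, ...) {
  br <- branches(x$hierarchy)
  purrr::map2_dfr(br$parent_code, br$child_codes, function(p, kids) {
    net <- x$networks[[p]]
    tibble::tibble(parent_code = p, n_children = length(kids),
                   trained = !is.null(net),
                   n_train = if (is.null(net)) NA_integer_ else net$n_train,
                   epochs_run = if (is.null(net)) NA_integer_ else net$epochs_run,
                   val_loss = if (is.null(net)) NA_real_ else net$val_loss)
  })
}

#' One-row ensemble summary
#' @param x A `too_ensemble`.
#' @param ... Unused.
#' @return Tibble with branch/label counts and the call threshold.
#' @export
#' @exportS3Method generics::glance
glance.too_ensemble <- function(x, ...) {
  tibble::tibble(n_branches = nrow(branches(x$hierarchy)),
                 n_trained = length(x$networks),
                 n_labels = sum(x$hierarchy$nodes$depth > 0),
                 n_major = n_major(x$hierarchy),
                 call_threshold = x$call_threshold)
}

#' Persist / restore a trained ensemble as a model directory
#'
#' Writes `hierarchy.json`, `encoder.json` (if present), one
#' `branch_<parent>.json` parameter file per trained network, and a
#' `manifest.json` with the training config, threshold and version.
#'
#' @param model A `too_ensemble`.
#' @param dir Model directory (created if needed).
#' @return `dir` (write) or a `too_ensemble` (read).
#' @export
write_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(model$hierarchy, file.path(dir, "hierarchy.json"))
  if (!is.null(model$encoder)) {
    write_encoder(model$encoder, file.path(dir, "encoder.json"))
  }
  for (p in names(model$networks)) {
    net <- model$networks[[p]]
    jsonlite::write_json(
      list(parent_code = net$parent_code, child_codes = net$child_codes,
           n_train = net$n_train, epochs_run = net$epochs_run,
           val_loss = net$val_loss, feature_names = net$feature_names,
           layers = net$layers),
      file.path(dir, paste0("branch_", p, ".json")),
      digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(
    list(version = pkg_version(), config = unclass(model$config),
         call_threshold = model$call_threshold, untrained = model$untrained,
         branches = names(model$networks)),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  h <- load_hierarchy(file.path(dir, "hierarchy.json"))
  enc_path <- file.path(dir, "encoder.json")
  enc <- if (file.exists(enc_path)) read_encoder(enc_path) else NULL
  networks <- lapply(manifest$branches, function(p) {
    raw <- jsonlite::fromJSON(file.path(dir, paste0("branch_", p, ".json")),
                              simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
    raw$layers <- lapply(raw$layers, function(ly) {
      if (!is.matrix(ly$W)) {
        ly$W <- do.call(rbind, lapply(ly$W, unlist))  # list of row vectors
      }
      ly
    })
    raw$feature_names <- unlist(raw$feature_names)
    structure(raw, class = "too_branch_network")
  })
  names(networks) <- manifest$branches
  cfg <- do.call(training_config, manifest$config)
  structure(list(hierarchy = h, encoder = enc, networks = networks,
                 untrained = manifest$untrained %||% character(0),
                 config = cfg, call_threshold = manifest$call_threshold),
            class = "too_ensemble")
}
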