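#' Feature encoding: variants, expression, sex
#'
#' A sample's feature vector concatenates (i) a binary gene-level block over
#' the clinically curated variant panel (1 if the gene carries at least one
#' reportable variant; allele frequencies are deliberately not features),
#' (ii) its expression profile restricted to the encoder's high-variance gene
#' set, platform-harmonized and z-standardized on the log2(TPM+1) scale, and
#' (iii) binary sex (male = 1, female = 0, unknown = 0.5).
#'
#' @name too_encoding
NULL

variant_classes <- c("pathogenic", "likely_pathogenic", "vus",
                     "likely_benign", "benign")

#' Filter variant calls down to reportable ones
#'
#' Reportable means classified pathogenic or likely pathogenic, with variant
#' allele frequency at least 5% and at least five supporting read alignments
#' (both comparisons inclusive).
#'
#' @param variants Tibble with columns `sample_id`, `gene`, `classification`,
#'   `vaf`, `support`.
#' @return The retained rows. Idempotent.
#' @export
filter_reportable_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  bad <- setdiff(unique(variants$classification), variant_classes)
  if (length(bad)) {
    too_abort(paste0("unknown variant classification(s): ",
                     paste(bad, collapse = ", "),
                     " (expected ", paste(variant_classes, collapse = "/"), ")"),
              "too_error_classification")
  }
  dplyr::filter(variants,
                .data$classification %in% c("pathogenic", "likely_pathogenic"),
                .data$vaf >= 0.05,
                .data$support >= 5)
}

#' One-hot encode reportable variants at the gene level
#'
#' @param variants Reportable variant rows for a single sample (already
#'   through [filter_reportable_variants()]).
#' @param panel Ordered character vector of panel gene symbols.
#' @return Named binary vector of length `length(panel)`; entry `g` is 1 iff
#'   the sample has at least one reportable variant in gene `g`. Genes
#'   outside the panel are ignored.
#' @export
encode_variant_block <- function(variants, panel) {
  stats::setNames(as.numeric(panel %in% unique(variants$gene)), panel)
}

expression_matrix <- function(expression) {
  expression <- tibble::as_tibble(expression)
  stopifnot(names(expression)[1] == "gene")
  m <- as.matrix(expression[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expression$gene
  if (any(m < 0, na.rm = TRUE)) {
    too_abort("negative TPM values in expression table", "too_error_negative_tpm")
  }
  m
}

#' Fit a feature encoder on training data
#'
#' Selects the `n_genes` highest-variance genes on log2(TPM+1) across the
#' training cohort, fits per-platform per-gene median-shift parameters that
#' align every platform's gene medians to the cohort-wide gene median, and
#' per-gene (center, scale) standardization on the shifted values. Scales of
#' (near-)constant genes are floored so such genes encode to zero.
#'
#' @param expression Tibble: first column `gene`, one TPM column per sample.
#' @param platforms Tibble `(sample_id, platform_id)` covering the samples.
#' @param variant_panel Ordered character vector of panel gene symbols
#'   (clinically curated; the production panel has 227).
#' @param n_genes Number of expression genes to retain (production ~10,000;
#'   pass less for small simulations).
#' @param min_tumor_content QC floor on percent tumor content (default 20);
#'   samples under it are flagged, not rejected.
#' @return A `too_encoder` object.
#' @export
fit_encoder <- function(expression, platforms, variant_panel,
                        n_genes = 10000L, min_tumor_content = 20) {
  if (anyDuplicated(variant_panel)) {
    too_abort("variant panel contains duplicate genes", "too_error_panel")
  }
  m <- expression_matrix(expression)
  if (ncol(m) < 2L) {
    too_abort("need at least 2 training profiles to fit an encoder",
              "too_error_training_set")
  }
  platforms <- tibble::as_tibble(platforms)
  plat <- platforms$platform_id[match(colnames(m), platforms$sample_id)]
  if (anyNA(plat)) {
    too_abort("platform map does not cover all expression samples",
              "too_error_platform_map")
  }
  lg <- log2(m + 1)

  v <- apply(lg, 1, stats::var)
  if (n_genes > nrow(lg)) {
    warning(sprintf("requested %d expression genes but only %d available; using all",
                    n_genes, nrow(lg)))
    n_genes <- nrow(lg)
  }
  genes <- rownames(lg)[order(-v, rownames(lg))][seq_len(n_genes)]
  genes <- sort(genes)
  lg <- lg[genes, , drop = FALSE]

  global_median <- apply(lg, 1, stats::median)
  platform_shift <- lapply(split(colnames(lg), plat), function(ids) {
    apply(lg[, ids, drop = FALSE], 1, stats::median) - global_median
  })
  shifted <- lg
  for (p in names(platform_shift)) {
    ids <- colnames(lg)[plat == p]
    shifted[, ids] <- lg[, ids, drop = FALSE] - platform_shift[[p]]
  }
  center <- rowMeans(shifted)
  scale <- apply(shifted, 1, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- Inf  # constant genes encode to 0

  structure(list(
    variant_panel = as.character(variant_panel),
    expression_genes = genes,
    platform_shift = platform_shift,
    center = center, scale = scale,
    min_tumor_content = min_tumor_content),
    class = "too_encoder")
}

#' @export
print.too_encoder <- function(x, ...) {
  cat(sprintf(
    "<too_encoder> %d panel genes + %d expression genes + sex (%d features), platforms: %s\n",
    length(x$variant_panel), length(x$expression_genes),
    length(x$variant_panel) + length(x$expression_genes) + 1L,
    paste(names(x$platform_shift), collapse = ", ")))
  invisible(x)
}

encode_sex <- function(sex) {
  unname(c(male = 1, female = 0, unknown = 0.5)[sex])
}

#' Encode a cohort into the fixed feature layout
#'
#' @param meta Tibble `(sample_id, sex, site_class, tumor_content,
#'   submitted_label)`.
#' @param variants Variant tibble (raw; reportability filtering is applied
#'   internally).
#' @param expression Expression tibble (first column `gene`).
#' @param platforms Tibble `(sample_id, platform_id)`. Samples on a platform
#'   the encoder has not seen are encoded with identity platform parameters,
#'   with a warning.
#' @param encoder A fitted `too_encoder`.
#' @return List: `features` (numeric matrix, samples x features, rownames =
#'   sample ids) and `qc` (tibble `sample_id`, `low_tumor_content` flag).
#'   Missing expression genes are imputed as 0 on the standardized scale.
#' @export
encode_cohort <- function(meta, variants, expression, platforms, encoder) {
  stopifnot(inherits(encoder, "too_encoder"))
  meta <- tibble::as_tibble(meta)
  m <- expression_matrix(expression)
  missing_expr <- setdiff(meta$sample_id, colnames(m))
  if (length(missing_expr)) {
    too_abort(paste0("samples missing from expression table: ",
                     paste(missing_expr, collapse = ", ")),
              "too_error_sample_mismatch")
  }
  bad_sex <- setdiff(unique(meta$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    too_abort(paste0("unknown sex value(s): ", paste(bad_sex, collapse = ", ")),
              "too_error_sex")
  }
  if (any(meta$tumor_content < 0 | meta$tumor_content > 100)) {
    too_abort("tumor_content must lie in [0, 100]", "too_error_tumor_content")
  }

  platforms <- tibble::as_tibble(platforms)
  plat <- platforms$platform_id[match(meta$sample_id, platforms$sample_id)]
  unknown_plat <- stats::na.omit(unique(plat[!plat %in% names(encoder$platform_shift)]))
  if (length(unknown_plat) || anyNA(plat)) {
    warning(sprintf("platform(s) unknown to the encoder (%s): using identity parameters",
                    paste(unique(c(unknown_plat, if (anyNA(plat)) "<missing>")),
                          collapse = ", ")))
  }

  reportable <- filter_reportable_variants(variants)
  rep_by_sample <- split(reportable$gene, reportable$sample_id)

  genes <- encoder$expression_genes
  lg_present <- intersect(genes, rownames(m))
  n_feat <- length(encoder$variant_panel) + length(genes) + 1L
  features <- matrix(0, nrow(meta), n_feat,
                     dimnames = list(meta$sample_id,
                                     c(paste0("var_", encoder$variant_panel),
                                       paste0("expr_", genes), "sex")))
  expr_cols <- length(encoder$variant_panel) + seq_along(genes)
  for (i in seq_len(nrow(meta))) {
    id <- meta$sample_id[i]
    vb <- encode_variant_block(
      tibble::tibble(gene = rep_by_sample[[id]] %||% character(0)),
      encoder$variant_panel)
    lg <- stats::setNames(rep(NA_real_, length(genes)), genes)
    lg[lg_present] <- log2(m[lg_present, id] + 1)
    p <- plat[i]
    if (!is.na(p) && p %in% names(encoder$platform_shift)) {
      lg <- lg - encoder$platform_shift[[p]]
    }
    z <- (lg - encoder$center) / encoder$scale
    z[!is.finite(z) | is.na(z)] <- 0  # missing gene or constant-gene scale
    features[i, ] <- c(vb, z, encode_sex(meta$sex[i]))
  }

  qc <- tibble::tibble(sample_id = meta$sample_id,
                       low_tumor_content = meta$tumor_content < encoder$min_tumor_content)
  if (any(qc$low_tumor_content)) {
    warning(sprintf("%d sample(s) below %g%% tumor content flagged in QC",
                    sum(qc$low_tumor_content), encoder$min_tumor_content))
  }
  list(features = features, qc = qc)
}

#' Encode a single sample
#'
#' Convenience wrapper around [encode_cohort()] for one sample's records.
#'
#' @param meta One-row metadata tibble.
#' @param variants Variant rows for the sample.
#' @param expression Expression tibble containing the sample's column.
#' @param platform_id The sample's platform.
#' @param encoder A fitted `too_encoder`.
#' @return Named numeric feature vector.
#' @export
encode_sample <- function(meta, variants, expression, platform_id, encoder) {
  stopifnot(nrow(meta) == 1L)
  if (nrow(variants) && any(variants$sample_id != meta$sample_id)) {
    too_abort("variant records do not match the sample id",
              "too_error_sample_mismatch")
  }
  enc <- encode_cohort(meta, variants, expression,
                       tibble::tibble(sample_id = meta$sample_id,
                                      platform_id = platform_id),
                       encoder)
  enc$features[1, ]
}

#' Persist / restore an encoder as JSON
#'
#' @param encoder A `too_encoder`.
#' @param path JSON path.
#' @return `path` (write) or a `too_encoder` (read).
#' @export
write_encoder <- function(encoder, path) {
  x <- unclass(encoder)
  x$scale[!is.finite(x$scale)] <- -1  # JSON has no Inf; scales are positive
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$platform_shift <- lapply(x$platform_shift, unlist)
  x$center <- unlist(x$center)
  x$scale <- unlist(x$scale)
  x$scale[x$scale < 0] <- Inf
  structure(x, class = "too_encoder")
}
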