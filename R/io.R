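#' Readers for the interchange TSV formats
#'
#' All tables are tab-separated with a header row; lines starting with `#`
#' (provenance headers written by this package) are skipped. Readers
#' validate invariants up front and report the offending row/column.
#'
#' @name too_io
NULL

check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    too_abort(sprintf("%s: malformed header, missing column(s): %s",
                      path, paste(missing, collapse = ", ")),
              "too_error_header")
  }
}

#' @describeIn too_io Expression table: column `gene`, one TPM column per
#'   sample. Errors name the first negative or non-numeric cell.
#' @param path Path to a TSV file.
#' @return A tibble (see each reader).
#' @export
read_expression <- function(path) {
  df <- read_tsv_quiet(path)
  check_header(df, "gene", path)
  sample_cols <- setdiff(names(df), "gene")
  for (s in sample_cols) {
    if (!is.numeric(df[[s]])) {
      too_abort(sprintf("%s: non-numeric TPM in column '%s'", path, s),
                "too_error_tpm")
    }
    bad <- which(df[[s]] < 0 | is.na(df[[s]]))
    if (length(bad)) {
      too_abort(sprintf("%s: negative or missing TPM at gene '%s', sample '%s'",
                        path, df$gene[bad[1]], s),
                "too_error_negative_tpm")
    }
  }
  df
}

#' @describeIn too_io Variant calls: `sample_id`, `gene`, `classification`,
#'   `vaf`, `support`.
#' @export
read_variants <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    sample_id = "c", gene = "c", classification = "c",
    vaf = "d", support = "i"))
  check_header(df, c("sample_id", "gene", "classification", "vaf", "support"),
               path)
  bad <- which(!df$classification %in% variant_classes)
  if (length(bad)) {
    too_abort(sprintf("%s: unknown classification '%s' (row %d)",
                      path, df$classification[bad[1]], bad[1]),
              "too_error_classification")
  }
  bad <- which(df$vaf < 0 | df$vaf > 1 | df$support < 0)
  if (length(bad)) {
    too_abort(sprintf("%s: vaf outside [0,1] or negative support (row %d)",
                      path, bad[1]), "too_error_variant_range")
  }
  df
}

#' @describeIn too_io Sample metadata: `sample_id`, `sex`, `site_class`,
#'   `tumor_content`, `submitted_label`.
#' @export
read_meta <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    sample_id = "c", sex = "c", site_class = "c",
    tumor_content = "d", submitted_label = "c"))
  check_header(df, c("sample_id", "sex", "site_class", "tumor_content",
                     "submitted_label"), path)
  for (col in c(sex = "sex", site_class = "site_class")) {
    allowed <- if (col == "sex") c("male", "female", "unknown")
               else c("primary", "metastatic")
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad)) {
      too_abort(sprintf("%s: unknown %s value '%s' (row %d)",
                        path, col, df[[col]][bad[1]], bad[1]),
                paste0("too_error_", col))
    }
  }
  bad <- which(df$tumor_content < 0 | df$tumor_content > 100)
  if (length(bad)) {
    too_abort(sprintf("%s: tumor_content outside [0,100] (row %d)", path, bad[1]),
              "too_error_tumor_content")
  }
  df
}

#' @describeIn too_io Platform map: `sample_id`, `platform_id`.
#' @export
read_platforms <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_header(df, c("sample_id", "platform_id"), path)
  df
}

#' @describeIn too_io Orthogonal evidence: `sample_id` plus the five
#'   tri-state columns.
#' @export
read_evidence <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_header(df, c("sample_id", evidence_fields), path)
  bad_vals <- setdiff(unlist(df[evidence_fields]), evidence_states)
  if (length(bad_vals)) {
    too_abort(sprintf("%s: invalid evidence state(s): %s", path,
                      paste(bad_vals, collapse = ", ")),
              "too_error_evidence")
  }
  df
}

#' @describeIn too_io Truth table: `sample_id`, `truth_code`.
#' @export
read_truth <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_header(df, c("sample_id", "truth_code"), path)
  df
}

#' Read and reconcile the cohort tables
#'
#' Samples present in the metadata but missing from the expression or
#' platform tables (or vice versa) are reported and excluded with a warning;
#' the run continues with the intersection. Variant records are allowed to
#' be absent for a sample (no reportable variants).
#'
#' @param expression,variants,meta,platforms Paths to the four TSVs
#'   (`variants` may be `NULL`).
#' @return List of reconciled tibbles plus `dropped` (excluded sample ids).
#' @export
read_tables <- function(expression, variants, meta, platforms) {
  expr <- read_expression(expression)
  vars <- if (is.null(variants)) {
    tibble::tibble(sample_id = character(0), gene = character(0),
                   classification = character(0), vaf = numeric(0),
                   support = integer(0))
  } else {
    read_variants(variants)
  }
  md <- read_meta(meta)
  pl <- read_platforms(platforms)

  expr_ids <- setdiff(names(expr), "gene")
  keep <- Reduce(intersect, list(md$sample_id, expr_ids, pl$sample_id))
  dropped <- setdiff(unique(c(md$sample_id, expr_ids, pl$sample_id)), keep)
  if (length(dropped)) {
    warning(sprintf("excluding %d sample(s) missing from at least one table: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  list(expression = expr[, c("gene", keep)],
       variants = vars[vars$sample_id %in% keep, , drop = FALSE],
       meta = md[md$sample_id %in% keep, , drop = FALSE],
       platforms = pl[pl$sample_id %in% keep, , drop = FALSE],
       dropped = dropped)
}
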