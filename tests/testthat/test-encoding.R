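variants_tbl <- function(...) {
  tibble::tribble(~sample_id, ~gene, ~classification, ~vaf, ~support, ...)
}

test_that("reportability filter applies class, VAF and support thresholds inclusively", {
  v <- variants_tbl(
    "s1", "TP53", "pathogenic", 0.04, 100L,         # VAF below 5%
    "s1", "KRAS", "pathogenic", 0.50, 100L,         # kept
    "s1", "EGFR", "vus", 0.50, 100L,                # not pathogenic
    "s1", "BRAF", "likely_pathogenic", 0.05, 5L,    # exactly at both thresholds
    "s1", "ALK", "pathogenic", 0.30, 4L,            # support below 5
    "s1", "MET", "benign", 0.30, 50L)
  kept <- filter_reportable_variants(v)
  expect_setequal(kept$gene, c("KRAS", "BRAF"))
  expect_identical(filter_reportable_variants(kept), kept)  # idempotent
  expect_error(
    filter_reportable_variants(variants_tbl("s1", "TP53", "Pathogenic!", 0.5, 9L)),
    class = "too_error_classification")
})

test_that("variant one-hot block is a gene-level indicator over the panel", {
  panel <- c("TP53", "KRAS", "EGFR")
  expect_equal(encode_variant_block(tibble::tibble(gene = character(0)), panel),
               c(TP53 = 0, KRAS = 0, EGFR = 0))
  # two variants in the same gene collapse to a single indicator, and the
  # result matches a brute-force set-membership computation
  recs <- tibble::tibble(gene = c("KRAS", "KRAS", "NOT_IN_PANEL"))
  got <- encode_variant_block(recs, panel)
  brute <- vapply(panel, function(g) as.numeric(g %in% recs$gene), numeric(1))
  expect_equal(got, brute)
  expect_equal(unname(got), c(0, 1, 0))
  expect_equal(sum(encode_variant_block(tibble::tibble(gene = "XYZ"), panel)), 0)
})

test_that("encoder removes multiplicative platform batch effects exactly", {
  withr::local_seed(5)
  n_gene <- 40; n_samp <- 60
  tpm <- matrix(2^stats::rnorm(n_gene * n_samp, 5, 2), n_gene, n_samp,
                dimnames = list(paste0("g", 1:n_gene), paste0("s", 1:n_samp)))
  plat <- rep(c("P1", "P2"), each = n_samp / 2)
  tpm[, plat == "P2"] <- tpm[, plat == "P2"] * 3  # known batch factor
  expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(tpm)),
                           tibble::as_tibble(tpm))
  platforms <- tibble::tibble(sample_id = colnames(tpm), platform_id = plat)
  enc <- fit_encoder(expr, platforms, variant_panel = "TP53", n_genes = n_gene)

  meta <- tibble::tibble(sample_id = colnames(tpm), sex = "female",
                         site_class = "primary", tumor_content = 50,
                         submitted_label = "x")
  fe <- encode_cohort(meta, tibble::tibble(sample_id = character(0),
                                           gene = character(0),
                                           classification = character(0),
                                           vaf = numeric(0), support = integer(0)),
                      expr, platforms, enc)
  z <- fe$features[, paste0("expr_", sort(rownames(tpm)))]
  med1 <- apply(z[plat == "P1", ], 2, median)
  med2 <- apply(z[plat == "P2", ], 2, median)
  expect_lt(max(abs(med1 - med2)), 1e-6)
})

test_that("constant genes get floored scales and encode to zero", {
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         s1 = c(5, 1), s2 = c(5, 2), s3 = c(5, 3))
  platforms <- tibble::tibble(sample_id = c("s1", "s2", "s3"), platform_id = "P")
  enc <- fit_encoder(expr, platforms, variant_panel = "TP53", n_genes = 2)
  meta <- tibble::tibble(sample_id = "s1", sex = "male", site_class = "primary",
                         tumor_content = 80, submitted_label = "x")
  v <- encode_sample(meta, tibble::tibble(sample_id = character(0),
                                          gene = character(0),
                                          classification = character(0),
                                          vaf = numeric(0), support = integer(0)),
                     expr, "P", enc)
  expect_equal(unname(v["expr_g1"]), 0)
  expect_warning(fit_encoder(expr, platforms, "TP53", n_genes = 99),
                 "only 2 available")
})

test_that("feature layout is panel + expression + sex, with QC and sex encoding", {
  fx <- encoded_cohort(n = 40)
  expect_equal(ncol(fx$features),
               length(fx$encoder$variant_panel) +
                 length(fx$encoder$expression_genes) + 1L)
  expect_true(all(fx$features[, seq_along(fx$encoder$variant_panel)] %in% 0:1))
  expect_true(all(fx$features[, "sex"] %in% c(0, 0.5, 1)))

  meta <- fx$cohort$meta[1, ]
  meta$sex <- "unknown"
  meta$tumor_content <- 15
  expect_warning(
    fe <- encode_cohort(meta, fx$cohort$variants, fx$cohort$expression,
                        fx$cohort$platforms, fx$encoder),
    "tumor content")
  expect_equal(unname(fe$features[1, "sex"]), 0.5)
  expect_true(fe$qc$low_tumor_content[1])
})

test_that("encoding is invariant to record order and warns on unknown platforms", {
  fx <- encoded_cohort(n = 30)
  co <- fx$cohort
  shuffled_vars <- co$variants[sample.int(nrow(co$variants)), ]
  shuffled_expr <- co$expression[sample.int(nrow(co$expression)), ]
  fe2 <- encode_cohort(co$meta, shuffled_vars, shuffled_expr,
                       co$platforms, fx$encoder)
  expect_equal(fe2$features, fx$features)

  alien <- co$platforms
  alien$platform_id <- "NOVEL_PLATFORM"
  expect_warning(
    encode_cohort(co$meta, co$variants, co$expression, alien, fx$encoder),
    "identity parameters")
})

test_that("encoders round-trip through JSON", {
  fx <- encoded_cohort(n = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_encoder(fx$encoder, path)
  enc2 <- read_encoder(path)
  fe2 <- encode_cohort(fx$cohort$meta, fx$cohort$variants, fx$cohort$expression,
                       fx$cohort$platforms, enc2)
  expect_equal(fe2$features, fx$features)
})
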