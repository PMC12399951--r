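#' Synthetic tumor cohorts
#'
#' The simulator emulates the statistical structure the classifier assumes:
#' hierarchically nested expression signatures (each hierarchy node adds a
#' sparse log-scale effect vector, so sibling subtypes share their parent's
#' signal and differ in finer genes), label-enriched reportable variants over
#' a gene panel, per-label sex priors, multiplicative platform batch factors,
#' inflated noise for metastatic specimens, and CUP samples whose truth is
#' withheld from the metadata but recorded for oracle evaluation.
#'
#' @name too_simulate
NULL

#' Simulation configuration
#'
#' Defaults describe a moderately separable cohort: effect shifts of 2
#' log2-units spread over 10% of genes per node against unit within-class
#' noise, 1.5x noise inflation for metastatic specimens, a 10% CUP fraction,
#' and two platforms differing by a 2x multiplicative batch factor.
#'
#' @param hierarchy A `too_hierarchy`.
#' @param n_samples Cohort size (default 300).
#' @param n_genes Expression genes simulated (default 200).
#' @param cup_fraction Fraction submitted as CUP (default 0.1).
#' @param metastatic_fraction Fraction of metastatic specimens (default 0.5).
#' @param node_effect_size Magnitude of per-node log2-expression shifts
#'   (default 2; 0 removes all class signal).
#' @param effect_sparsity Fraction of genes carrying each node's effect
#'   (default 0.1).
#' @param within_class_sd Within-class log2 noise SD (default 1).
#' @param metastatic_noise_inflation Noise multiplier for metastatic samples
#'   (default 1.5; must be >= 1).
#' @param platform_factors Named multiplicative TPM batch factors
#'   (default `c(PLAT_A = 1, PLAT_B = 2)`).
#' @param variant_panel Panel gene names (default `"PG1"`..`"PG25"`).
#' @param enriched_per_label Panel genes enriched per label (default 2).
#' @param enriched_rate Reportable-variant rate in enriched genes
#'   (default 0.4).
#' @param background_variant_rate Background rate (default 0.02).
#' @param nonreportable_noise_rate Rate of extra sub-threshold / VUS records
#'   exercising the reportability filter (default 0.1).
#' @param sex_skew Per-label male-fraction priors are drawn from
#'   `Beta(sex_skew, sex_skew)`; default 2 gives mild skew.
#' @param tumor_content_range Uniform range for percent tumor content
#'   (default `c(20, 100)`).
#' @param seed Integer seed (default 1).
#' @return A `too_sim_config` list.
#' @export
sim_config <- function(hierarchy, n_samples = 300L, n_genes = 200L,
                       cup_fraction = 0.1, metastatic_fraction = 0.5,
                       node_effect_size = 2, effect_sparsity = 0.1,
                       within_class_sd = 1, metastatic_noise_inflation = 1.5,
                       platform_factors = c(PLAT_A = 1, PLAT_B = 2),
                       variant_panel = paste0("PG", 1:25),
                       enriched_per_label = 2L, enriched_rate = 0.4,
                       background_variant_rate = 0.02,
                       nonreportable_noise_rate = 0.1,
                       sex_skew = 2, tumor_content_range = c(20, 100),
                       seed = 1L) {
  stopifnot(inherits(hierarchy, "too_hierarchy"),
            cup_fraction >= 0, cup_fraction <= 1,
            metastatic_fraction >= 0, metastatic_fraction <= 1,
            metastatic_noise_inflation >= 1, within_class_sd > 0)
  structure(as.list(environment()), class = "too_sim_config")
}

#' Simulate a cohort under a configuration
#'
#' Truth labels are drawn uniformly over reportable labels. A sample's
#' log2-expression is `baseline + sum(node effects along its truth path) +
#' Gaussian noise` (SD inflated for metastatic samples), exponentiated to the
#' TPM scale and multiplied by the platform batch factor. Panel variants are
#' Bernoulli draws at the label-enriched or background rate with VAF/support
#' above the reportability thresholds, plus sub-threshold noise records.
#' CUP samples get `submitted_label = cup_marker()`.
#'
#' @param cfg A [sim_config()].
#' @return A `too_cohort`: list of tibbles `expression` (gene x sample TPM),
#'   `variants`, `meta`, `platforms`, and `truth` (`sample_id`,
#'   `truth_code`) which includes the withheld truth of CUP samples.
#'   Byte-identical across runs with the same config.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "too_sim_config"))
  h <- cfg$hierarchy
  set.seed(cfg$seed)
  labels <- reportable_labels(h)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids <- sprintf("S%04d", seq_len(cfg$n_samples))

  baseline <- stats::rnorm(cfg$n_genes, mean = 4, sd = 1.5)
  n_hit <- max(1L, round(cfg$effect_sparsity * cfg$n_genes))
  node_effect <- lapply(stats::setNames(nm = h$nodes$code[h$nodes$depth > 0]),
                        function(code) {
    e <- numeric(cfg$n_genes)
    hit <- sample.int(cfg$n_genes, n_hit)
    e[hit] <- sample(c(-1, 1), n_hit, replace = TRUE) * cfg$node_effect_size
    e
  })
  enriched <- lapply(stats::setNames(nm = labels), function(code) {
    sample(cfg$variant_panel, min(cfg$enriched_per_label,
                                  length(cfg$variant_panel)))
  })
  sex_prior <- stats::setNames(
    stats::rbeta(length(labels), cfg$sex_skew, cfg$sex_skew), labels)

  truth <- sample(labels, cfg$n_samples, replace = TRUE)
  is_cup <- stats::runif(cfg$n_samples) < cfg$cup_fraction
  is_met <- stats::runif(cfg$n_samples) < cfg$metastatic_fraction
  platform <- sample(names(cfg$platform_factors), cfg$n_samples, replace = TRUE)
  sex <- unname(ifelse(stats::runif(cfg$n_samples) < sex_prior[truth], "male", "female"))
  tumor_content <- stats::runif(cfg$n_samples, cfg$tumor_content_range[1],
                                cfg$tumor_content_range[2])

  tpm <- matrix(0, cfg$n_genes, cfg$n_samples, dimnames = list(genes, ids))
  for (i in seq_len(cfg$n_samples)) {
    mu <- baseline
    for (node in path_to_root(h, truth[i])) mu <- mu + node_effect[[node]]
    sd_i <- cfg$within_class_sd *
      (if (is_met[i]) cfg$metastatic_noise_inflation else 1)
    lg <- mu + stats::rnorm(cfg$n_genes, sd = sd_i)
    tpm[, i] <- pmax(2^lg - 1, 0) * cfg$platform_factors[[platform[i]]]
  }

  var_rows <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    rate <- ifelse(cfg$variant_panel %in% enriched[[truth[i]]],
                   cfg$enriched_rate, cfg$background_variant_rate)
    hit <- cfg$variant_panel[stats::runif(length(rate)) < rate]
    noise <- cfg$variant_panel[stats::runif(length(rate)) <
                                 cfg$nonreportable_noise_rate]
    rows <- list()
    if (length(hit)) {
      rows$reportable <- tibble::tibble(
        sample_id = ids[i], gene = hit,
        classification = sample(c("pathogenic", "likely_pathogenic"),
                                length(hit), replace = TRUE),
        vaf = stats::runif(length(hit), 0.05, 0.6),
        support = sample(5:200, length(hit), replace = TRUE))
    }
    if (length(noise)) {
      # half below the VAF/support thresholds, half benign/VUS classes
      low <- stats::runif(length(noise)) < 0.5
      rows$noise <- tibble::tibble(
        sample_id = ids[i], gene = noise,
        classification = ifelse(low, "pathogenic",
                                sample(c("vus", "likely_benign", "benign"),
                                       length(noise), replace = TRUE)),
        vaf = ifelse(low, stats::runif(length(noise), 0.001, 0.049),
                     stats::runif(length(noise), 0.05, 0.6)),
        support = ifelse(low, sample(0:4, length(noise), replace = TRUE),
                         sample(5:200, length(noise), replace = TRUE)))
    }
    var_rows[[i]] <- dplyr::bind_rows(rows)
  }

  structure(list(
    expression = dplyr::bind_cols(tibble::tibble(gene = genes),
                                  tibble::as_tibble(tpm)),
    variants = dplyr::bind_rows(var_rows),
    meta = tibble::tibble(
      sample_id = ids, sex = sex,
      site_class = ifelse(is_met, "metastatic", "primary"),
      tumor_content = round(tumor_content, 1),
      submitted_label = ifelse(is_cup, cup_marker(), truth)),
    platforms = tibble::tibble(sample_id = ids, platform_id = platform),
    truth = tibble::tibble(sample_id = ids, truth_code = truth),
    config_hash = config_hash(unclass(cfg)[setdiff(names(cfg), "hierarchy")])),
    class = "too_cohort")
}

#' @export
print.too_cohort <- function(x, ...) {
  cat(sprintf("<too_cohort> %d samples, %d genes, %d variant records, %d CUP\n",
              nrow(x$meta), nrow(x$expression), nrow(x$variants),
              sum(x$meta$submitted_label == cup_marker())))
  invisible(x)
}

#' Worked hierarchical-metric example fixtures
#'
#' Four (prediction path, truth path) pairs on a three-level toy hierarchy
#' that exercise the canonical metric cases: (a) exact match, (b) prediction
#' is a two-level prefix of a deeper truth, (c) wrong terminal under the
#' right level-2 node, (d) prediction more granular than the truth but inside
#' its subtree. Their (hPPV, hSens) are (1, 1), (1, 2/3), (2/3, 2/3), (1, 1).
#'
#' @return List with `hierarchy` and a `cases` tibble (`case`, `pred_path`,
#'   `truth_path` list-columns, `hppv`, `hsens` expected values).
#' @export
worked_example_fixtures <- function() {
  h <- as_hierarchy(data.frame(
    code = c("ROOT", "A", "B", "A1", "A2", "A1a", "A1b"),
    parent = c(NA, "ROOT", "ROOT", "A", "A", "A1", "A1")))
  cases <- tibble::tibble(
    case = c("a", "b", "c", "d"),
    pred_path = list(c("A", "A1", "A1a"), c("A", "A1"),
                     c("A", "A1", "A1b"), c("A", "A1", "A1a")),
    truth_path = list(c("A", "A1", "A1a"), c("A", "A1", "A1a"),
                      c("A", "A1", "A1a"), c("A", "A1")),
    hppv = c(1, 1, 2 / 3, 1),
    hsens = c(1, 2 / 3, 2 / 3, 1))
  list(hierarchy = h, cases = cases)
}

#' Write a simulated cohort as the standard TSV set
#'
#' @param cohort A `too_cohort`.
#' @param dir Output directory (created if needed): `expression.tsv`,
#'   `variants.tsv`, `meta.tsv`, `platforms.tsv`, `truth.tsv`.
#' @param seed Provenance seed recorded in the headers.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("expression", "variants", "meta", "platforms", "truth")) {
    write_tsv_provenance(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         seed = seed, config_hash = cohort$config_hash)
  }
  invisible(dir)
}
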