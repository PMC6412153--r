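# End-to-end orchestrator: simulate (or read) -> renormalize -> cohorts ->
# filters/entropy -> two-level DE -> population structure -> annotate/report.

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a synthetic cohort (when
#' `sim_config` is given or `inputs` is NULL) or user-supplied files:
#' coding-TPM renormalization, cohort assignment, confound summary, the
#' per-sex abundance filter and entropy filters, the two-level quantile DE
#' test on the baseline (BSL) cohort, PCA of all samples over
#' variable genes with outlier detection, PCA of BSL samples over the DE
#' genes, per-sex age-gene correlation over the DE genes, component-age
#' correlation, optional gene-list annotation, and the master report.
#' Per-stage gene and sample counts are logged to stderr. With a fixed
#' seed the run is fully deterministic: two invocations write byte-identical
#' result tables.
#'
#' @param config analysis thresholds from [pipeline_config()] (or a YAML
#'   path readable by [read_config()]).
#' @param sim_config a [simulation_config()]; used when `inputs` is NULL.
#' @param inputs optional list with paths `expression`, `metadata`,
#'   `annotation` (and optional `expression_dialect`).
#' @param gene_lists optional list of [gene_list()] objects for annotation.
#' @param outdir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return Invisibly, a list with elements `expression` (renormalized),
#'   `cohorts`, `confounds`, `entropy`, `de`, `pca_variable`, `outliers`,
#'   `pca_de`, `age_genes`, `age_components`, `report`, and `truth` for
#'   synthetic runs.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         sim_config = simulation_config(),
                         inputs = NULL, gene_lists = NULL, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!is.null(config$simulation)) sim_config <- config$simulation

  truth <- NULL
  if (is.null(inputs)) {
    message("simulating cohort (seed ", sim_config$seed, ")")
    sim <- generate_cohort(sim_config)
    expr <- sim$expression
    metadata <- sim$metadata
    annotation <- sim$annotation
    truth <- sim$truth
  } else {
    expr <- read_expression(inputs$expression,
                            dialect = inputs$expression_dialect %||% "tsv")
    metadata <- read_metadata(inputs$metadata,
                              age_range = config$age_range)
    annotation <- read_annotation(inputs$annotation)
  }
  message("input: ", nrow(expr), " genes x ", ncol(expr), " samples")

  expr <- renormalize_coding(expr, annotation)
  message("after coding renormalization: ", nrow(expr), " genes")

  cohorts <- assign_cohorts(metadata)
  message("cohorts: ",
          paste(names(table(cohorts$cohort)), table(cohorts$cohort),
                sep = "=", collapse = ", "))
  confounds <- confound_summary(cohorts, metadata)

  analysed <- cohorts$sample_id[cohorts$cohort != "EXCLUDED"]
  bsl <- cohorts$sample_id[cohorts$cohort == "BSL"]
  bsl_sex <- cohorts$sex[match(bsl, cohorts$sample_id)]
  if (length(unique(bsl_sex)) < 2L) {
    stop("BSL cohort does not contain both sexes")
  }

  # expression + entropy filters on the BSL cohort (per-sex abundance rule;
  # ubiquity filter agnostic to sex)
  groups <- split(bsl, bsl_sex)
  expressed <- filter_expressed(expr[, analysed, drop = FALSE], groups,
                                config$expression_median_min,
                                config$expression_max_min)
  message("expressed genes (BSL per-sex rule): ", sum(expressed))
  e_all <- normalized_entropy(expr[, analysed, drop = FALSE])
  e_bsl <- normalized_entropy(expr[, bsl, drop = FALSE])
  variable <- select_variable(e_all, expressed,
                              config$entropy_variable_percentile)
  testable <- select_nonubiquitous(e_bsl, expressed,
                                   config$entropy_nonubiquitous_percentile)
  message("variable genes: ", sum(variable),
          "; testable (non-ubiquitous) genes: ", sum(testable))
  entropy_tab <- data.frame(gene_id = rownames(expr),
                            e_all_cohorts = unname(e_all),
                            e_bsl = unname(e_bsl),
                            expressed = unname(expressed),
                            variable = unname(variable),
                            testable = unname(testable),
                            stringsAsFactors = FALSE)

  de <- run_de(expr[testable, bsl, drop = FALSE], bsl_sex,
               de_config(alpha = config$alpha,
                         fold_threshold = config$fold_threshold,
                         epsilon = config$epsilon,
                         fold_pseudo = config$fold_pseudo,
                         fold_gate = config$fold_gate))
  message("DE calls: ", sum(de$call != "none"), " of ", nrow(de),
          " tested genes")

  # sample structure over variable genes, all analysed samples
  pca_variable <- NULL
  outliers <- NULL
  if (sum(variable) >= 2L) {
    pca_variable <- pca_samples(expr[, analysed, drop = FALSE],
                                genes = variable,
                                log2_transform = config$pca_log2,
                                standardize = config$pca_standardize)
    outliers <- detect_outliers(pca_variable,
                                n_components = config$outlier_components,
                                sd_threshold = config$outlier_sd,
                                cohorts = cohorts,
                                standardize = config$outlier_standardize)
  }

  # structure of the BSL cohort over the DE gene set, plus age correlation
  de_genes <- de$gene_id[de$call != "none"]
  pca_de <- NULL
  age_components <- NULL
  age_genes <- NULL
  if (length(de_genes) >= 2L) {
    pca_de <- pca_samples(expr[, bsl, drop = FALSE], genes = de_genes,
                          log2_transform = config$pca_log2,
                          standardize = config$pca_standardize)
    age_components <- age_correlation_components(pca_de, metadata)
    age_genes <- rbind(
      age_correlation_genes(expr[, bsl, drop = FALSE], metadata,
                            genes = de_genes, sex = "male",
                            annotation = annotation, alpha = config$alpha,
                            r_threshold = config$r_threshold),
      age_correlation_genes(expr[, bsl, drop = FALSE], metadata,
                            genes = de_genes, sex = "female",
                            annotation = annotation, alpha = config$alpha,
                            r_threshold = config$r_threshold))
  } else {
    message("fewer than 2 DE genes: skipping DE-gene structure analysis")
  }

  if (!is.null(gene_lists)) {
    de <- intersect_gene_lists(de, gene_lists, annotation = annotation)
  }
  report <- build_report(de, entropy = entropy_tab, truth = truth)

  result <- list(expression = expr, cohorts = cohorts,
                 confounds = confounds, entropy = entropy_tab, de = de,
                 pca_variable = pca_variable, outliers = outliers,
                 pca_de = pca_de, age_genes = age_genes,
                 age_components = age_components, report = report,
                 truth = truth)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all pipeline result tables to a directory
#'
#' Emits the deterministic TSV result set of a [run_pipeline()] run:
#' cohorts, confound summary, entropy table, DE results, outlier table,
#' PCA variance fractions, age correlations and the master report.
#'
#' @param result list returned by [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(tab, name) {
    if (!is.null(tab)) write_results(tab, file.path(outdir, name))
  }
  out(result$cohorts, "cohorts.tsv")
  out(result$confounds, "confound_summary.tsv")
  out(result$entropy, "entropy.tsv")
  out(result$de, "de_results.tsv")
  out(result$outliers$samples, "outlier_samples.tsv")
  out(result$outliers$cohort_fractions, "outlier_fractions.tsv")
  if (!is.null(result$pca_variable)) {
    out(data.frame(component = paste0("PC",
                     seq_along(result$pca_variable$variance_fraction)),
                   variance_fraction = result$pca_variable$variance_fraction),
        "pca_variable_variance.tsv")
  }
  out(result$age_genes, "age_correlation_genes.tsv")
  out(result$age_components, "age_correlation_components.tsv")
  out(result$report, "report.tsv")
  if (!is.null(result$truth)) out(result$truth, "truth.tsv")
  invisible(outdir)
}
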