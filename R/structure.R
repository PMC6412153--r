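# Sample-level population structure: PCA over selected gene sets, outlier
# detection in the leading component space, and age-expression correlation.

#' PCA of samples over a gene set
#'
#' Principal components analysis of samples in the space of the selected
#' genes. By default expression is log2(TPM + 1) transformed and each gene
#' is centered and standardized first, so no single high-abundance gene
#' dominates the components. Zero-variance genes are dropped with a warning
#' (they carry no information and break standardization). Component signs
#' are fixed deterministically: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param mat expression matrix (genes x samples).
#' @param genes optional gene ids or logical/integer mask selecting >= 2
#'   rows; default all genes.
#' @param log2_transform log2(TPM + 1) before PCA (default TRUE).
#' @param standardize scale genes to unit variance (default TRUE).
#' @return A list of class `dimorph_pca`: `scores` (samples x components),
#'   `loadings` (genes x components, unit norm), `variance_fraction`
#'   (non-increasing, summing to 1 over all retained components), `sdev`.
#' @export
pca_samples <- function(mat, genes = NULL, log2_transform = TRUE,
                        standardize = TRUE) {
  validate_expression(mat)
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (nrow(mat) < 2L) stop("PCA requires at least 2 selected genes")
  if (ncol(mat) < 2L) stop("PCA requires at least 2 samples")
  x <- t(if (log2_transform) log2(mat + 1) else mat)
  vars <- apply(x, 2L, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance gene(s) dropped before PCA")
    x <- x[, vars > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 non-constant genes for PCA")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest-magnitude loading positive per component
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  structure(list(scores = pr$x,
                 loadings = pr$rotation,
                 variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
                 sdev = pr$sdev),
            class = "dimorph_pca")
}

#' Flag PCA outlier samples
#'
#' A sample is an outlier when its standardized Euclidean distance from the
#' origin of the leading component space,
#' sqrt(sum_c (score_c / sd_c)^2) over the first `n_components` components,
#' is at least `sd_threshold` — i.e. it lies two or more standard deviations
#' away from the origin around which the scores are centered. With
#' `standardize = FALSE` the raw Euclidean norm of the scores is compared
#' against `sd_threshold` times the RMS score magnitude.
#'
#' @param pca a [pca_samples()] result.
#' @param n_components number of leading components (default 2).
#' @param sd_threshold flag distance in standard deviations (default 2).
#' @param cohorts optional named vector (or data.frame with `sample_id` and
#'   `cohort`) giving each sample's cohort, for per-cohort outlier
#'   fractions.
#' @param standardize divide each component by its score SD (default TRUE).
#' @return A list with `samples` (data.frame: sample_id, distance, outlier)
#'   and `cohort_fractions` (data.frame or NULL).
#' @export
detect_outliers <- function(pca, n_components = 2L, sd_threshold = 2,
                            cohorts = NULL, standardize = TRUE) {
  stopifnot(inherits(pca, "dimorph_pca"))
  k <- min(n_components, ncol(pca$scores))
  sc <- pca$scores[, seq_len(k), drop = FALSE]
  sds <- apply(sc, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance component among the leading ",
                          k, " components")
  d <- if (standardize) {
    sqrt(rowSums(sweep(sc, 2L, sds, `/`)^2))
  } else {
    # unitless comparison: norm relative to the RMS per-component scale
    sqrt(rowSums(sc^2)) / sqrt(mean(sds^2))
  }
  samples <- data.frame(sample_id = rownames(pca$scores),
                        distance = unname(d),
                        outlier = unname(d >= sd_threshold),
                        stringsAsFactors = FALSE)
  cohort_fractions <- NULL
  if (!is.null(cohorts)) {
    if (is.data.frame(cohorts)) {
      cohorts <- stats::setNames(cohorts$cohort, cohorts$sample_id)
    }
    co <- cohorts[samples$sample_id]
    agg <- tapply(samples$outlier, co, mean)
    cohort_fractions <- data.frame(cohort = names(agg),
                                   outlier_fraction = as.numeric(agg),
                                   n = as.integer(table(co)[names(agg)]),
                                   stringsAsFactors = FALSE)
  }
  list(samples = samples, cohort_fractions = cohort_fractions)
}

#' Per-gene age-expression correlation within one sex
#'
#' Pearson correlation of each gene's TPM with donor age over the samples of
#' one sex, with Benjamini-Hochberg adjustment across the tested genes. A
#' correlation is called significant when |R| exceeds `r_threshold` and the
#' BH q-value passes `alpha`. When annotation is supplied, Y-chromosome
#' genes are excluded from the female run (they are not expressed in
#' females, so the test is undefined there). Constant genes are reported
#' with NA correlation and reason "constant", never as significant.
#'
#' @param mat expression matrix.
#' @param metadata donor metadata with SAMPID, SEX and AGE.
#' @param genes gene ids (or mask) to test; default all rows.
#' @param sex "male" or "female"; at least 3 samples of that sex required.
#' @param annotation optional annotation with `gene_id` and `chromosome`.
#' @param alpha BH threshold (default 0.05).
#' @param r_threshold minimum |R| for significance (default 0.20).
#' @return A data.frame: gene_id, sex, n, r, p, q, significant, reason.
#' @export
age_correlation_genes <- function(mat, metadata, genes = NULL,
                                  sex = c("male", "female"),
                                  annotation = NULL, alpha = 0.05,
                                  r_threshold = 0.20) {
  validate_expression(mat)
  sex <- match.arg(sex)
  stopifnot(all(c("SAMPID", "SEX", "AGE") %in% names(metadata)))
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (sex == "female" && !is.null(annotation)) {
    y_genes <- annotation$gene_id[annotation$chromosome == "Y"]
    drop <- rownames(mat) %in% y_genes
    if (any(drop)) mat <- mat[!drop, , drop = FALSE]
  }
  meta <- metadata[match(colnames(mat), metadata$SAMPID), ]
  keep <- which(meta$SEX == sex)
  if (length(keep) < 3L) stop("need at least 3 ", sex, " samples")
  ages <- meta$AGE[keep]
  sub <- mat[, keep, drop = FALSE]
  g <- nrow(sub)
  r <- p <- rep(NA_real_, g)
  reason <- rep(NA_character_, g)
  for (i in seq_len(g)) {
    v <- sub[i, ]
    if (stats::sd(v) == 0 || stats::sd(ages) == 0) {
      reason[i] <- "constant"
      next
    }
    ct <- stats::cor.test(v, ages, method = "pearson")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  q <- rep(NA_real_, g)
  tested <- !is.na(p)
  if (any(tested)) q[tested] <- bh_adjust(p[tested], alpha)$qvalues
  significant <- tested & q <= alpha & abs(r) > r_threshold
  significant[is.na(significant)] <- FALSE
  data.frame(gene_id = rownames(sub), sex = sex, n = length(keep),
             r = r, p = p, q = q, significant = significant,
             reason = reason, stringsAsFactors = FALSE)
}

#' Age correlation of principal components
#'
#' Pearson correlation of each leading component score with donor age.
#' Flipping a component's sign flips the sign of its correlation, so the
#' deterministic sign convention of [pca_samples()] makes results
#' reproducible.
#'
#' @param pca a [pca_samples()] result.
#' @param metadata donor metadata with SAMPID and AGE covering the scored
#'   samples.
#' @param n_components number of leading components to test (default 6).
#' @return A data.frame: component, r, p.
#' @export
age_correlation_components <- function(pca, metadata, n_components = 6L) {
  stopifnot(inherits(pca, "dimorph_pca"))
  stopifnot(all(c("SAMPID", "AGE") %in% names(metadata)))
  ids <- rownames(pca$scores)
  meta <- metadata[match(ids, metadata$SAMPID), ]
  if (anyNA(meta$SAMPID)) stop("scores contain samples absent from metadata")
  k <- min(n_components, ncol(pca$scores))
  out <- lapply(seq_len(k), function(c) {
    ct <- stats::cor.test(pca$scores[, c], meta$AGE, method = "pearson")
    data.frame(component = paste0("PC", c), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
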