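# Coding-TPM renormalization, cohort assignment, confound summary, and the
# abundance/entropy gene filters applied before DE testing.

#' Renormalize TPMs over coding genes
#'
#' Restricts the matrix to coding genes and rescales each sample so that its
#' coding TPMs sum to one million. This removes the varying non-polyA read
#' fraction of rRNA-depleted total-RNA libraries from the relative-abundance
#' scale. Idempotent: renormalizing a renormalized matrix is a no-op.
#'
#' @param mat expression matrix (genes x samples, TPM).
#' @param annotation gene annotation data.frame with `gene_id` and
#'   `is_coding`; every gene in `mat` must be annotated.
#' @return The coding-gene submatrix, rescaled per sample to sum to 1e6.
#' @export
#' @examples
#' mat <- matrix(c(1, 3, 4, 2, 6, 8), nrow = 3,
#'               dimnames = list(c("A", "B", "C"), c("S1", "S2")))
#' ann <- data.frame(gene_id = c("A", "B", "C"), symbol = c("A", "B", "C"),
#'                   chromosome = "1", is_coding = c(TRUE, TRUE, FALSE))
#' renormalize_coding(mat, ann)  # A,B rescaled to 250000/750000 per sample
renormalize_coding <- function(mat, annotation) {
  validate_expression(mat)
  missing <- setdiff(rownames(mat), annotation$gene_id)
  if (length(missing)) {
    stop("unannotated gene id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  coding <- annotation$gene_id[annotation$is_coding]
  keep <- rownames(mat) %in% coding
  if (!any(keep)) stop("no coding genes present in the matrix")
  sub <- mat[keep, , drop = FALSE]
  totals <- colSums(sub)
  zero <- which(totals <= 0)
  if (length(zero)) {
    stop("all-zero coding expression for sample(s): ",
         paste(colnames(sub)[zero], collapse = ", "))
  }
  sweep(sub, 2L, 1e6 / totals, `*`)
}

#' Assign donors to clinical cohorts
#'
#' Classifies each donor from medical-history flags into one of three
#' analysis cohorts, after applying the exclusion rules: donors with sepsis,
#' a positive HIV serology, Type I diabetes, or both chronic joint pain and
#' Type II diabetes are excluded outright. Remaining donors with arthritis
#' or rheumatoid arthritis form the chronic-joint-pain cohort (CJP), donors
#' with Type II diabetes the T2D cohort, and all others the baseline cohort
#' (BSL). Unknown flag values never trigger an exclusion or a disease cohort
#' (treated as "no" for assignment purposes).
#'
#' @param metadata metadata data.frame from [read_metadata()] (or with the
#'   same columns).
#' @return A data.frame with `sample_id`, `cohort` in
#'   \{BSL, CJP, T2D, EXCLUDED\}, `sex`, and `exclusion_reason` (NA unless
#'   excluded). Assignment is exhaustive and mutually exclusive.
#' @export
assign_cohorts <- function(metadata) {
  need <- c("SAMPID", "SEX", "MHT1D", "MHT2D", "MHARTHTS", "MHRA",
            "MHSEPSIS", "LBHIV1NT")
  missing <- setdiff(need, names(metadata))
  if (length(missing)) {
    stop("metadata is missing cohort-defining column(s): ",
         paste(missing, collapse = ", "))
  }
  yes <- function(col) metadata[[col]] == "yes"
  arthritis <- yes("MHARTHTS") | yes("MHRA")
  t2d <- yes("MHT2D")
  reason <- rep(NA_character_, nrow(metadata))
  reason[arthritis & t2d] <- "chronic joint pain with Type II diabetes"
  reason[yes("MHT1D")] <- "Type I diabetes"
  reason[metadata$LBHIV1NT == "positive"] <- "HIV positive"
  reason[yes("MHSEPSIS")] <- "sepsis"
  cohort <- ifelse(!is.na(reason), "EXCLUDED",
                   ifelse(arthritis, "CJP",
                          ifelse(t2d, "T2D", "BSL")))
  data.frame(sample_id = metadata$SAMPID,
             cohort = cohort,
             sex = metadata$SEX,
             exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Summarize potential confounders per cohort and sex
#'
#' Tabulates the clinical variables typically screened as confounders:
#' percentages per level for categorical variables (race, medical-history
#' flags, HIV serology) and mean/standard deviation (sample SD) for AGE,
#' BMI, HGHT and WGHT, within each cohort-by-sex subcohort. Empty
#' subcohorts appear with count 0 and blank statistics.
#'
#' @param assignments cohort table from [assign_cohorts()].
#' @param metadata matching metadata data.frame.
#' @param cohorts cohorts to summarize (default all non-excluded present).
#' @return A long data.frame: `cohort`, `sex`, `variable`, `statistic`
#'   (a level name, "mean", "sd" or "n"), `value`.
#' @export
confound_summary <- function(assignments, metadata,
                             cohorts = c("BSL", "CJP", "T2D")) {
  stopifnot(all(assignments$sample_id %in% metadata$SAMPID))
  metadata <- metadata[match(assignments$sample_id, metadata$SAMPID), ]
  numeric_vars <- intersect(c("AGE", "BMI", "HGHT", "WGHT"), names(metadata))
  cat_vars <- intersect(c("RACE", .flag_cols, "LBHIV1NT"), names(metadata))
  rows <- list()
  add <- function(cohort, sex, variable, statistic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cohort = cohort, sex = sex, variable = variable,
      statistic = statistic, value = value, stringsAsFactors = FALSE)
  }
  for (co in cohorts) {
    for (sx in c("male", "female")) {
      sel <- assignments$cohort == co & assignments$sex == sx
      add(co, sx, "cohort", "n", sum(sel))
      if (!any(sel)) next
      sub <- metadata[sel, , drop = FALSE]
      for (v in numeric_vars) {
        add(co, sx, v, "mean", mean(sub[[v]], na.rm = TRUE))
        add(co, sx, v, "sd", stats::sd(sub[[v]], na.rm = TRUE))
      }
      for (v in cat_vars) {
        tab <- table(sub[[v]])
        for (lev in names(tab)) {
          add(co, sx, v, lev, 100 * as.numeric(tab[[lev]]) / nrow(sub))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Flag expressed genes
#'
#' A gene is considered not expressed only if it fails the abundance
#' criterion (median TPM below `median_min` or maximum TPM below `max_min`)
#' in every group; passing in any single group keeps the gene. With a single
#' pooled group this reduces to the cross-cohort variant of the filter. The
#' comparisons are strict, so a gene sitting exactly at median 0.5 and
#' maximum 1.0 passes.
#'
#' @param mat expression matrix.
#' @param groups a list of sample id (or index) vectors partitioning — or
#'   selecting from — the columns of `mat`; typically
#'   `list(male = ..., female = ...)` or a single pooled group.
#' @param median_min,max_min abundance thresholds (defaults 0.5 and 1.0).
#' @return Named logical vector over genes: TRUE if expressed.
#' @export
filter_expressed <- function(mat, groups, median_min = 0.5, max_min = 1.0) {
  validate_expression(mat)
  if (!is.list(groups)) groups <- list(groups)
  fails <- matrix(FALSE, nrow = nrow(mat), ncol = length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sub <- mat[, idx, drop = FALSE]
    if (ncol(sub) == 0L) stop("empty sample group in filter_expressed()")
    med <- apply(sub, 1L, stats::median)
    mx <- apply(sub, 1L, max)
    fails[, g] <- med < median_min | mx < max_min
  }
  expressed <- !apply(fails, 1L, all)
  names(expressed) <- rownames(mat)
  expressed
}

#' Normalized Shannon entropy of gene expression across samples
#'
#' For gene i with TPM t_ij in sample j, the across-sample distribution
#' p_ij = t_ij / sum_k t_ik has Shannon entropy -sum_j p_ij log2 p_ij (with
#' 0 log 0 = 0), normalized by log2 N so that e lies in \[0, 1\]: e = 1 for
#' perfectly uniform (ubiquitous) expression, e = 0 for expression confined
#' to a single sample. Genes with an all-zero row are scored 0 by the
#' 0 log 0 convention. Entropy is invariant to sample order and to rescaling
#' a gene row.
#'
#' @param mat expression matrix with at least 2 samples.
#' @return Named numeric vector of entropies in \[0, 1\].
#' @export
#' @examples
#' m <- rbind(unif = c(1, 1, 1), spike = c(0, 0, 5), mix = c(1, 1, 2))
#' colnames(m) <- paste0("S", 1:3)
#' normalized_entropy(m)  # 1, 0, 1.5/log2(3)
normalized_entropy <- function(mat) {
  validate_expression(mat)
  n <- ncol(mat)
  if (n < 2L) stop("normalized entropy requires at least 2 samples")
  totals <- rowSums(mat)
  p <- mat / ifelse(totals > 0, totals, 1)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  e <- -rowSums(plogp) / log2(n)
  e[totals == 0] <- 0
  # clamp tiny negative round-off
  pmin(pmax(e, 0), 1)
}

#' Select stably, broadly expressed genes for sample PCA
#'
#' Flags expressed genes whose normalized entropy is at or above the given
#' percentile of entropies over expressed genes. Percentiles use the linear
#' interpolation convention (R quantile type 7); ties at the threshold are
#' included.
#'
#' @param entropy named entropy vector from [normalized_entropy()].
#' @param expressed logical vector (same genes) from [filter_expressed()].
#' @param percentile entropy percentile (default 0.90).
#' @return Named logical mask of selected genes.
#' @export
select_variable <- function(entropy, expressed, percentile = 0.90) {
  stopifnot(length(entropy) == length(expressed))
  out <- rep(FALSE, length(entropy))
  names(out) <- names(entropy)
  if (!any(expressed)) return(out)
  thr <- stats::quantile(entropy[expressed], percentile, type = 7,
                         names = FALSE)
  out[expressed & entropy >= thr] <- TRUE
  out
}

#' Select non-ubiquitous genes for DE testing
#'
#' Flags expressed genes whose normalized entropy is strictly below the
#' given percentile of entropies over expressed genes, removing the most
#' ubiquitously, uniformly expressed genes from testing. The selection is
#' agnostic to sample sex. Warns if the strict comparison leaves no genes
#' (e.g. all entropies equal).
#'
#' @inheritParams select_variable
#' @param percentile entropy percentile (default 0.75).
#' @return Named logical mask of testable genes.
#' @export
select_nonubiquitous <- function(entropy, expressed, percentile = 0.75) {
  stopifnot(length(entropy) == length(expressed))
  out <- rep(FALSE, length(entropy))
  names(out) <- names(entropy)
  if (!any(expressed)) return(out)
  thr <- stats::quantile(entropy[expressed], percentile, type = 7,
                         names = FALSE)
  out[expressed & entropy < thr] <- TRUE
  if (!any(out)) {
    warning("strict entropy threshold left no testable genes")
  }
  out
}
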