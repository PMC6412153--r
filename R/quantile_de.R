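# Two-level quantile differential-expression testing: Wilcoxon rank-sum at
# the median over full subcohorts and at the upper quartile over each sex's
# upper half, with independent BH control per level, quantile fold-change
# gating, and SSMD effect sizes.

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test of location difference between two samples. Ties
#' receive mid-ranks. For small groups (minimum group size at most
#' `exact_max_n` and at most `max_combinations` distinct group assignments)
#' the permutation null is enumerated exhaustively, which remains exact in
#' the presence of ties; otherwise the tie-corrected normal approximation
#' with continuity correction is used. The statistic is the rank sum of `x`.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact `"auto"` (default), `TRUE` to force enumeration, `FALSE` to
#'   force the normal approximation.
#' @param exact_max_n largest minimum-group-size for which enumeration is
#'   attempted under `"auto"` (default 10).
#' @param max_combinations cap on choose(n, n_x) for enumeration (default 1e5).
#' @return A list with `statistic` (rank sum of `x`), `p.value` (two-sided,
#'   in (0, 1\]) and `method` ("exact" or "normal").
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
rank_sum_test <- function(x, y, exact = "auto", exact_max_n = 10L,
                          max_combinations = 1e5) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  use_exact <- if (identical(exact, "auto")) {
    min(nx, ny) <= exact_max_n && choose(n, min(nx, ny)) <= max_combinations
  } else {
    isTRUE(exact)
  }
  if (use_exact && choose(n, min(nx, ny)) > max_combinations) {
    stop("exact enumeration over ", choose(n, min(nx, ny)),
         " assignments exceeds max_combinations")
  }
  mu <- nx * (n + 1) / 2
  if (use_exact) {
    # enumerate over the smaller group; rank sums convert by symmetry
    small_x <- nx <= ny
    k <- if (small_x) nx else ny
    combos <- utils::combn(n, k)
    wall <- colSums(matrix(r[combos], nrow = k))
    if (!small_x) wall <- sum(r) - wall
    dev <- abs(w - mu)
    p <- mean(abs(wall - mu) >= dev - 1e-8)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = w, p.value = p,
       method = if (use_exact) "exact" else "normal")
}

#' Values at or above a group's own median
#'
#' The conditional subset used by the upper-quartile test: the multiset of a
#' group's values greater than or equal to the group median. Its size is at
#' least ceiling(n/2), and the median of the full group is (approximately)
#' the lower end of the subset, so a rank-sum test on these subsets compares
#' the groups around their 75th percentiles.
#'
#' @param values non-empty numeric vector.
#' @return The values at or above `median(values)`.
#' @export
#' @examples
#' upper_subset(c(1, 2, 3, 4))  # 3 4
#' upper_subset(c(1, 2, 3))     # 2 3
upper_subset <- function(values) {
  if (length(values) == 0L) stop("upper_subset() requires a non-empty input")
  values[values >= stats::median(values)]
}

#' Benjamini-Hochberg adjustment with rejection mask
#'
#' Step-up false-discovery-rate control. Adjusted q-values come from
#' `stats::p.adjust(method = "BH")`; the rejection set \{q <= alpha\}
#' coincides with the classical step-up rule (reject the k smallest
#' p-values where k is the largest index with p_(k) <= k * alpha / m).
#'
#' @param pvalues numeric vector of p-values, all in \[0, 1\].
#' @param alpha FDR threshold (default 0.05).
#' @return A list with `qvalues` and logical `reject`.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = q, reject = q <= alpha)
}

#' Quantile fold change between the sexes
#'
#' Ratio of the two groups' level-quantiles, oriented so the fold is at
#' least 1, with a small pseudo-quantity added to both quantiles so that
#' zero quantiles (e.g. Y-linked genes in females) yield a large but finite
#' fold. Direction names the higher group; equal quantiles give fold 1 and
#' direction "tie".
#'
#' @param female,male numeric TPM vectors for the two groups.
#' @param level quantile level: 50 (median) or 75 (upper quartile).
#' @param pseudo pseudo-quantity added to both quantiles (default 0.001).
#' @return A list with `fold` (>= 1) and `direction` in
#'   \{"female_up", "male_up", "tie"\}.
#' @export
#' @examples
#' quantile_fold(female = c(2, 2, 2), male = c(3, 3, 3), level = 50)
quantile_fold <- function(female, male, level = c(50, 75), pseudo = 0.001) {
  level <- match.arg(as.character(level[1L]), c("50", "75"))
  prob <- as.numeric(level) / 100
  stopifnot(length(female) > 0L, length(male) > 0L, pseudo > 0)
  qf <- stats::quantile(female, prob, type = 7, names = FALSE)
  qm <- stats::quantile(male, prob, type = 7, names = FALSE)
  if (qf == qm) {
    list(fold = 1, direction = "tie")
  } else if (qf > qm) {
    list(fold = (qf + pseudo) / (qm + pseudo), direction = "female_up")
  } else {
    list(fold = (qm + pseudo) / (qf + pseudo), direction = "male_up")
  }
}

#' Strictly standardized mean difference (SSMD)
#'
#' Effect size s = (mean(female) - mean(male) + eps) /
#' sqrt(var(female) + var(male) + eps), with sample variances, zero assumed
#' covariance, and a small smoothing factor eps added to both numerator and
#' denominator. Positive values indicate higher female means. Robust to
#' constant groups: with both variances 0 and equal means, s = eps/sqrt(eps).
#'
#' @param female,male numeric vectors, each of length >= 2.
#' @param epsilon smoothing factor (default 0.001).
#' @return The SSMD, a finite scalar.
#' @export
#' @examples
#' # means 3 vs 1, unit variances: (2 + 0.001)/sqrt(2.001)
#' ssmd(c(2, 3, 4), c(0, 1, 2))
ssmd <- function(female, male, epsilon = 0.001) {
  if (length(female) < 2L || length(male) < 2L) {
    stop("ssmd() requires at least 2 values per group")
  }
  stopifnot(epsilon > 0)
  (mean(female) - mean(male) + epsilon) /
    sqrt(stats::var(female) + stats::var(male) + epsilon)
}

#' Configuration for the two-level DE test
#'
#' @param alpha per-level BH FDR threshold, in (0, 1) (default 0.05).
#' @param fold_threshold minimum quantile fold change for a call (>= 1,
#'   default 1.2).
#' @param epsilon SSMD smoothing factor (default 0.001).
#' @param fold_pseudo pseudo-quantity in fold computation (default 0.001).
#' @param fold_gate `"own"` (default) gates each level on the fold at its
#'   own quantile; `"median"` gates both levels on the median fold.
#' @return A validated list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, fold_threshold = 1.2, epsilon = 0.001,
                      fold_pseudo = 0.001, fold_gate = c("own", "median")) {
  fold_gate <- match.arg(fold_gate)
  stopifnot(alpha > 0, alpha < 1, fold_threshold >= 1, epsilon > 0,
            fold_pseudo > 0)
  structure(list(alpha = alpha, fold_threshold = fold_threshold,
                 epsilon = epsilon, fold_pseudo = fold_pseudo,
                 fold_gate = fold_gate),
            class = "de_config")
}

# Lean internal rank-sum p-value used in the per-gene loop; identical to the
# normal path of rank_sum_test() but without argument handling overhead.
.ranksum_normal_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  lens <- rle(sort(r))$lengths
  tie_term <- sum(lens^3 - lens) / (n * (n - 1))
  sigma2 <- nx * (n - nx) / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-level quantile differential-expression test
#'
#' For every gene, tests for a sex difference at two quantile levels of the
#' TPM distribution. The median-level (50th percentile) test is a Wilcoxon
#' rank-sum comparison of the full female and male subcohorts. The
#' upper-quartile (75th percentile) test compares only the values at or
#' above each sex's own median ([upper_subset()]), making it sensitive to
#' expression shifts carried by a subset of donors of one sex. The two
#' p-value vectors are adjusted separately by Benjamini-Hochberg across all
#' tested genes. A gene is called at the median level when its level-50
#' q-value passes `alpha` and its median fold change passes
#' `fold_threshold`; genes not called at the median level are additionally
#' called at the upper-quartile level under the same rule applied to the
#' level-75 quantities, so the two call sets partition the discoveries.
#' SSMD effect sizes over the full subcohorts are reported for every gene.
#'
#' @param mat expression matrix restricted to testable genes (rows) with
#'   samples as columns.
#' @param sex character/factor vector aligned to the columns, with values
#'   "male"/"female"; both sexes need at least 2 samples.
#' @param config a [de_config()] list.
#' @return A data.frame with one row per gene: `gene_id`, `p50`, `q50`,
#'   `fc50`, `dir50`, `n_used_50`, `p75`, `q75`, `fc75`, `dir75`,
#'   `n_used_75`, `ssmd`, `call` in \{none, male_50, female_50, male_75,
#'   female_75\}, and `direction_conflict` (TRUE when the raw level-50 and
#'   level-75 directions disagree).
#' @export
run_de <- function(mat, sex, config = de_config()) {
  validate_expression(mat)
  stopifnot(inherits(config, "de_config") || is.list(config))
  sex <- as.character(sex)
  if (length(sex) != ncol(mat)) {
    stop("'sex' must have one entry per sample column")
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("'sex' values must be 'male' or 'female'")
  }
  f_idx <- which(sex == "female")
  m_idx <- which(sex == "male")
  if (length(f_idx) < 2L || length(m_idx) < 2L) {
    stop("need at least 2 samples of each sex")
  }
  g <- nrow(mat)
  p50 <- p75 <- fc50 <- fc75 <- s <- numeric(g)
  dir50 <- dir75 <- character(g)
  n50 <- n75 <- integer(g)
  for (i in seq_len(g)) {
    f <- mat[i, f_idx]
    m <- mat[i, m_idx]
    p50[i] <- .ranksum_normal_p(f, m)
    q_f50 <- quantile_fold(f, m, 50, config$fold_pseudo)
    fc50[i] <- q_f50$fold
    dir50[i] <- q_f50$direction
    n50[i] <- length(f) + length(m)
    f_up <- upper_subset(f)
    m_up <- upper_subset(m)
    p75[i] <- .ranksum_normal_p(f_up, m_up)
    q_f75 <- quantile_fold(f, m, 75, config$fold_pseudo)
    fc75[i] <- q_f75$fold
    dir75[i] <- q_f75$direction
    n75[i] <- length(f_up) + length(m_up)
    s[i] <- ssmd(f, m, config$epsilon)
  }
  adj50 <- bh_adjust(p50, config$alpha)
  adj75 <- bh_adjust(p75, config$alpha)
  gate50 <- fc50
  gate75 <- if (config$fold_gate == "own") fc75 else fc50
  call <- rep("none", g)
  called50 <- adj50$reject & gate50 >= config$fold_threshold & dir50 != "tie"
  call[called50] <- paste0(sub("_up$", "", dir50[called50]), "_50")
  called75 <- !called50 & adj75$reject &
    gate75 >= config$fold_threshold & dir75 != "tie"
  call[called75] <- paste0(sub("_up$", "", dir75[called75]), "_75")
  conflict <- dir50 != "tie" & dir75 != "tie" & dir50 != dir75
  data.frame(gene_id = rownames(mat),
             p50 = p50, q50 = adj50$qvalues, fc50 = fc50, dir50 = dir50,
             n_used_50 = n50,
             p75 = p75, q75 = adj75$qvalues, fc75 = fc75, dir75 = dir75,
             n_used_75 = n75,
             ssmd = s, call = call,
             direction_conflict = conflict,
             stringsAsFactors = FALSE)
}
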