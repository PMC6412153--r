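# Synthetic two-sex cohort generator with per-gene ground truth. Emulates the
# statistical structure the downstream analysis assumes (log-scale
# multiplicative noise on a long-tailed baseline, whole-population and
# subset-restricted sex effects, Y-linked and X-escape genes, age trends),
# so every pipeline stage is testable without controlled-access donor data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the baseline (BSL) cohort structure of a large bulk
#' peripheral-nerve donor collection: 168 male and 80 female donors with
#' ages drawn from Normal(51, 13) truncated to 21-70 years. Gene classes:
#' \describe{
#'   \item{median_DE}{a whole-population sex effect: one sex's values are
#'     multiplied by `fold_median`.}
#'   \item{subset_DE}{a sex effect present in only a fraction `pi_subset`
#'     of one sex's donors (multiplied by `fold_subset`), which shifts the
#'     upper quartile while leaving the median nearly unchanged when
#'     `pi_subset` <= 0.5.}
#'   \item{y_linked}{expression exactly zero in females.}
#'   \item{x_escape}{modest female bias (`fold_x_escape`), as for genes
#'     escaping X inactivation.}
#'   \item{age_corr}{log-abundance linear in donor age with per-sex slopes
#'     (`slope_female`, `slope_male`, per year on the natural-log scale).}
#'   \item{null}{no systematic effect.}
#' }
#'
#' @param n_male,n_female donor counts (defaults 168 and 80).
#' @param n_genes total number of genes, including `n_noncoding` non-coding
#'   genes (default 2000).
#' @param frac_median_de fraction of genes with a whole-population sex
#'   effect (default 0.05).
#' @param fold_median fold of the median-level effect (default 2).
#' @param frac_subset_de fraction of genes with a subset-restricted effect
#'   (default 0.02).
#' @param fold_subset fold of the subset effect (default 2).
#' @param pi_subset fraction of one sex's donors carrying the subset effect,
#'   in (0, 1\] (default 0.4).
#' @param n_y_linked,n_x_escape counts of Y-linked and X-escape genes
#'   (defaults 10 each).
#' @param fold_x_escape female-up fold for X-escape genes (default 1.3).
#' @param n_age_corr count of age-correlated genes (default 20).
#' @param slope_female,slope_male per-year slope of natural-log abundance
#'   (defaults -0.02 and 0: a decline in females, flat in males).
#' @param sigma_noise standard deviation of the log-scale multiplicative
#'   noise (default 0.5).
#' @param age_mean,age_sd,age_range donor age distribution parameters
#'   (defaults 51, 13, c(21, 70)).
#' @param baseline_log_mean,baseline_log_sd parameters of the log-normal
#'   baseline abundance distribution (defaults 1 and 1): long-tailed on the
#'   positive TPM scale while keeping any single gene's share of the total
#'   coding mass realistic for bulk tissue, so renormalization is not
#'   dominated by individual genes.
#' @param n_noncoding number of additional non-coding (null-class) genes
#'   among `n_genes` (default 0).
#' @param frac_cjp,frac_t2d fractions of donors flagged with arthritis or
#'   Type II diabetes in the metadata (no expression effect; defaults 0).
#' @param seed integer seed governing all draws through one stream.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_male = 168L, n_female = 80L,
                              n_genes = 2000L,
                              frac_median_de = 0.05, fold_median = 2,
                              frac_subset_de = 0.02, fold_subset = 2,
                              pi_subset = 0.4,
                              n_y_linked = 10L, n_x_escape = 10L,
                              fold_x_escape = 1.3,
                              n_age_corr = 20L,
                              slope_female = -0.02, slope_male = 0,
                              sigma_noise = 0.5,
                              age_mean = 51, age_sd = 13,
                              age_range = c(21, 70),
                              baseline_log_mean = 1, baseline_log_sd = 1,
                              n_noncoding = 0L,
                              frac_cjp = 0, frac_t2d = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_male >= 1, n_female >= 1, n_genes >= 1,
    frac_median_de >= 0, frac_median_de <= 1,
    frac_subset_de >= 0, frac_subset_de <= 1,
    frac_median_de + frac_subset_de <= 1,
    fold_median >= 1, fold_subset >= 1, fold_x_escape >= 1,
    pi_subset > 0, pi_subset <= 1,
    n_y_linked >= 0, n_x_escape >= 0, n_age_corr >= 0, n_noncoding >= 0,
    sigma_noise >= 0, age_sd > 0,
    length(age_range) == 2, age_range[1] < age_range[2],
    frac_cjp >= 0, frac_cjp <= 1, frac_t2d >= 0, frac_t2d <= 1,
    frac_cjp + frac_t2d <= 1
  )
  n_special <- round(frac_median_de * n_genes) +
    round(frac_subset_de * n_genes) +
    n_y_linked + n_x_escape + n_age_corr + n_noncoding
  if (n_special > n_genes) {
    stop("infeasible configuration: ", n_special,
         " special genes exceed n_genes = ", n_genes)
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic two-sex cohort with ground truth
#'
#' Draws a gene-by-sample TPM matrix, donor metadata, gene annotation and a
#' per-gene truth table under the model described in
#' [simulation_config()]. Each value is
#' baseline_i x effect_ij x exp(Normal(0, sigma_noise)), with the baseline
#' drawn once per gene from a log-normal distribution and effects determined
#' by the gene's class. After effects, coding-gene TPMs are renormalized to
#' sum to one million per sample. The same seed always reproduces the same
#' outputs bit for bit.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `dimorph_sim` with elements:
#'   \describe{
#'     \item{expression}{TPM matrix (coding genes renormalized; non-coding
#'       rows, if any, left on the raw scale).}
#'     \item{metadata}{donor table with GTEx-style columns.}
#'     \item{annotation}{gene_id/symbol/chromosome/is_coding table
#'       (Y-linked genes on "Y", X-escape genes on "X").}
#'     \item{truth}{gene_id, class, direction, fold, pi, slope_female,
#'       slope_male.}
#'   }
#' @export
#' @examples
#' sim <- generate_cohort(simulation_config(n_genes = 50, n_male = 10,
#'                                          n_female = 8, seed = 7))
#' table(sim$truth$class)
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_male + config$n_female
  g <- config$n_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(g))
  sex <- c(rep("male", config$n_male), rep("female", config$n_female))

  # donor ages: truncated normal, rounded to whole years
  age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])

  # gene classes, assigned in random order across the gene panel
  n_med <- round(config$frac_median_de * g)
  n_sub <- round(config$frac_subset_de * g)
  classes <- rep("null", g)
  special <- c(rep("median_DE", n_med), rep("subset_DE", n_sub),
               rep("y_linked", config$n_y_linked),
               rep("x_escape", config$n_x_escape),
               rep("age_corr", config$n_age_corr),
               rep("noncoding", config$n_noncoding))
  slots <- sample.int(g, length(special))
  classes[slots] <- special
  is_coding <- classes != "noncoding"
  classes[classes == "noncoding"] <- "null"

  direction <- rep("none", g)
  direction[classes == "median_DE"] <-
    sample(c("male_up", "female_up"), sum(classes == "median_DE"),
           replace = TRUE)
  direction[classes == "subset_DE"] <-
    sample(c("male_up", "female_up"), sum(classes == "subset_DE"),
           replace = TRUE)
  direction[classes == "y_linked"] <- "male_up"
  direction[classes == "x_escape"] <- "female_up"

  fold <- rep(1, g)
  fold[classes == "median_DE"] <- config$fold_median
  fold[classes == "subset_DE"] <- config$fold_subset
  fold[classes == "x_escape"] <- config$fold_x_escape

  baseline <- exp(stats::rnorm(g, config$baseline_log_mean,
                               config$baseline_log_sd))

  male_cols <- which(sex == "male")
  female_cols <- which(sex == "female")
  log_effect <- matrix(0, nrow = g, ncol = n)
  for (i in which(classes == "median_DE")) {
    cols <- if (direction[i] == "male_up") male_cols else female_cols
    log_effect[i, cols] <- log(fold[i])
  }
  for (i in which(classes == "subset_DE")) {
    cols <- if (direction[i] == "male_up") male_cols else female_cols
    k <- max(1L, round(config$pi_subset * length(cols)))
    carriers <- sample(cols, k)
    log_effect[i, carriers] <- log(fold[i])
  }
  for (i in which(classes == "x_escape")) {
    log_effect[i, female_cols] <- log(fold[i])
  }
  slope <- cbind(female = rep(0, g), male = rep(0, g))
  age_centered <- age - config$age_mean
  for (i in which(classes == "age_corr")) {
    slope[i, "female"] <- config$slope_female
    slope[i, "male"] <- config$slope_male
    per_sample_slope <- ifelse(sex == "male", config$slope_male,
                               config$slope_female)
    log_effect[i, ] <- log_effect[i, ] + per_sample_slope * age_centered
  }

  noise <- matrix(stats::rnorm(g * n, 0, config$sigma_noise), nrow = g)
  values <- baseline * exp(log_effect + noise)
  values[classes == "y_linked", female_cols] <- 0

  dimnames(values) <- list(gene_ids, sample_ids)

  chromosome <- sample(as.character(1:22), g, replace = TRUE)
  chromosome[classes == "y_linked"] <- "Y"
  chromosome[classes == "x_escape"] <- "X"
  annotation <- data.frame(gene_id = gene_ids, symbol = gene_ids,
                           chromosome = chromosome, is_coding = is_coding,
                           stringsAsFactors = FALSE)

  # renormalize coding genes to TPM scale; non-coding rows stay raw
  coding_rows <- which(is_coding)
  totals <- colSums(values[coding_rows, , drop = FALSE])
  if (any(totals <= 0)) stop("degenerate simulation: all-zero coding sample")
  values[coding_rows, ] <- sweep(values[coding_rows, , drop = FALSE], 2L,
                                 1e6 / totals, `*`)

  metadata <- .simulate_metadata(sample_ids, sex, age, config)
  truth <- data.frame(gene_id = gene_ids, class = classes,
                      direction = direction, fold = fold,
                      pi = ifelse(classes == "subset_DE", config$pi_subset,
                                  NA_real_),
                      slope_female = slope[, "female"],
                      slope_male = slope[, "male"],
                      stringsAsFactors = FALSE)

  structure(list(expression = values, metadata = metadata,
                 annotation = annotation, truth = truth,
                 config = config),
            class = "dimorph_sim")
}

# Donor metadata with GTEx-style columns; clinical flags are "no" except the
# optional arthritis / Type II diabetes fractions (disjoint donors, so no
# simulated donor hits the joint exclusion rule).
.simulate_metadata <- function(sample_ids, sex, age, config) {
  n <- length(sample_ids)
  race_levels <- c("White", "African American/Black", "Asian", "Unknown")
  race_probs <- c(0.863, 0.097, 0.024, 0.016)
  male <- sex == "male"
  meta <- data.frame(
    SAMPID = sample_ids,
    SEX = sex,
    AGE = age,
    RACE = sample(race_levels, n, replace = TRUE, prob = race_probs),
    BMI = round(stats::rnorm(n, 27.2, 3.9), 1),
    HGHT = round(ifelse(male, stats::rnorm(n, 69.8, 3.1),
                        stats::rnorm(n, 64.8, 2.8)), 1),
    WGHT = round(ifelse(male, stats::rnorm(n, 188.8, 32.3),
                        stats::rnorm(n, 163.6, 26.8)), 1),
    stringsAsFactors = FALSE
  )
  meta$BMI <- pmin(pmax(meta$BMI, 18.5), 35)
  for (col in .flag_cols) meta[[col]] <- "no"
  meta$LBHIV1NT <- sample(c("negative", "not performed"), n, replace = TRUE,
                          prob = c(0.95, 0.05))
  n_cjp <- round(config$frac_cjp * n)
  n_t2d <- round(config$frac_t2d * n)
  if (n_cjp + n_t2d > 0) {
    flagged <- sample.int(n, n_cjp + n_t2d)
    if (n_cjp > 0) meta$MHARTHTS[flagged[seq_len(n_cjp)]] <- "yes"
    if (n_t2d > 0) meta$MHT2D[flagged[n_cjp + seq_len(n_t2d)]] <- "yes"
  }
  meta
}

#' Permute sex labels for null calibration
#'
#' Returns a copy of the metadata with the SEX column permuted uniformly at
#' random and every other field unchanged. The per-sex counts are preserved,
#' so DE statistics recomputed under the permuted labels estimate the null
#' distribution. A single-sex input is returned unchanged with a warning.
#'
#' @param metadata donor metadata data.frame with a SEX column.
#' @param seed integer seed.
#' @return The metadata with permuted SEX.
#' @export
generate_null_permutation <- function(metadata, seed = 1L) {
  stopifnot("SEX" %in% names(metadata))
  if (length(unique(metadata$SEX)) < 2L) {
    warning("single-sex metadata: returning input unchanged")
    return(metadata)
  }
  set.seed(seed)
  metadata$SEX <- sample(metadata$SEX)
  metadata
}

#' @export
print.dimorph_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  cat("  sexes:", sum(x$metadata$SEX == "male"), "male /",
      sum(x$metadata$SEX == "female"), "female\n")
  cat("  gene classes:\n")
  print(table(x$truth$class))
  invisible(x)
}
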