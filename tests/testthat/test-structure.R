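test_that("PCA satisfies its algebraic invariants", {
  set.seed(20)
  base <- rlnorm(10, 2, 1)
  mat <- matrix(rep(base, 6), nrow = 10) * exp(matrix(rnorm(60, 0, 0.4), 10))
  dimnames(mat) <- list(paste0("G", 1:10), paste0("S", 1:6))
  pca <- pca_samples(mat)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_equal(unname(colSums(pca$loadings^2)),
               rep(1, ncol(pca$loadings)), tolerance = 1e-9)
  # reconstruction from all components recovers the transformed data
  x <- scale(t(log2(mat + 1)), center = TRUE, scale = TRUE)
  rec <- pca$scores %*% t(pca$loadings)
  expect_equal(rec, as.matrix(x), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("two perfectly correlated genes collapse onto one component", {
  g1 <- c(1, 2, 3, 4, 5)
  mat <- rbind(A = g1, B = 2 * g1)
  colnames(mat) <- paste0("S", 1:5)
  pca <- pca_samples(mat, log2_transform = FALSE, standardize = TRUE)
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("component signs follow the largest-loading-positive convention", {
  set.seed(21)
  mat <- matrix(rlnorm(200), nrow = 20,
                dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  pca <- pca_samples(mat)
  for (k in seq_len(ncol(pca$loadings))) {
    j <- which.max(abs(pca$loadings[, k]))
    expect_gt(pca$loadings[j, k], 0)
  }
  # rerunning gives bitwise-identical output (no sign flips)
  expect_identical(pca_samples(mat)$scores, pca$scores)
})

test_that("outlier detection reproduces hand-computed standardized norms", {
  # 5 samples, scores chosen so per-component variances are exact by hand:
  # var(PC1) = (36+1+0+1+36)/4 = 18.5, var(PC2) = (9+9)/4 = 4.5
  scores <- cbind(PC1 = c(6, -1, 0, 1, -6), PC2 = c(0, 3, 0, -3, 0))
  rownames(scores) <- paste0("S", 1:5)
  pca <- structure(list(scores = scores), class = "dimorph_pca")
  out <- detect_outliers(pca, n_components = 2, sd_threshold = 2)
  d_expect <- c(6 / sqrt(18.5), sqrt(1 / 18.5 + 9 / 4.5), 0,
                sqrt(1 / 18.5 + 9 / 4.5), 6 / sqrt(18.5))
  expect_equal(out$samples$distance, d_expect, tolerance = 1e-9)
  expect_identical(out$samples$outlier, d_expect >= 2)
  expect_false(out$samples$outlier[3])   # the origin sample

  # a sample at (1.5 sd, 1.5 sd) has norm ~2.12 and is flagged
  sc2 <- cbind(PC1 = c(1.5, -1, 0.2, -0.7), PC2 = c(1.5, 0.3, -1.1, -0.7))
  sc2 <- rbind(sc2, -colSums(sc2))        # centered
  sds <- apply(sc2, 2, sd)
  sc2 <- sweep(sc2, 2, sds, `/`)          # per-component SD exactly 1
  rownames(sc2) <- paste0("T", 1:5)
  pca2 <- structure(list(scores = sc2), class = "dimorph_pca")
  out2 <- detect_outliers(pca2, sd_threshold = 2)
  expect_identical(out2$samples$outlier,
                   unname(sqrt(rowSums(sc2^2)) >= 2))
})

test_that("outlier fractions are invariant to uniform rescaling of scores", {
  set.seed(22)
  scores <- cbind(PC1 = rnorm(40, 0, 5), PC2 = rnorm(40, 0, 2))
  rownames(scores) <- paste0("S", 1:40)
  cohorts <- setNames(rep(c("BSL", "CJP"), each = 20), rownames(scores))
  p1 <- structure(list(scores = scores), class = "dimorph_pca")
  p2 <- structure(list(scores = scores * 37), class = "dimorph_pca")
  o1 <- detect_outliers(p1, cohorts = cohorts)
  o2 <- detect_outliers(p2, cohorts = cohorts)
  expect_identical(o1$samples$outlier, o2$samples$outlier)
  expect_equal(o1$cohort_fractions, o2$cohort_fractions)
})

test_that("top components separate the sexes on sex-DE-only data", {
  cfg <- simulation_config(n_male = 60L, n_female = 40L, n_genes = 200L,
                           frac_median_de = 0.2, fold_median = 2,
                           frac_subset_de = 0, n_y_linked = 5L,
                           n_x_escape = 5L, n_age_corr = 0L,
                           sigma_noise = 0.5, seed = 23L)
  sim <- generate_cohort(cfg)
  de_genes <- sim$truth$gene_id[sim$truth$class != "null"]
  pca <- pca_samples(sim$expression, genes = de_genes)
  sex <- sim$metadata$SEX
  sc <- pca$scores[, 1:2]
  w <- colMeans(sc[sex == "male", ]) - colMeans(sc[sex == "female", ])
  proj <- sc %*% w
  thr <- (mean(proj[sex == "male"]) + mean(proj[sex == "female"])) / 2
  acc <- mean((proj > thr) == (sex == "male"))
  expect_gte(max(acc, 1 - acc), 0.95)
})

test_that("age-gene correlation recovers designed trends and respects exclusions", {
  set.seed(24)
  n <- 40
  meta <- do.call(rbind, lapply(seq_len(n), function(i) {
    meta_row(paste0("S", i), sex = if (i <= 25) "female" else "male",
             age = sample(25:65, 1))
  }))
  age <- meta$AGE
  mat <- rbind(
    linear = 10 + age,                        # exact age dependence
    flat = rep(5, n),                          # constant: untestable
    noise = rlnorm(n),
    ygene = c(rep(0, 25), rlnorm(15))
  )
  colnames(mat) <- meta$SAMPID
  ann <- data.frame(gene_id = rownames(mat), symbol = rownames(mat),
                    chromosome = c("1", "2", "3", "Y"),
                    is_coding = TRUE)
  fem <- age_correlation_genes(mat, meta, sex = "female", annotation = ann)
  expect_false("ygene" %in% fem$gene_id)     # Y genes not tested in females
  expect_equal(fem$r[fem$gene_id == "linear"], 1, tolerance = 1e-9)
  expect_true(fem$significant[fem$gene_id == "linear"])
  expect_identical(fem$reason[fem$gene_id == "flat"], "constant")
  expect_false(fem$significant[fem$gene_id == "flat"])
  mal <- age_correlation_genes(mat, meta, sex = "male", annotation = ann)
  expect_true("ygene" %in% mal$gene_id)
  expect_error(age_correlation_genes(mat[, 1:2], meta[1:2, ], sex = "male"),
               "at least 3")
})

test_that("sex-specific age slopes are recovered from synthetic cohorts", {
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(n_male = 80L, n_female = 60L, n_genes = 60L,
                             frac_median_de = 0, frac_subset_de = 0,
                             n_y_linked = 0L, n_x_escape = 0L,
                             n_age_corr = 3L, slope_female = -0.03,
                             slope_male = 0, sigma_noise = 0.5,
                             seed = 300L + s)
    sim <- generate_cohort(cfg)
    genes <- sim$truth$gene_id[sim$truth$class == "age_corr"]
    fem <- age_correlation_genes(sim$expression, sim$metadata,
                                 genes = genes, sex = "female",
                                 annotation = sim$annotation)
    mal <- age_correlation_genes(sim$expression, sim$metadata,
                                 genes = genes, sex = "male",
                                 annotation = sim$annotation)
    ok_f <- fem$significant & fem$r < 0
    hits <- hits + sum(ok_f)
    # flat male slope: strong negative male correlations should be rare
    expect_lt(sum(mal$significant & mal$r < -0.5), 3L)
  }
  expect_gte(hits / (3 * n_seeds), 0.8)
})

test_that("component-age correlation is exact for an age component and antisymmetric", {
  set.seed(25)
  n <- 30
  meta <- do.call(rbind, lapply(seq_len(n), function(i) {
    meta_row(paste0("S", i), age = sample(25:65, 1))
  }))
  scores <- cbind(PC1 = scale(meta$AGE)[, 1], PC2 = rnorm(n))
  rownames(scores) <- meta$SAMPID
  pca <- structure(list(scores = scores), class = "dimorph_pca")
  out <- age_correlation_components(pca, meta, n_components = 2)
  expect_equal(out$r[out$component == "PC1"], 1, tolerance = 1e-9)
  flipped <- pca
  flipped$scores[, 1] <- -flipped$scores[, 1]
  out2 <- age_correlation_components(flipped, meta, n_components = 2)
  expect_equal(out2$r[1], -out$r[1], tolerance = 1e-12)
})
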