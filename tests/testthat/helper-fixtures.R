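# Shared fixture builders. Everything is generated in code at test time.

# small 3-gene x 2-sample TPM matrix used by the IO tests
fixture_matrix <- function() {
  matrix(c(1, 0, 2.5, 4, 5, 0), nrow = 3,
         dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
}

write_tsv_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  tab <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gct_fixture <- function(mat, path = tempfile(fileext = ".gct")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  tab <- data.frame(Name = rownames(mat), Description = rownames(mat),
                    mat, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# one metadata row per argument set; defaults are an unremarkable BSL donor
meta_row <- function(id = "D1", sex = "male", age = 50, MHT1D = "no",
                     MHT2D = "no", MHARTHTS = "no", MHRA = "no",
                     MHSEPSIS = "no", LBHIV1NT = "negative") {
  data.frame(SAMPID = id, SEX = sex, AGE = age, RACE = "White",
             BMI = 27, HGHT = 68, WGHT = 170,
             MHT1D = MHT1D, MHT2D = MHT2D, MHARTHTS = MHARTHTS,
             MHRA = MHRA, MHSEPSIS = MHSEPSIS,
             MHLUPUS = "no", MHCLLULTS = "no", MHSCLRDRM = "no",
             MHSRCDSS = "no", LBHIV1NT = LBHIV1NT,
             stringsAsFactors = FALSE)
}

meta_table <- function(...) do.call(rbind, list(...))

# independent exhaustive-permutation oracle for the two-sided rank-sum p:
# enumerates every assignment of the pooled mid-ranks to the first group and
# measures the symmetric deviation of the rank sum from its null mean
ranksum_enumeration_oracle <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  e_w <- nx * (n + 1) / 2
  combos <- utils::combn(seq_len(n), nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-8)
}

# Monte-Carlo permutation oracle (for sizes where enumeration is infeasible)
ranksum_mc_oracle <- function(x, y, n_perm = 20000L) {
  nx <- length(x)
  z <- c(x, y)
  r <- rank(z)
  e_w <- nx * (length(z) + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  w_perm <- replicate(n_perm, sum(r[sample.int(length(z), nx)]))
  mean(abs(w_perm - e_w) >= abs(w_obs - e_w) - 1e-8)
}

# brute-force BH step-up: reject the k* smallest p-values where k* is the
# largest k with p_(k) <= k * alpha / m
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}
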