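# Per-sex Spearman association: rank oracle, the n >= 15 rule, category
# logic, sex-label symmetry and the cluster-association matrix.

# Metadata with n WT mice per sex.
assoc_meta <- function(n_per_sex) {
  validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(2 * n_per_sex)),
    sex = rep(c("F", "M"), each = n_per_sex),
    genotype = "WT", zygosity = "wt", role = "study", batch = "B1"))
}

test_that("spearman_test matches rank-then-Pearson with ties", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(12:40, 1)
    x <- sample(round(rnorm(n), 1))      # rounded -> frequent ties
    y <- round(rnorm(n), 1)
    st <- spearman_test(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(st$rho, oracle, tolerance = 1e-12)
    expect_equal(st$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # monotone identity
  x <- 1:20
  st <- spearman_test(x, x^3)
  expect_equal(st$rho, 1)
  expect_lt(st$p, 1e-10)
  # exact permutation p for small n agrees with cor.test's exact p (no ties)
  set.seed(52)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    st <- spearman_test(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(st$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("pairs below 15 points per sex are skipped, others categorized", {
  set.seed(53)
  meta <- assoc_meta(16)
  x <- rlnorm(32, 8, 0.4)
  tbl <- make_table(matrix(x, 32, 1), samples = meta$sample_id)
  ph <- matrix(rnorm(32 * 2), 32, 2,
               dimnames = list(meta$sample_id, c("P1", "P2")))
  ph[1:2, 2] <- NA                       # 14 female points for P2
  res <- spearman_by_sex(tbl, ph, meta, min_n = 15)
  expect_equal(nrow(res), 1)
  expect_equal(res$phenotype_id, "P1")
  sk <- attr(res, "skipped")
  expect_equal(sk$phenotype_id, "P2")
  expect_equal(sk$reason, "insufficient-n")
  expect_gte(res$n_F, 15)
  # constant metabolite -> skipped with reason
  tbl2 <- make_table(matrix(5, 32, 1), samples = meta$sample_id)
  res2 <- spearman_by_sex(tbl2, ph[, 1, drop = FALSE], meta)
  expect_equal(nrow(res2), 0)
  expect_equal(attr(res2, "skipped")$reason, "constant-variable")
})

test_that("opposite significant correlations in the sexes are categorized", {
  set.seed(54)
  meta <- assoc_meta(20)
  z <- rnorm(40)
  y <- ifelse(meta$sex == "F", -z, z) + rnorm(40, 0, 0.3)
  tbl <- make_table(matrix(exp(z + 8), 40, 1), samples = meta$sample_id)
  ph <- matrix(y, 40, 1, dimnames = list(meta$sample_id, "P1"))
  res <- spearman_by_sex(tbl, ph, meta)
  expect_lt(res$rho_F, -0.5)
  expect_gt(res$rho_M, 0.5)
  expect_equal(res$category, "both-opposite-direction")
})

test_that("swapping sex labels mirrors results exactly", {
  coh <- small_cohort(seed = 55, n_wt_per_sex = 16)
  qc <- compute_qc_stats(coh$abundance, coh$meta)
  tbl <- impute_half_min(filter_features(coh$abundance, qc,
                                         annotation = coh$annotation)$table,
                         coh$meta)
  ph <- impute_phenotype_min(coh$phenotypes, coh$meta)$pheno
  res <- spearman_by_sex(tbl, ph, coh$meta)
  meta_sw <- coh$meta
  meta_sw$sex <- c(F = "M", M = "F")[meta_sw$sex]
  res_sw <- spearman_by_sex(tbl, ph, meta_sw)
  expect_equal(res_sw$rho_F, res$rho_M)
  expect_equal(res_sw$p_M, res$p_F)
  map <- c("female-only" = "male-only", "male-only" = "female-only",
           "both-same-direction" = "both-same-direction",
           "both-opposite-direction" = "both-opposite-direction",
           "ns" = "ns")
  expect_equal(res_sw$category, unname(map[res$category]))
})

test_that("category counts partition the significant correlations", {
  coh <- small_cohort(seed = 56, n_wt_per_sex = 16)
  qc <- compute_qc_stats(coh$abundance, coh$meta)
  tbl <- impute_half_min(filter_features(coh$abundance, qc,
                                         annotation = coh$annotation)$table,
                         coh$meta)
  ph <- impute_phenotype_min(coh$phenotypes, coh$meta)$pheno
  res <- spearman_by_sex(tbl, ph, coh$meta)
  s <- categorize_summary(res)
  expect_equal(s$n_female_only + s$n_male_only + s$n_both_same +
                 s$n_both_opposite, s$n_significant)
  expect_equal(s$n_tested, nrow(res))
  # sex-specific drivers dominate the both-* categories in this generator
  expect_gt(s$n_female_only + s$n_male_only, s$n_both_same + s$n_both_opposite)
  # empty input
  res0 <- res[0, ]
  s0 <- categorize_summary(res0)
  expect_equal(s0$n_significant, 0)
  expect_equal(s0$pct_significant, 0)
})

test_that("cluster-phenotype matrix has the contracted shape and direction", {
  set.seed(57)
  meta <- assoc_meta(20)
  n <- 40
  # 12 features in 2 clusters; cluster c1 drives P1 in males only
  z <- rnorm(n)
  vals <- sapply(1:12, function(j) exp(rnorm(n, 8, 0.2)))
  male <- meta$sex == "M"
  for (j in 1:6) vals[male, j] <- exp(z[male] * 0.9 + rnorm(sum(male), 0, 0.2))
  tbl <- make_table(vals, samples = meta$sample_id)
  ph <- matrix(c(z, rnorm(n)), n, 2,
               dimnames = list(meta$sample_id, c("P1", "P2")))
  clusters <- setNames(rep(c("c1", "c2"), each = 6),
                       sprintf("F%03d", 1:12))
  res <- spearman_by_sex(tbl, ph, meta)
  hm <- cluster_phenotype_matrix(res, clusters)
  expect_equal(nrow(hm), 2 * 2 * 2)      # phenotypes x clusters x sexes
  cell_m <- hm[hm$phenotype_id == "P1" & hm$cluster == "c1" & hm$sex == "M", ]
  cell_f <- hm[hm$phenotype_id == "P1" & hm$cluster == "c1" & hm$sex == "F", ]
  expect_lt(cell_m$ks_p, 0.05)
  expect_gt(cell_m$signed_score, 0)      # positive correlations in males
  expect_gt(cell_f$ks_p, 0.05)
})
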