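# Nested F tests, dimorphism classification, standardized fold-changes and
# KO summaries.

ko_design <- function(n_ko = 3, n_wt = 20) {
  data.frame(
    geno = factor(rep(c("KO", "WT"), c(2 * n_ko, 2 * n_wt)),
                  levels = c("WT", "KO")),
    sex = factor(c(rep(c("F", "M"), each = n_ko),
                   rep(c("F", "M"), each = n_wt))))
}

test_that("nested F test is exact on degenerate and shifted inputs", {
  dat <- ko_design(3, 3)
  # identical values in every genotype-sex cell: F = 0, p = 1
  y <- rep(c(1, 2), 6)
  p <- nested_f_test(y, dat, ~ geno * sex, ~ sex)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "statistic"), 0)
  # location invariance
  set.seed(21)
  y2 <- rlnorm(12, 5, 0.4)
  p_a <- nested_f_test(y2, dat, ~ geno * sex, ~ geno + sex)
  p_b <- nested_f_test(y2 + 137.5, dat, ~ geno * sex, ~ geno + sex)
  expect_equal(as.numeric(p_a), as.numeric(p_b), tolerance = 1e-9)
  expect_error(nested_f_test(y2, dat, ~ sex, ~ geno * sex), "nested")
})

test_that("nested F equals the anova() oracle on random small designs", {
  set.seed(22)
  for (i in 1:100) {
    dat <- ko_design(sample(2:4, 1), sample(4:8, 1))
    y <- rlnorm(nrow(dat), 6, 0.6)
    for (null in list(~ sex, ~ geno + sex)) {
      p <- nested_f_test(y, dat, ~ geno * sex, null)
      full <- lm(y ~ geno * sex, dat)
      red <- lm(stats::update(null, y ~ .), dat)
      oracle <- anova(red, full)$`Pr(>F)`[2]
      expect_equal(as.numeric(p), oracle, tolerance = 1e-10)
    }
  }
})

test_that("interaction p equals the classical two-way ANOVA table", {
  set.seed(23)
  dat <- data.frame(geno = factor(rep(c("WT", "KO"), each = 10)),
                    sex = factor(rep(c("F", "M"), 10)))
  y <- rlnorm(20, 5, 0.5)
  p <- nested_f_test(y, dat, ~ geno * sex, ~ geno + sex)
  tab <- summary(aov(y ~ geno * sex, dat))[[1]]
  expect_equal(as.numeric(p), tab["geno:sex", "Pr(>F)"], tolerance = 1e-10)
})

test_that("classification follows the decision tree and partitions all pairs", {
  expect_equal(classify_dimorphism(0.01, 0.30, 0.5, 0.5, 1, 1),
               "genotype-no-sex-difference")
  expect_equal(classify_dimorphism(0.01, 0.01, 0.01, 0.60, -1, 1),
               "female-only")
  expect_equal(classify_dimorphism(0.01, 0.01, 0.60, 0.01, -1, 1),
               "male-only")
  expect_equal(classify_dimorphism(0.01, 0.01, 0.01, 0.01, 1, -1),
               "opposite-direction")
  expect_equal(classify_dimorphism(0.01, 0.01, 0.01, 0.01, -1, -1),
               "different-effect-size")
  expect_equal(classify_dimorphism(0.20, 0.01, 0.60, 0.60, 1, 1),
               "interaction-only")
  expect_equal(classify_dimorphism(0.20, 0.30, 0.01, 0.01, 1, 1), "ns")
  # gate on the genotype test when requested
  expect_equal(classify_dimorphism(0.20, 0.01, 0.01, 0.60, 1, 1,
                                   gate_genotype = TRUE), "ns")
  # property: total function, ns exactly when both gates fail
  set.seed(24)
  pg <- runif(500); pi_ <- runif(500); pf <- runif(500); pm <- runif(500)
  sf <- sample(c(-1, 1), 500, TRUE); sm <- sample(c(-1, 1), 500, TRUE)
  cat_ <- classify_dimorphism(pg, pi_, pf, pm, sf, sm)
  expect_true(all(cat_ %in% metadimorph:::KO_CATEGORIES))
  expect_identical(cat_ == "ns", pg >= 0.05 & pi_ >= 0.05)
})

test_that("planted archetypes drive the expected categories", {
  # both-sexes-equal with large effects -> mostly genotype-no-sex-difference
  coh <- planted_cohort(c("both-sexes-equal" = 1), effect = 2,
                        n_features = 200, seed = 31)
  res <- test_line(coh$abundance, coh$meta, "Ko01")
  expect_gt(mean(res$category == "genotype-no-sex-difference"), 0.5)
  # null config -> ns at roughly 1 - alpha
  coh0 <- simulate_cohort(sim_config(
    n_ko_lines = 1, n_features = 400, ko_affected_frac = 0,
    sex_affected_frac = 0, missing_rate = 0, low_detect_frac = 0,
    high_rsd_frac = 0, istd_frac = 0, n_phenotypes = 0, n_qc = 4,
    n_blank = 0, seed = 32))
  res0 <- test_line(coh0$abundance, coh0$meta, "Ko01")
  expect_gt(mean(res0$category == "ns"), 0.85)
  expect_lt(mean(res0$category == "ns"), 0.97)
  # opposite-direction +-2 log2 recovered in more than half the features
  coh2 <- planted_cohort(c("opposite-direction" = 1), effect = 2,
                         n_features = 200, seed = 33)
  res2 <- test_line(coh2$abundance, coh2$meta, "Ko01")
  expect_gt(mean(res2$category == "opposite-direction"), 0.5)
})

test_that("a missing genotype-sex cell is flagged and skipped", {
  coh <- planted_cohort(c("both-sexes-equal" = 1), effect = 1,
                        n_features = 10, seed = 34)
  meta <- coh$meta
  drop <- meta$sample_id[meta$genotype == "Ko01" & meta$sex == "M"]
  tbl <- subset_abundance(coh$abundance,
                          samples = setdiff(rownames(coh$abundance$values),
                                            drop))
  meta <- meta[!meta$sample_id %in% drop, ]
  expect_warning(res <- test_line(tbl, meta, "Ko01"), "rank-deficient")
  expect_equal(nrow(res), 0)
})

test_that("standardized fold-change matches its definition and the bootstrap", {
  meta <- validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%d", 1:12),
    sex = rep(c("F", "M"), 6),
    genotype = rep(c("Ko1", "WT"), each = 6),
    zygosity = "wt", role = "study", batch = "B1"))
  v <- matrix(1, 12, 1)
  v[meta$genotype == "Ko1", 1] <- 3      # KO mean 3, WT mean 1
  tbl <- make_table(v, samples = meta$sample_id)
  fc <- standardized_fold_change(tbl, meta, "Ko1", "F001")
  expect_equal(fc$standardized_fc, c(3, 3))
  v2 <- v; v2[meta$genotype == "Ko1", 1] <- v[meta$genotype == "Ko1", 1] / 3
  fc2 <- standardized_fold_change(make_table(v2, samples = meta$sample_id),
                                  meta, "Ko1", "F001")
  expect_equal(fc2$standardized_fc, c(1, 1))
  # delta-method spread vs 500-resample bootstrap, within 20%
  set.seed(35)
  ko <- rlnorm(15, 10.5, 0.4); wt <- rlnorm(20, 10, 0.4)
  meta2 <- validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%d", 1:35),
    sex = "F", genotype = rep(c("Ko1", "WT"), c(15, 20)),
    zygosity = "wt", role = "study", batch = "B1"))
  meta2$sex[c(1, 16)] <- "M"             # keep both sexes represented
  tbl2 <- make_table(matrix(c(ko, wt), 35, 1), samples = meta2$sample_id)
  fc3 <- standardized_fold_change(tbl2, meta2, "Ko1", "F001")
  kof <- ko[-1]; wtf <- wt[-1]
  boot <- replicate(500, mean(sample(kof, replace = TRUE)) /
                      mean(sample(wtf, replace = TRUE)))
  prop <- fc3$spread[fc3$sex == "F"]
  expect_lt(abs(prop - sd(boot)) / sd(boot), 0.2)
})

test_that("KO summary fractions partition the significant pairs", {
  coh <- small_cohort(seed = 36)
  qc <- compute_qc_stats(coh$abundance, coh$meta)
  tbl <- impute_half_min(filter_features(coh$abundance, qc,
                                         annotation = coh$annotation)$table,
                         coh$meta)
  res <- test_all_lines(tbl, coh$meta)
  s <- summarize_ko(res)
  fr <- unlist(s$global[grep("^frac_", names(s$global))])
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(s$global$n_significant, sum(res$category != "ns"))
  # all-ns input
  res_ns <- res; res_ns$category <- "ns"
  s0 <- summarize_ko(res_ns)
  expect_equal(s0$global$pct_significant, 0)
  expect_equal(s0$global$pct_dimorphic_among_significant, 0)
})
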