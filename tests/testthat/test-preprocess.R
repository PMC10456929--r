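# QC statistics, strict filter boundaries, imputation rules and batch
# median normalization.

qc_meta <- function(n_study, n_qc) {
  validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_study + n_qc)),
    sex = c(rep(c("F", "M"), length.out = n_study), rep(NA, n_qc)),
    genotype = c(rep("WT", n_study), rep(NA, n_qc)),
    zygosity = "wt",
    role = c(rep("study", n_study), rep("QC", n_qc)),
    batch = "B1"))
}

test_that("QC statistics follow the sample-sd RSD and study-row conventions", {
  meta <- qc_meta(10, 3)
  v <- matrix(5, 13, 2)
  v[11:13, 1] <- c(10, 10, 10)           # QC rows of feature 1
  v[11:13, 2] <- c(1, 3, NA)             # two QC values for feature 2
  v[1:7, 2] <- NA                        # missing in 7 of 10 study rows
  tbl <- make_table(v, samples = meta$sample_id)
  qc <- compute_qc_stats(tbl, meta)
  expect_equal(qc$rsd_qc[1], 0)
  expect_equal(qc$rsd_qc[2], sd(c(1, 3)) / mean(c(1, 3)) * 100)  # 70.71%
  expect_equal(qc$rsd_qc[2], 70.71068, tolerance = 1e-6)
  expect_equal(qc$missing_fraction[2], 0.7)
  expect_equal(qc$prevalence[2], 0.3)
})

test_that("filter boundaries are strict exactly as documented", {
  qc <- tibble::tibble(
    feature_id = c("F001", "F002", "F003", "F004"),
    rsd_qc = c(50.0, 50.0001, 10, 10),
    missing_fraction = c(0, 0, 0.70, 0.699),
    prevalence = c(1, 1, 0.30, 0.301))
  tbl <- make_table(matrix(1, 2, 4), samples = c("a", "b"))
  meta <- validate_sample_meta(tibble::tibble(
    sample_id = c("a", "b"), sex = c("F", "M"), genotype = "WT",
    zygosity = "wt", role = "study", batch = "B1"))
  out <- filter_features(tbl, qc)
  # RSD exactly 50 retained; RSD just above removed
  expect_true("F001" %in% colnames(out$table$values))
  expect_false("F002" %in% colnames(out$table$values))
  # missing fraction exactly 0.70 removed ("at least 70%")
  expect_false("F003" %in% colnames(out$table$values))
  # prevalence 0.301 (> 0.30 strictly) retained
  expect_true("F004" %in% colnames(out$table$values))
  expect_setequal(out$log$feature_id, c("F002", "F003"))
})

test_that("filtering is order-independent", {
  set.seed(2)
  for (rep in 1:5) {
    qc <- tibble::tibble(
      feature_id = sprintf("F%03d", 1:40),
      rsd_qc = runif(40, 0, 100),
      missing_fraction = runif(40),
      prevalence = NA)
    qc$prevalence <- 1 - qc$missing_fraction
    tbl <- make_table(matrix(1, 2, 40), samples = c("a", "b"))
    # disable two rules at a time, apply singly in every order
    single <- list(
      rsd  = function(t) filter_features(t, qc, rsd_max = 50,
                                         missing_max = 1.1,
                                         prevalence_min = -0.1)$table,
      mis  = function(t) filter_features(t, qc, rsd_max = Inf,
                                         missing_max = 0.70,
                                         prevalence_min = -0.1)$table,
      prev = function(t) filter_features(t, qc, rsd_max = Inf,
                                         missing_max = 1.1,
                                         prevalence_min = 0.30)$table)
    joint <- colnames(filter_features(tbl, qc)$table$values)
    for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))) {
      t2 <- tbl
      for (k in ord) t2 <- single[[k]](t2)
      expect_setequal(colnames(t2$values), joint)
    }
  }
})

test_that("half-minimum imputation is group-wise and total", {
  meta <- validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%d", 1:6),
    sex = rep(c("F", "M"), 3),
    genotype = rep(c("WT", "Ko1"), each = 3),
    zygosity = "wt", role = "study", batch = "B1"))
  v <- matrix(c(2, 4, NA, 8, NA, 16), 6, 1)
  tbl <- make_table(v, samples = meta$sample_id)
  out <- impute_half_min(tbl, meta)
  expect_equal(out$values[3, 1], 1.0)    # WT group: half of min(2, 4)
  expect_equal(out$values[5, 1], 4.0)    # Ko1 group: half of min(8, 16)
  expect_false(anyNA(out$values))
  # non-missing cells never change
  obs <- !is.na(tbl$values)
  expect_identical(out$values[obs], tbl$values[obs])
  # feature observed nowhere -> error
  tbl2 <- make_table(matrix(NA_real_, 6, 1), samples = meta$sample_id)
  expect_error(impute_half_min(tbl2, meta), "no observed")
})

test_that("phenotype imputation drops sparse phenotypes and uses group minima", {
  meta <- validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%d", 1:20),
    sex = rep(c("F", "M"), each = 10),
    genotype = rep(c("WT", "Ko1"), 10),
    zygosity = "wt", role = "study", batch = "B1"))
  ph <- matrix(rnorm(20 * 3, 10), 20, 3,
               dimnames = list(meta$sample_id, c("P1", "P2", "P3")))
  ph[1:8, 1] <- NA                       # 8/10 females missing -> drop
  ph[2, 2] <- NA                         # impute with genotype-group min
  out <- impute_phenotype_min(ph, meta)
  expect_equal(out$dropped, "P1")
  expect_equal(colnames(out$pheno), c("P2", "P3"))
  ko_rows <- meta$sample_id[meta$genotype == "Ko1"]
  expect_equal(out$pheno["S2", "P2"],
               min(ph[setdiff(ko_rows, "S2"), "P2"], na.rm = TRUE))
  # all-observed table is unchanged
  expect_identical(impute_phenotype_min(ph[, 3, drop = FALSE], meta)$pheno,
                   ph[, 3, drop = FALSE])
})

batch_meta <- function(n, batches) {
  validate_sample_meta(tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    genotype = "WT", zygosity = "wt", role = "study", batch = batches))
}

test_that("median batch normalization equalizes per-feature batch medians", {
  set.seed(6)
  # single batch -> identity
  meta1 <- batch_meta(8, "B1")
  t1 <- make_table(matrix(rlnorm(8 * 5, 8), 8, 5), platform = "HILIC",
                   samples = meta1$sample_id)
  expect_equal(median_batch_normalize(t1, meta1)$values, t1$values)
  # batch B doubled feature-wise -> equal medians afterwards
  meta2 <- batch_meta(12, rep(c("B1", "B2"), each = 6))
  base <- matrix(rlnorm(6 * 4, 8, 0.3), 6, 4)
  t2 <- make_table(rbind(base, 2 * base), platform = "HILIC",
                   samples = meta2$sample_id)
  out <- median_batch_normalize(t2, meta2)
  m1 <- apply(out$values[1:6, ], 2, median)
  m2 <- apply(out$values[7:12, ], 2, median)
  expect_equal(m1, m2, tolerance = 1e-12)
  # random two-batch data -> batch-median ratio within 1%
  t3 <- make_table(matrix(rlnorm(12 * 20, 8, 0.5), 12, 20),
                   platform = "HILIC", samples = meta2$sample_id)
  out3 <- median_batch_normalize(t3, meta2)
  r <- apply(out3$values[1:6, ], 2, median) /
    apply(out3$values[7:12, ], 2, median)
  expect_true(all(r >= 0.99 & r <= 1.01))
  # scale equivariance
  t4 <- make_table(3.7 * t3$values, platform = "HILIC",
                   samples = meta2$sample_id)
  expect_equal(median_batch_normalize(t4, meta2)$values, 3.7 * out3$values,
               tolerance = 1e-12)
  # non-selected platforms flow through untouched
  t5 <- make_table(t3$values, platform = "GC", samples = meta2$sample_id)
  expect_identical(median_batch_normalize(t5, meta2)$values, t5$values)
})
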