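# Feature QC, filtering, imputation and batch normalization.

#' Per-feature QC statistics
#'
#' RSD (relative standard deviation, sd/mean x 100 with the sample n-1 sd)
#' is computed over QC injections only; the missing fraction and prevalence
#' (fraction of samples with a detected, i.e. non-missing, value) over study
#' samples only. RSD is `NA` when fewer than two non-missing QC values
#' exist.
#'
#' @param table An [abundance_table()].
#' @param meta Validated sample metadata.
#' @return Tibble with `feature_id`, `rsd_qc` (%), `missing_fraction`,
#'   `prevalence`.
#' @export
compute_qc_stats <- function(table, meta) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  qc <- v[meta$sample_id[meta$role == "QC"], , drop = FALSE]
  st <- v[meta$sample_id[meta$role == "study"], , drop = FALSE]
  rsd <- apply(qc, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x) * 100
  })
  miss <- colMeans(is.na(st))
  tibble::tibble(feature_id = colnames(v),
                 rsd_qc = unname(rsd),
                 missing_fraction = unname(miss),
                 prevalence = 1 - unname(miss))
}

#' Filter features on QC reproducibility, missingness and prevalence
#'
#' Applies the standard untargeted-metabolomics feature filters, each read
#' strictly at its boundary:
#' * internal standards (annotation flag) are removed;
#' * features with QC RSD strictly greater than `rsd_max` are removed
#'   (RSD exactly at the threshold is retained);
#' * features missing in at least `missing_max` of study samples are
#'   removed (a missing fraction exactly at the threshold is removed);
#' * features are retained only when detected in strictly more than
#'   `prevalence_min` of study samples (prevalence exactly at the threshold
#'   is removed).
#'
#' The three rules are individually idempotent and order-independent.
#' Features with undefined RSD (fewer than 2 QC values) pass the RSD rule.
#'
#' @param table An [abundance_table()].
#' @param qc QC statistics from [compute_qc_stats()].
#' @param rsd_max Maximum tolerated QC RSD, percent.
#' @param missing_max Missing-fraction removal threshold.
#' @param prevalence_min Minimum (strict) detection prevalence.
#' @param annotation Optional feature annotation; rows with
#'   `is_internal_standard == TRUE` are removed first.
#' @return List with `table` (filtered [abundance_table()]) and `log`
#'   (tibble `feature_id`, `rule` naming the first rule that removed each
#'   dropped feature).
#' @export
filter_features <- function(table, qc, rsd_max = 50, missing_max = 0.70,
                            prevalence_min = 0.30, annotation = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  qc <- qc[match(colnames(table$values), qc$feature_id), ]
  rule <- rep(NA_character_, ncol(table$values))
  if (!is.null(annotation)) {
    istd <- annotation$feature_id[isTRUE_v(annotation$is_internal_standard)]
    rule[colnames(table$values) %in% istd] <- "internal-standard"
  }
  bad_rsd <- !is.na(qc$rsd_qc) & qc$rsd_qc > rsd_max
  rule[is.na(rule) & bad_rsd] <- "rsd"
  rule[is.na(rule) & qc$missing_fraction >= missing_max] <- "missing"
  rule[is.na(rule) & qc$prevalence <= prevalence_min] <- "prevalence"
  drop <- !is.na(rule)
  keep <- colnames(table$values)[!drop]
  list(table = subset_abundance(table, features = keep),
       log = tibble::tibble(feature_id = colnames(table$values)[drop],
                            rule = rule[drop]))
}

# vectorized isTRUE over a possibly-NA logical column
isTRUE_v <- function(x) !is.na(x) & x

#' Half-minimum imputation within genotype groups
#'
#' Replaces every missing study-sample cell with half the minimum of the
#' non-missing values of that feature within the sample's genotype group
#' (the below-detection assumption). A group with no observed value falls
#' back to half the feature's global non-missing minimum. QC and blank rows
#' are left untouched. A feature with no observed study value at all is an
#' error (it should have been removed by [filter_features()]).
#'
#' With `gc_noise_floor = TRUE`, missing cells of GC-platform features are
#' instead drawn Uniform(0.3, 0.7) x group minimum, emulating a local-noise
#' replacement policy for electron-impact GC data.
#'
#' @param table An [abundance_table()].
#' @param meta Validated sample metadata.
#' @param gc_noise_floor Use the stochastic noise-floor rule for GC features.
#' @param seed Seed for the noise-floor draw.
#' @return The imputed [abundance_table()] (no missing study cells remain).
#' @export
impute_half_min <- function(table, meta, gc_noise_floor = FALSE, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.null(seed)) set.seed(seed)
  v <- table$values
  st <- meta$sample_id[meta$role == "study"]
  geno <- meta$genotype[match(st, meta$sample_id)]
  sv <- v[st, , drop = FALSE]
  if (any(colSums(!is.na(sv)) == 0))
    stop("feature(s) with no observed study values; filter before imputing")
  for (j in seq_len(ncol(sv))) {
    x <- sv[, j]
    if (!anyNA(x)) next
    gmin <- min(x, na.rm = TRUE)
    for (g in unique(geno[is.na(x)])) {
      rows <- which(geno == g)
      obs <- x[rows][!is.na(x[rows])]
      base <- if (length(obs)) min(obs) else gmin
      nas <- rows[is.na(x[rows])]
      if (gc_noise_floor && table$platform[j] == "GC") {
        x[nas] <- stats::runif(length(nas), 0.3, 0.7) * base
      } else {
        x[nas] <- 0.5 * base
      }
    }
    sv[, j] <- x
  }
  v[st, ] <- sv
  abundance_table(v, table$platform)
}

#' Minimum imputation and missingness filtering for phenotypes
#'
#' Phenotypes missing in strictly more than `missing_max` of the mice of
#' either sex group are dropped entirely. Remaining missing values are
#' replaced by the minimum (not half-minimum) of the non-missing values
#' within the sample's genotype group, assuming missing phenotype readings
#' are likely minimal values; a genotype group with no observed value falls
#' back to the phenotype's global minimum.
#'
#' @param pheno Numeric matrix, samples x phenotypes.
#' @param meta Validated sample metadata (study rows of `pheno`).
#' @param missing_max Per-sex-group missingness drop threshold (strict).
#' @return List with `pheno` (imputed matrix, dropped columns removed) and
#'   `dropped` (character vector of dropped phenotype ids).
#' @export
impute_phenotype_min <- function(pheno, meta, missing_max = 0.70) {
  m <- meta[match(rownames(pheno), meta$sample_id), ]
  drop <- vapply(seq_len(ncol(pheno)), function(j) {
    any(vapply(c("F", "M"), function(s) {
      rows <- which(m$sex == s)
      length(rows) > 0 && mean(is.na(pheno[rows, j])) > missing_max
    }, logical(1)))
  }, logical(1))
  dropped <- colnames(pheno)[drop]
  pheno <- pheno[, !drop, drop = FALSE]
  for (j in seq_len(ncol(pheno))) {
    x <- pheno[, j]
    if (!anyNA(x)) next
    if (all(is.na(x))) next
    gmin <- min(x, na.rm = TRUE)
    for (g in unique(m$genotype[is.na(x)])) {
      rows <- which(m$genotype == g)
      obs <- x[rows][!is.na(x[rows])]
      base <- if (length(obs)) min(obs) else gmin
      x[rows][is.na(x[rows])] <- base
    }
    pheno[, j] <- x
  }
  list(pheno = pheno, dropped = dropped)
}

#' Median batch normalization
#'
#' For each feature on the selected platforms, values are divided by their
#' batch's per-feature median and rescaled by the feature's grand median,
#' so that after normalization every batch has the same per-feature median
#' and the intensity units are preserved. When a feature has fewer than
#' `min_obs` observed values in a batch, the batch-global scaling (median
#' over all features in the batch relative to the grand value) is used as a
#' fallback. Blank injections are excluded from median computation but are
#' rescaled along with their batch.
#'
#' The operation is scale-equivariant: multiplying all inputs by c
#' multiplies all outputs by c.
#'
#' @param table An [abundance_table()].
#' @param meta Validated sample metadata with a `batch` column.
#' @param platforms Platforms to normalize (default HILIC, the platform on
#'   which batch effects are typically observed).
#' @param min_obs Minimum observed values per (feature, batch) for the
#'   per-feature median.
#' @return The normalized [abundance_table()].
#' @export
median_batch_normalize <- function(table, meta, platforms = "HILIC",
                                   min_obs = 3) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  m <- meta[match(rownames(v), meta$sample_id), ]
  use_row <- m$role != "blank"
  feats <- which(table$platform %in% platforms)
  if (!length(feats)) return(table)
  batches <- unique(m$batch[use_row])
  if (length(batches) < 1) return(table)
  sub <- v[use_row, feats, drop = FALSE]
  grand_f <- apply(sub, 2, stats::median, na.rm = TRUE)
  grand_all <- stats::median(sub, na.rm = TRUE)
  for (b in batches) {
    rows_med <- use_row & m$batch == b
    rows_apply <- m$batch == b
    bm <- v[rows_med, feats, drop = FALSE]
    med_f <- apply(bm, 2, stats::median, na.rm = TRUE)
    nobs <- colSums(!is.na(bm))
    batch_global <- stats::median(bm, na.rm = TRUE)
    fac <- ifelse(nobs >= min_obs, med_f / grand_f, batch_global / grand_all)
    fac[!is.finite(fac) | fac == 0] <- 1
    v[rows_apply, feats] <- sweep(v[rows_apply, feats, drop = FALSE], 2, fac, `/`)
  }
  abundance_table(v, table$platform)
}
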