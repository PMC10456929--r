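# Synthetic cohort generator: emulates a KO-mouse plasma metabolomics study
# design (shared WT controls, 3 mice/sex/KO line, five MS platforms,
# lognormal abundances, MNAR missingness, QC replicates) and records the
# planted ground truth for recovery testing.

#' Simulation configuration
#'
#' Defaults emulate a 30-line knockout study: 40 wildtype mice (20 per sex),
#' 6 mice per KO line (3 per sex), ~800 features across five MS platforms,
#' lognormal abundances, sex effects on 55% of features with up to 4-fold
#' differences (skewed toward higher levels in males), planted
#' genotype/interaction archetypes on 30% of (line, feature) pairs (one
#' third of them sexually dimorphic), missing-not-at-random dropout, 22 QC
#' replicates, and phenotypes driven by designated features with
#' sex-specific coefficients.
#'
#' @param n_wt_per_sex Wildtype mice per sex.
#' @param n_ko_lines Number of KO lines.
#' @param n_ko_per_sex KO mice per sex per line.
#' @param n_features Number of metabolite features.
#' @param platform_props Named proportions over [MD_PLATFORMS].
#' @param log_mean_range Range of per-feature baseline natural-log means.
#' @param log_sd_range Range of per-feature natural-log residual sd
#'   (biological CV roughly 20-65% at the defaults).
#' @param sex_affected_frac Fraction of features with a true sex effect.
#' @param sex_log2fc_range Magnitude range (log2) of sex effects.
#' @param sex_male_higher_prob Probability a sex-affected feature is higher
#'   in males.
#' @param ko_affected_frac Fraction of features affected per KO line.
#' @param ko_dimorphic_frac Among affected pairs, fraction with a sexually
#'   dimorphic archetype (split equally across the four dimorphic types
#'   unless `ko_archetype_weights` is given).
#' @param ko_archetype_weights Optional named weights over
#'   `c("both-sexes-equal","female-only","male-only","opposite-direction",
#'   "different-effect-size")`; overrides `ko_dimorphic_frac`.
#' @param ko_log2fc_range Magnitude range (log2) of planted KO effects.
#' @param archetype_map Optional data frame (`ko_line`, `feature_id`,
#'   `archetype`) forcing archetypes for specific pairs; lines must exist.
#' @param missing_rate Target overall missing fraction among study cells.
#' @param mnar_quantile Per-feature abundance quantile below which cells are
#'   preferentially censored.
#' @param mnar_weight Odds multiplier for censoring low-abundance cells.
#' @param low_detect_frac Fraction of features simulated near the detection
#'   limit (~80% missing; exercises the prevalence filter).
#' @param n_qc Number of pooled QC injections.
#' @param n_blank Number of blank injections.
#' @param qc_rsd_target Median technical RSD (%) of QC replicates.
#' @param high_rsd_frac Fraction of features with poor technical
#'   reproducibility (RSD drawn from `high_rsd_range`).
#' @param high_rsd_range RSD range (%) for poor features.
#' @param istd_frac Fraction of features flagged as deuterated internal
#'   standards (removed by the QC filter).
#' @param n_batches Number of acquisition batches.
#' @param batch_log_fc Natural-log multiplicative batch effect applied to
#'   HILIC features in the second batch.
#' @param n_phenotypes Number of continuous phenotypes.
#' @param pheno_type_probs Named probabilities of phenotype driver patterns
#'   (`null`, `both-same`, `female-only`, `male-only`, `opposite`).
#' @param pheno_noise_sd Residual sd of phenotypes (drivers contribute on a
#'   standardized scale with unit coefficients).
#' @param pheno_missing_rate Missing-completely-at-random rate of phenotype
#'   cells.
#' @param n_het_lines Number of lines typed heterozygous (the rest are
#'   homozygous null).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `md_sim_config` list.
#' @export
sim_config <- function(n_wt_per_sex = 20,
                       n_ko_lines = 30,
                       n_ko_per_sex = 3,
                       n_features = 800,
                       platform_props = c("GC" = 0.13, "HILIC" = 0.22,
                                          "CSH-lipidomics" = 0.545,
                                          "bile-steroids" = 0.04,
                                          "oxylipins" = 0.065),
                       log_mean_range = c(log(1e4), log(1e7)),
                       log_sd_range = c(0.2, 0.6),
                       sex_affected_frac = 0.55,
                       sex_log2fc_range = c(0.25, 2),
                       sex_male_higher_prob = 0.75,
                       ko_affected_frac = 0.30,
                       ko_dimorphic_frac = 1 / 3,
                       ko_archetype_weights = NULL,
                       ko_log2fc_range = c(1, 2.5),
                       archetype_map = NULL,
                       missing_rate = 0.10,
                       mnar_quantile = 0.30,
                       mnar_weight = 4,
                       low_detect_frac = 0.03,
                       n_qc = 22,
                       n_blank = 22,
                       qc_rsd_target = 10,
                       high_rsd_frac = 0.05,
                       high_rsd_range = c(55, 120),
                       istd_frac = 0.01,
                       n_batches = 2,
                       batch_log_fc = 0.4,
                       n_phenotypes = 208,
                       pheno_type_probs = c("null" = 0.20, "both-same" = 0.15,
                                            "female-only" = 0.30,
                                            "male-only" = 0.30,
                                            "opposite" = 0.05),
                       pheno_noise_sd = 1,
                       pheno_missing_rate = 0.03,
                       n_het_lines = 17,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_wt_per_sex, n_ko_lines, n_ko_per_sex, n_features,
              n_qc, n_blank, n_batches, n_phenotypes)
  if (any(counts < 0) || any(c(n_wt_per_sex, n_features) == 0))
    stop("counts must be positive")
  fr <- c(sex_affected_frac, ko_affected_frac, ko_dimorphic_frac,
          missing_rate, low_detect_frac, high_rsd_frac, istd_frac,
          pheno_missing_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  if (abs(sum(platform_props) - 1) > 1e-8 ||
      !all(names(platform_props) %in% MD_PLATFORMS))
    stop("platform_props must be named by known platforms and sum to 1")
  structure(cfg, class = "md_sim_config")
}

.ARCHETYPES <- c("both-sexes-equal", "female-only", "male-only",
                 "opposite-direction", "different-effect-size")

# Draw per-sex log2 effects for one archetype.
.archetype_effects <- function(archetype, lo, hi) {
  sgn <- sample(c(-1, 1), 1)
  b <- stats::runif(1, lo, hi) * sgn
  switch(archetype,
    "both-sexes-equal"      = c(f = b, m = b),
    "female-only"           = c(f = b, m = 0),
    "male-only"             = c(f = 0, m = b),
    "opposite-direction"    = c(f = b, m = -b),
    "different-effect-size" = {
      small <- stats::runif(1, lo, lo + 0.25 * (hi - lo)) * sgn
      large <- small + sgn * stats::runif(1, 1.5, 2)
      if (stats::runif(1) < 0.5) c(f = small, m = large) else c(f = large, m = small)
    },
    stop("unknown archetype: ", archetype))
}

#' Simulate a knockout-study cohort
#'
#' Generates abundances, sample metadata, feature annotation, phenotypes and
#' the planted ground truth under the design described in [sim_config()].
#' Abundances are lognormal; sex effects are applied to males on the log
#' scale (so the planted value is exactly log2 of the male/female ratio);
#' KO effects follow the archetype drawn for each (line, feature) pair.
#' Phenotypes are linear combinations of a standardized log-abundance driver
#' feature with sex-specific coefficients plus Gaussian noise. Missingness
#' is injected MNAR via [inject_missingness()]. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `abundance` ([abundance_table()]), `meta`, `annotation`,
#'   `phenotypes` (matrix, study samples only), `truth` (tibble of planted
#'   non-null KO archetypes with per-sex log2 effects and the feature's sex
#'   effect), `sex_truth`, `pheno_truth`, and the echoed `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "md_sim_config"))
  c_ <- config
  set.seed(c_$seed)

  lines <- sprintf("Ko%02d", seq_len(c_$n_ko_lines))
  if (!is.null(c_$archetype_map)) {
    bad <- setdiff(unique(c_$archetype_map$ko_line), lines)
    if (length(bad))
      stop("archetype_map references unknown line(s): ",
           paste(bad, collapse = ", "))
  }
  zyg <- rep(c("het", "hom"),
             c(min(c_$n_het_lines, c_$n_ko_lines),
               max(0, c_$n_ko_lines - c_$n_het_lines)))

  ## ---- sample metadata ----
  wt_ids <- c(sprintf("WT_F%02d", seq_len(c_$n_wt_per_sex)),
              sprintf("WT_M%02d", seq_len(c_$n_wt_per_sex)))
  ko_ids <- unlist(lapply(lines, function(l)
    c(sprintf("%s_F%d", l, seq_len(c_$n_ko_per_sex)),
      sprintf("%s_M%d", l, seq_len(c_$n_ko_per_sex)))))
  qc_ids <- sprintf("QC_%02d", seq_len(c_$n_qc))
  bl_ids <- sprintf("BLANK_%02d", seq_len(c_$n_blank))
  per_line <- 2 * c_$n_ko_per_sex
  meta <- tibble::tibble(
    sample_id = c(wt_ids, ko_ids, qc_ids, bl_ids),
    sex = c(rep(c("F", "M"), each = c_$n_wt_per_sex),
            rep(rep(c("F", "M"), each = c_$n_ko_per_sex), c_$n_ko_lines),
            rep(NA_character_, c_$n_qc + c_$n_blank)),
    genotype = c(rep("WT", length(wt_ids)), rep(lines, each = per_line),
                 rep(NA_character_, c_$n_qc + c_$n_blank)),
    zygosity = c(rep("wt", length(wt_ids)), rep(zyg, each = per_line),
                 rep("na", c_$n_qc + c_$n_blank)),
    role = c(rep("study", length(wt_ids) + length(ko_ids)),
             rep("QC", c_$n_qc), rep("blank", c_$n_blank)),
    batch = paste0("B", rep_len(seq_len(c_$n_batches),
                                length(wt_ids) + length(ko_ids) +
                                  c_$n_qc + c_$n_blank)),
    body_weight = NA_real_)
  is_study <- meta$role == "study"
  meta$body_weight[is_study] <-
    ifelse(meta$sex[is_study] == "M",
           stats::rnorm(sum(is_study), 30, 2.5),
           stats::rnorm(sum(is_study), 23, 2.0))

  ## ---- feature annotation ----
  fid <- sprintf("F%04d", seq_len(c_$n_features))
  platform <- sample(names(c_$platform_props), c_$n_features,
                     replace = TRUE, prob = c_$platform_props)
  cluster <- character(c_$n_features)
  for (pl in unique(platform)) {
    idx <- which(platform == pl)
    n_cl <- max(1L, round(length(idx) / 15))
    cluster[idx] <- sprintf("%s_cl%02d", pl,
                            sample(seq_len(n_cl), length(idx), replace = TRUE))
  }
  istd <- stats::runif(c_$n_features) < c_$istd_frac
  annot <- tibble::tibble(
    feature_id = fid,
    name = paste0("compound_", fid),
    chemical_cluster = ifelse(istd, NA_character_, cluster),
    platform = platform,
    compound_id = NA_character_,
    is_internal_standard = istd)

  ## ---- per-feature baseline parameters ----
  mu <- stats::runif(c_$n_features, c_$log_mean_range[1], c_$log_mean_range[2])
  sd_f <- stats::runif(c_$n_features, c_$log_sd_range[1], c_$log_sd_range[2])

  ## ---- sex effects (log2 of male/female ratio) ----
  sex_hit <- !istd & stats::runif(c_$n_features) < c_$sex_affected_frac
  sex_log2 <- numeric(c_$n_features)
  nh <- sum(sex_hit)
  if (nh > 0) {
    mag <- stats::runif(nh, c_$sex_log2fc_range[1], c_$sex_log2fc_range[2])
    sgn <- ifelse(stats::runif(nh) < c_$sex_male_higher_prob, 1, -1)
    sex_log2[sex_hit] <- mag * sgn
  }

  ## ---- KO archetypes and effects ----
  wts <- c_$ko_archetype_weights
  if (is.null(wts)) {
    wts <- c("both-sexes-equal" = 1 - c_$ko_dimorphic_frac,
             "female-only" = c_$ko_dimorphic_frac / 4,
             "male-only" = c_$ko_dimorphic_frac / 4,
             "opposite-direction" = c_$ko_dimorphic_frac / 4,
             "different-effect-size" = c_$ko_dimorphic_frac / 4)
  }
  stopifnot(all(names(wts) %in% .ARCHETYPES))
  eff_f <- matrix(0, c_$n_features, c_$n_ko_lines, dimnames = list(fid, lines))
  eff_m <- eff_f
  arch <- matrix("null", c_$n_features, c_$n_ko_lines, dimnames = list(fid, lines))
  for (j in seq_len(c_$n_ko_lines)) {
    hit <- which(!istd & stats::runif(c_$n_features) < c_$ko_affected_frac)
    if (!length(hit)) next
    a <- sample(names(wts), length(hit), replace = TRUE, prob = wts)
    arch[hit, j] <- a
    for (k in seq_along(hit)) {
      e <- .archetype_effects(a[k], c_$ko_log2fc_range[1], c_$ko_log2fc_range[2])
      eff_f[hit[k], j] <- e["f"]
      eff_m[hit[k], j] <- e["m"]
    }
  }
  if (!is.null(c_$archetype_map)) {
    am <- c_$archetype_map
    for (r in seq_len(nrow(am))) {
      i <- match(am$feature_id[r], fid); j <- match(am$ko_line[r], lines)
      arch[i, j] <- am$archetype[r]
      if (am$archetype[r] == "null") {
        eff_f[i, j] <- eff_m[i, j] <- 0
      } else {
        e <- .archetype_effects(am$archetype[r], c_$ko_log2fc_range[1],
                                c_$ko_log2fc_range[2])
        eff_f[i, j] <- e["f"]; eff_m[i, j] <- e["m"]
      }
    }
  }

  ## ---- study abundances (log scale, then exp) ----
  n_study <- sum(is_study)
  study_meta <- meta[is_study, ]
  L <- matrix(stats::rnorm(n_study * c_$n_features), n_study, c_$n_features)
  L <- sweep(L, 2, sd_f, `*`)
  L <- sweep(L, 2, mu, `+`)
  male <- study_meta$sex == "M"
  L[male, ] <- sweep(L[male, , drop = FALSE], 2, sex_log2 * log(2), `+`)
  for (j in seq_len(c_$n_ko_lines)) {
    rows_f <- which(study_meta$genotype == lines[j] & !male)
    rows_m <- which(study_meta$genotype == lines[j] & male)
    L[rows_f, ] <- sweep(L[rows_f, , drop = FALSE], 2, eff_f[, j] * log(2), `+`)
    L[rows_m, ] <- sweep(L[rows_m, , drop = FALSE], 2, eff_m[, j] * log(2), `+`)
  }
  study_vals <- exp(L)

  ## ---- QC and blank injections ----
  qc_rsd <- ifelse(stats::runif(c_$n_features) < c_$high_rsd_frac,
                   stats::runif(c_$n_features, c_$high_rsd_range[1],
                                c_$high_rsd_range[2]),
                   pmax(2, stats::rnorm(c_$n_features, c_$qc_rsd_target, 3)))
  qc_sigma <- sqrt(log(1 + (qc_rsd / 100)^2))
  qc_vals <- exp(sweep(
    sweep(matrix(stats::rnorm(c_$n_qc * c_$n_features),
                 nrow = c_$n_qc, ncol = c_$n_features), 2, qc_sigma, `*`),
    2, mu, `+`))
  bl_vals <- exp(sweep(
    matrix(stats::rnorm(c_$n_blank * c_$n_features),
           nrow = c_$n_blank, ncol = c_$n_features) * 0.5,
    2, mu + log(1e-3), `+`))

  vals <- rbind(study_vals, qc_vals, bl_vals)
  rownames(vals) <- meta$sample_id
  colnames(vals) <- fid

  ## ---- batch effect (multiplicative, HILIC) ----
  if (c_$n_batches > 1 && c_$batch_log_fc != 0) {
    hil <- platform == "HILIC"
    b2 <- meta$batch != "B1" & meta$role != "blank"
    vals[b2, hil] <- vals[b2, hil] * exp(c_$batch_log_fc)
  }

  tbl <- abundance_table(vals, platform)

  ## ---- missingness: MNAR over study cells, plus low-detect features ----
  if (c_$missing_rate > 0) {
    sub <- abundance_table(vals[is_study, , drop = FALSE], platform)
    sub <- inject_missingness(sub, c_$missing_rate, c_$mnar_quantile,
                              mnar_weight = c_$mnar_weight)
    tbl$values[is_study, ] <- sub$values
  }
  low <- which(!istd & stats::runif(c_$n_features) < c_$low_detect_frac)
  if (length(low)) {
    drop <- matrix(stats::runif(n_study * length(low)) < 0.8,
                   n_study, length(low))
    v <- tbl$values[is_study, low, drop = FALSE]
    v[drop] <- NA_real_
    tbl$values[is_study, low] <- v
  }

  ## ---- phenotypes (study samples; drivers on standardized log abundance) ----
  pheno <- NULL; pheno_truth <- NULL
  if (c_$n_phenotypes > 0) {
    pid <- sprintf("P%03d", seq_len(c_$n_phenotypes))
    drivers <- sample(which(!istd), c_$n_phenotypes, replace = TRUE)
    type <- sample(names(c_$pheno_type_probs), c_$n_phenotypes,
                   replace = TRUE, prob = c_$pheno_type_probs)
    bF <- ifelse(type %in% c("both-same", "female-only", "opposite"), 1,
                 ifelse(type == "male-only", 0, 0))
    bM <- ifelse(type %in% c("both-same", "male-only"), 1,
                 ifelse(type == "opposite", -1, 0))
    Z <- scale(L[, drivers, drop = FALSE])
    isF <- as.numeric(!male)
    pheno <- Z * outer(isF, bF) + Z * outer(1 - isF, bM) +
      matrix(stats::rnorm(n_study * c_$n_phenotypes, 0, c_$pheno_noise_sd),
             n_study)
    dimnames(pheno) <- list(study_meta$sample_id, pid)
    if (c_$pheno_missing_rate > 0) {
      drop <- matrix(stats::runif(length(pheno)) < c_$pheno_missing_rate,
                     nrow(pheno))
      pheno[drop] <- NA_real_
    }
    pheno_truth <- tibble::tibble(phenotype_id = pid,
                                  driver_feature = fid[drivers],
                                  type = type, beta_f = bF, beta_m = bM)
  }

  ## ---- truth tables ----
  nz <- which(arch != "null", arr.ind = TRUE)
  truth <- tibble::tibble(
    feature_id = fid[nz[, 1]],
    ko_line = lines[nz[, 2]],
    archetype = arch[nz],
    effect_f_log2 = eff_f[nz],
    effect_m_log2 = eff_m[nz],
    sex_log2 = sex_log2[nz[, 1]])
  sex_truth <- tibble::tibble(feature_id = fid, sex_log2 = sex_log2)

  list(abundance = tbl, meta = meta, annotation = annot,
       phenotypes = pheno, truth = truth, sex_truth = sex_truth,
       pheno_truth = pheno_truth, config = config)
}

#' Inject missing-not-at-random dropout
#'
#' Cells below each feature's `mnar_quantile` abundance quantile are
#' censored with `mnar_weight`-fold higher probability than cells above it,
#' calibrated so the expected overall missing fraction equals `rate`
#' (low abundance implies higher missingness, the below-detection
#' assumption under which half-minimum imputation is well posed).
#'
#' @param table An [abundance_table()].
#' @param rate Target overall missing fraction, in \[0, 1).
#' @param mnar_quantile Per-feature quantile defining "low abundance".
#' @param mnar_weight Censoring odds multiplier for low cells.
#' @param seed Optional integer seed.
#' @return The table with additional `NA` cells.
#' @export
inject_missingness <- function(table, rate, mnar_quantile = 0.3,
                               mnar_weight = 4, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (rate >= 1 || rate < 0) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  v <- table$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    if (!any(obs)) next
    thr <- stats::quantile(x[obs], mnar_quantile, names = FALSE)
    low <- obs & x <= thr
    q_eff <- sum(low) / sum(obs)
    p_high <- rate / (q_eff * mnar_weight + (1 - q_eff))
    p_low <- min(1, mnar_weight * p_high)
    p <- ifelse(low, p_low, p_high)
    drop <- obs & stats::runif(length(x)) < p
    x[drop] <- NA_real_
    v[, j] <- x
  }
  abundance_table(v, table$platform)
}
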