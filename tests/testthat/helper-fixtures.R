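# In-code fixtures shared across test files.

# A minimal abundance table from a literal matrix (samples x features).
make_table <- function(values, platform = "GC",
                       samples = sprintf("S%02d", seq_len(nrow(values))),
                       features = sprintf("F%03d", seq_len(ncol(values)))) {
  rownames(values) <- samples
  colnames(values) <- features
  abundance_table(values, platform)
}

# Metadata for a table whose samples are all WT study mice, half F half M.
wt_meta <- function(samples, weights = NULL) {
  n <- length(samples)
  validate_sample_meta(tibble::tibble(
    sample_id = samples,
    sex = rep(c("F", "M"), each = n / 2),
    genotype = "WT", zygosity = "wt", role = "study", batch = "B1",
    body_weight = if (is.null(weights)) stats::rnorm(n, 25, 2) else weights))
}

# A small full-design cohort used where the defaults would be too slow.
small_cohort <- function(seed = 42, ...) {
  args <- list(n_wt_per_sex = 8, n_ko_lines = 3, n_features = 60, n_qc = 6,
               n_blank = 2, n_phenotypes = 8, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  simulate_cohort(do.call(sim_config, args))
}

# One-line cohort with forced archetypes; clean settings for recovery tests.
planted_cohort <- function(weights, effect, n_features = 200, seed = 1,
                           ...) {
  simulate_cohort(sim_config(
    n_ko_lines = 1, n_features = n_features, ko_affected_frac = 1,
    ko_archetype_weights = weights, ko_log2fc_range = c(effect, effect),
    sex_affected_frac = 0, missing_rate = 0, low_detect_frac = 0,
    high_rsd_frac = 0, istd_frac = 0, n_phenotypes = 0, n_qc = 4,
    n_blank = 0, seed = seed, ...))
}

DIMORPHIC_CATS <- c("female-only", "male-only", "opposite-direction",
                    "different-effect-size", "interaction-only")
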