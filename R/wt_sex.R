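# Sex-effect testing in wildtype mice: two-group linear models with pooled
# or per-sex residual variances, optional body-weight covariate, BH FDR and
# fold-change summaries.

#' Fit a sex-effect model to one feature
#'
#' Fits `y ~ sex` (or `y ~ sex + body_weight` when `adjust_weight = TRUE`)
#' on wildtype study samples. `variance_mode = "pooled"` is ordinary least
#' squares, whose sex-coefficient Wald test equals the pooled-variance
#' two-sample t-test. `variance_mode = "per-sex"` allows different residual
#' variances in females and males via two-step feasible generalized least
#' squares: OLS residual variances are estimated per sex and the model is
#' refit with inverse-variance weights. When the per-sex variances are
#' equal, the two modes coincide.
#'
#' @param y Numeric abundances, one per sample, natural scale.
#' @param meta Data frame aligned with `y`; needs `sex` and, when
#'   adjusting, `body_weight`.
#' @param adjust_weight Include body weight as a covariate.
#' @param variance_mode `"per-sex"` (default) or `"pooled"`.
#' @return One-row tibble: `estimate` (mean M - mean F, natural scale),
#'   `log2_fc` (log2 of mean M / mean F), `p_value`. A constant `y` yields
#'   estimate 0 and p = 1 with a warning.
#' @export
fit_sex_model <- function(y, meta, adjust_weight = FALSE,
                          variance_mode = c("per-sex", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  sex <- factor(meta$sex, levels = c("F", "M"))
  if (any(table(sex) < 2)) stop("both sexes must be present with >= 2 samples")
  est <- mean(y[sex == "M"]) - mean(y[sex == "F"])
  l2 <- log2(mean(y[sex == "M"]) / mean(y[sex == "F"]))
  if (stats::var(y) == 0) {
    warning("response has zero variance; p set to 1")
    return(tibble::tibble(estimate = 0, log2_fc = 0, p_value = 1))
  }
  dat <- data.frame(y = y, sex = sex)
  form <- y ~ sex
  if (adjust_weight) {
    dat$body_weight <- meta$body_weight
    form <- y ~ sex + body_weight
  }
  fit <- stats::lm(form, data = dat)
  if (variance_mode == "per-sex") {
    r <- stats::residuals(fit)
    s2 <- tapply(r^2, sex, sum) / (table(sex) - 1)
    if (any(s2 == 0)) {
      warning("zero residual variance in one sex; using pooled variances")
    } else {
      fit <- stats::lm(form, data = dat, weights = 1 / s2[as.character(sex)])
    }
  }
  co <- summary(fit)$coefficients
  p <- co["sexM", "Pr(>|t|)"]
  tibble::tibble(estimate = est, log2_fc = l2, p_value = unname(p))
}

#' Test every feature for a sex effect in wildtype mice
#'
#' Runs [fit_sex_model()] on the WT study samples for each feature, adds
#' Benjamini-Hochberg q-values and a significance-aware direction call.
#'
#' @param table An [abundance_table()] (imputed; no missing study cells
#'   among WT samples for tested features).
#' @param meta Validated sample metadata.
#' @param adjust_weight,variance_mode Passed to [fit_sex_model()].
#' @param alpha Significance level for the direction call.
#' @param use_fdr Call direction on `q_value` instead of `p_value`.
#' @return Tibble: `feature_id`, `estimate`, `log2_fc`, `p_value`,
#'   `q_value`, `direction` in `higher-in-M` / `higher-in-F` / `ns`.
#' @export
wt_sex_test <- function(table, meta, adjust_weight = FALSE,
                        variance_mode = "per-sex", alpha = 0.05,
                        use_fdr = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  wt <- meta[meta$role == "study" & meta$genotype == "WT", ]
  v <- table$values[wt$sample_id, , drop = FALSE]
  rows <- lapply(seq_len(ncol(v)), function(j) {
    suppressWarnings(fit_sex_model(v[, j], wt, adjust_weight, variance_mode))
  })
  res <- dplyr::bind_rows(rows)
  res <- tibble::add_column(res, feature_id = colnames(v), .before = 1)
  res$q_value <- bh_adjust(res$p_value)
  crit <- if (use_fdr) res$q_value else res$p_value
  res$direction <- ifelse(crit >= alpha, "ns",
                          ifelse(res$estimate > 0, "higher-in-M", "higher-in-F"))
  res
}

#' Summarize sex-effect directions
#'
#' Counts and percentages (one decimal) of features higher in males, higher
#' in females, and not significant, at `p < alpha` (or `q < alpha` with
#' `use_fdr`).
#'
#' @param results Output of [wt_sex_test()].
#' @param alpha Significance level.
#' @param use_fdr Use q-values.
#' @return One-row tibble with counts `n_total`, `n_higher_m`,
#'   `n_higher_f`, `n_ns` and percentages `pct_significant`,
#'   `pct_higher_m`, `pct_higher_f`.
#' @export
summarize_sex_effects <- function(results, alpha = 0.05, use_fdr = FALSE) {
  crit <- if (use_fdr) results$q_value else results$p_value
  sig <- !is.na(crit) & crit < alpha
  hm <- sum(sig & results$estimate > 0)
  hf <- sum(sig & results$estimate < 0)
  n <- nrow(results)
  pct <- function(k) if (n == 0) 0 else round(100 * k / n, 1)
  tibble::tibble(n_total = n, n_higher_m = hm, n_higher_f = hf,
                 n_ns = n - hm - hf,
                 pct_significant = pct(hm + hf),
                 pct_higher_m = pct(hm), pct_higher_f = pct(hf))
}
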