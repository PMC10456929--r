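# Per-line genotype and genotype-by-sex interaction testing with rule-based
# sexual-dimorphism classification and standardized effect sizes.

KO_CATEGORIES <- c("ns", "genotype-no-sex-difference", "female-only",
                   "male-only", "opposite-direction", "different-effect-size",
                   "interaction-only")

#' Classify the sexual dimorphism of a genotype effect
#'
#' Decision tree over the four test p-values of one (KO line, metabolite)
#' pair (all two-sided at level `alpha`):
#' 1. genotype and interaction both non-significant: `ns`;
#' 2. genotype significant, interaction not: `genotype-no-sex-difference`;
#' 3. interaction significant: `female-only` when only the female KO-vs-WT
#'    comparison is significant, `male-only` for the converse,
#'    `opposite-direction` when both are significant with opposite signs of
#'    change, `different-effect-size` when both are significant with the
#'    same sign, and `interaction-only` when neither per-sex comparison
#'    reaches significance (an interaction with no resolvable per-sex
#'    effect; reported separately, never merged).
#'
#' With `gate_genotype = TRUE`, step 3 additionally requires the genotype
#' test itself to be significant; interaction-significant pairs failing that
#' gate fall back to `ns`.
#'
#' All arguments are vectorized; the categories partition every tested pair.
#'
#' @param p_genotype,p_interaction Nested-model F-test p-values.
#' @param p_female,p_male Per-sex KO-vs-WT comparison p-values.
#' @param sign_female,sign_male Signs of (KO mean - WT mean) per sex.
#' @param alpha Significance level.
#' @param gate_genotype Also require `p_genotype < alpha` for dimorphic
#'   sub-classification.
#' @return Character vector of categories.
#' @export
classify_dimorphism <- function(p_genotype, p_interaction, p_female, p_male,
                                sign_female, sign_male, alpha = 0.05,
                                gate_genotype = FALSE) {
  n <- length(p_genotype)
  sig_g <- !is.na(p_genotype) & p_genotype < alpha
  sig_i <- !is.na(p_interaction) & p_interaction < alpha
  sig_f <- !is.na(p_female) & p_female < alpha
  sig_m <- !is.na(p_male) & p_male < alpha
  out <- rep("ns", n)
  out[sig_g & !sig_i] <- "genotype-no-sex-difference"
  sub <- sig_i & (!gate_genotype | sig_g)
  out[sub & sig_f & !sig_m] <- "female-only"
  out[sub & !sig_f & sig_m] <- "male-only"
  both <- sub & sig_f & sig_m
  out[both & sign_female * sign_male < 0] <- "opposite-direction"
  out[both & sign_female * sign_male >= 0] <- "different-effect-size"
  out[sub & !sig_f & !sig_m] <- "interaction-only"
  out
}

#' Test one KO line against the wildtype pool
#'
#' For every feature, compares the line's mice (both sexes) plus the shared
#' WT pool with two nested-model F tests -- genotype
#' (`~ genotype + sex + genotype:sex` vs `~ sex`) and genotype-sex
#' interaction (full vs `~ genotype + sex`) -- and with per-sex two-group
#' KO-vs-WT linear-model comparisons, then assigns the dimorphism category
#' via [classify_dimorphism()]. All tests operate on natural-scale
#' abundances; fold-changes are ratios of arithmetic group means. No FDR is
#' applied across features here by design (hypothesis generation, not
#' biomarker discovery); use [bh_adjust()] downstream if wanted.
#'
#' @param table An imputed [abundance_table()].
#' @param meta Validated sample metadata.
#' @param ko_line Genotype label of the line to test.
#' @param alpha Significance level for the classification.
#' @param welch Use Welch (unequal-variance) per-sex comparisons instead of
#'   pooled-variance OLS.
#' @param gate_genotype Passed to [classify_dimorphism()].
#' @return Tibble with one row per feature: `ko_line`, `feature_id`,
#'   `p_genotype`, `p_interaction`, `p_female`, `p_male`, `fc_female`,
#'   `fc_male` (KO mean / sex-matched WT mean), `sign_female`, `sign_male`,
#'   `category`. Returns a zero-row tibble with a warning when the design
#'   is rank deficient (e.g. one sex absent in the KO line).
#' @export
test_line <- function(table, meta, ko_line, alpha = 0.05, welch = FALSE,
                      gate_genotype = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  sub <- meta[meta$role == "study" & meta$genotype %in% c(ko_line, "WT"), ]
  if (!any(sub$genotype == ko_line)) stop("unknown KO line: ", ko_line)
  Y <- table$values[sub$sample_id, , drop = FALSE]
  geno <- factor(sub$genotype, levels = c("WT", ko_line))
  sex <- factor(sub$sex, levels = c("F", "M"))
  empty <- tibble::tibble(ko_line = character(), feature_id = character(),
                          p_genotype = double(), p_interaction = double(),
                          p_female = double(), p_male = double(),
                          fc_female = double(), fc_male = double(),
                          sign_female = double(), sign_male = double(),
                          category = character())
  if (any(table(geno, sex) == 0)) {
    warning("rank-deficient design for line ", ko_line,
            " (a genotype-sex cell is empty); line skipped")
    return(empty)
  }
  dat <- data.frame(geno = geno, sex = sex)
  X1 <- stats::model.matrix(~ geno * sex, dat)
  Xs <- stats::model.matrix(~ sex, dat)
  Xgs <- stats::model.matrix(~ geno + sex, dat)
  rss1 <- .rss_matrix(X1, Y)
  rss_s <- .rss_matrix(Xs, Y)
  rss_gs <- .rss_matrix(Xgs, Y)
  df2 <- nrow(Y) - ncol(X1)
  f_g <- pmax(0, ((rss_s - rss1) / 2) / (rss1 / df2))
  f_i <- pmax(0, ((rss_gs - rss1) / 1) / (rss1 / df2))
  p_g <- stats::pf(f_g, 2, df2, lower.tail = FALSE)
  p_i <- stats::pf(f_i, 1, df2, lower.tail = FALSE)
  # zero residual variance (e.g. constant feature): no evidence either way
  degen <- rss1 == 0
  p_g[degen & rss_s == 0] <- 1
  p_i[degen & rss_gs == 0] <- 1
  per_sex <- lapply(c("F", "M"), function(s) {
    a <- Y[sex == s & geno == ko_line, , drop = FALSE]
    b <- Y[sex == s & geno == "WT", , drop = FALSE]
    tt <- .two_group_test(a, b, welch = welch)
    list(p = tt$p, fc = tt$mean1 / tt$mean2, sign = sign(tt$estimate))
  })
  cat_ <- classify_dimorphism(p_g, p_i, per_sex[[1]]$p, per_sex[[2]]$p,
                              per_sex[[1]]$sign, per_sex[[2]]$sign,
                              alpha = alpha, gate_genotype = gate_genotype)
  tibble::tibble(ko_line = ko_line, feature_id = colnames(Y),
                 p_genotype = unname(p_g), p_interaction = unname(p_i),
                 p_female = unname(per_sex[[1]]$p),
                 p_male = unname(per_sex[[2]]$p),
                 fc_female = unname(per_sex[[1]]$fc),
                 fc_male = unname(per_sex[[2]]$fc),
                 sign_female = unname(per_sex[[1]]$sign),
                 sign_male = unname(per_sex[[2]]$sign),
                 category = cat_)
}

#' Test all KO lines
#'
#' @param table,meta,alpha,welch,gate_genotype As in [test_line()].
#' @return Row-bound tibble of [test_line()] results for every non-WT
#'   genotype among study samples, ordered by line then feature.
#' @export
test_all_lines <- function(table, meta, alpha = 0.05, welch = FALSE,
                           gate_genotype = FALSE) {
  lines <- setdiff(unique(meta$genotype[meta$role == "study"]), "WT")
  dplyr::bind_rows(lapply(sort(lines), function(l)
    test_line(table, meta, l, alpha, welch, gate_genotype)))
}

#' Standardized fold-change of a KO line for one feature
#'
#' The KO group arithmetic mean divided by the sex-matched WT arithmetic
#' mean, per sex. `spread` is the first-order (delta-method) standard
#' deviation of that ratio of means, propagated from the two group standard
#' errors: fc * sqrt(sd_KO^2 / (n_KO mean_KO^2) + sd_WT^2 / (n_WT mean_WT^2)).
#'
#' @param table An imputed [abundance_table()].
#' @param meta Validated sample metadata.
#' @param ko_line Genotype label.
#' @param feature Feature id.
#' @return Tibble with rows for sexes F and M: `ko_line`, `feature_id`,
#'   `sex`, `standardized_fc`, `spread`.
#' @export
standardized_fold_change <- function(table, meta, ko_line, feature) {
  stopifnot(inherits(table, "abundance_table"))
  sub <- meta[meta$role == "study" & meta$genotype %in% c(ko_line, "WT"), ]
  y <- table$values[sub$sample_id, feature]
  rows <- lapply(c("F", "M"), function(s) {
    ko <- y[sub$sex == s & sub$genotype == ko_line]
    wt <- y[sub$sex == s & sub$genotype == "WT"]
    if (!length(wt) || mean(wt) <= 0)
      stop("WT ", s, " group empty or non-positive mean for ", feature)
    fc <- mean(ko) / mean(wt)
    spread <- fc * sqrt(stats::var(ko) / (length(ko) * mean(ko)^2) +
                        stats::var(wt) / (length(wt) * mean(wt)^2))
    tibble::tibble(ko_line = ko_line, feature_id = feature, sex = s,
                   standardized_fc = fc, spread = spread)
  })
  dplyr::bind_rows(rows)
}

#' Summarize KO test results
#'
#' A (line, feature) pair is significant when its genotype or interaction
#' test falls below `alpha` -- equivalently when its category is not `ns` --
#' and sexually dimorphic when its category is one of `female-only`,
#' `male-only`, `opposite-direction`, `different-effect-size` or
#' `interaction-only`.
#'
#' @param results Output of [test_all_lines()] (or one [test_line()]).
#' @param alpha Significance level (only used for the `n_tests` sanity
#'   fields; categories were fixed at test time).
#' @return List with `global` (one-row tibble: test counts, percent
#'   significant, percent dimorphic among significant, per-category
#'   fractions among significant) and `per_line` (tibble per KO line:
#'   `pct_altered`, `pct_dimorphic_among_altered`).
#' @export
summarize_ko <- function(results, alpha = 0.05) {
  dim_cats <- c("female-only", "male-only", "opposite-direction",
                "different-effect-size", "interaction-only")
  sig <- results$category != "ns"
  n <- nrow(results)
  n_sig <- sum(sig)
  cat_frac <- vapply(setdiff(KO_CATEGORIES, "ns"), function(k)
    if (n_sig == 0) 0 else sum(results$category == k) / n_sig, numeric(1))
  global <- tibble::tibble(
    n_tests = n, n_significant = n_sig,
    pct_significant = if (n == 0) 0 else round(100 * n_sig / n, 1),
    pct_dimorphic_among_significant =
      if (n_sig == 0) 0 else round(100 * sum(results$category %in% dim_cats) / n_sig, 1))
  for (k in names(cat_frac)) global[[paste0("frac_", k)]] <- unname(cat_frac[k])
  per_line <- dplyr::bind_rows(lapply(
    split(results, results$ko_line), function(r)
      tibble::tibble(
        ko_line = r$ko_line[1],
        n_features = nrow(r),
        n_altered = sum(r$category != "ns"),
        pct_altered = round(100 * mean(r$category != "ns"), 1),
        pct_dimorphic_among_altered =
          round(100 * sum(r$category %in% dim_cats) /
                  max(1L, sum(r$category != "ns")), 1))))
  list(global = global, per_line = per_line)
}
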