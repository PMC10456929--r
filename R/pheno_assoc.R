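# Per-sex Spearman metabolite-phenotype association in wildtype mice, with
# dimorphism categorization of correlations and cluster-level summaries.

CORR_CATEGORIES <- c("ns", "female-only", "male-only", "both-same-direction",
                     "both-opposite-direction")

#' Per-sex Spearman correlations between metabolites and phenotypes
#'
#' For wildtype study mice, computes the Spearman rank correlation of every
#' (metabolite, phenotype) pair separately in females and males on pairwise
#' complete observations ([spearman_test()]). Pairs with fewer than `min_n`
#' complete observations in either sex, or with a constant variable, are
#' skipped and recorded in the `"skipped"` attribute. Each reported pair is
#' categorized at level `alpha`: `both-same-direction` when significant in
#' both sexes with equal rho signs, `both-opposite-direction` when the
#' signs differ, `female-only` / `male-only` when exactly one sex is
#' significant, else `ns`.
#'
#' @param table An imputed [abundance_table()].
#' @param pheno Numeric matrix samples x phenotypes (after
#'   [impute_phenotype_min()], typically).
#' @param meta Validated sample metadata.
#' @param alpha Significance level for categorization.
#' @param min_n Minimum complete observations per sex (the "more than 14
#'   data points" rule, read strictly: n >= 15).
#' @return Tibble: `feature_id`, `phenotype_id`, `rho_F`, `p_F`, `n_F`,
#'   `rho_M`, `p_M`, `n_M`, `category`; attribute `"skipped"` holds the
#'   excluded pairs with the reason.
#' @export
spearman_by_sex <- function(table, pheno, meta, alpha = 0.05, min_n = 15) {
  stopifnot(inherits(table, "abundance_table"))
  wt <- meta[meta$role == "study" & meta$genotype == "WT", ]
  res <- lapply(c("F", "M"), function(s) {
    ids <- intersect(wt$sample_id[wt$sex == s], rownames(pheno))
    .spearman_matrix(table$values[ids, , drop = FALSE],
                     pheno[ids, , drop = FALSE])
  })
  f <- res[[1]]; m <- res[[2]]
  out <- tibble::tibble(
    feature_id = rep(colnames(table$values), times = ncol(pheno)),
    phenotype_id = rep(colnames(pheno), each = ncol(table$values)),
    rho_F = as.vector(f$rho), p_F = as.vector(f$p), n_F = as.vector(f$n),
    rho_M = as.vector(m$rho), p_M = as.vector(m$p), n_M = as.vector(m$n))
  low_n <- out$n_F < min_n | out$n_M < min_n
  undef <- !low_n & (is.na(out$rho_F) | is.na(out$rho_M))
  skipped <- out[low_n | undef, c("feature_id", "phenotype_id")]
  skipped$reason <- ifelse(low_n[low_n | undef], "insufficient-n",
                           "constant-variable")
  out <- out[!(low_n | undef), ]
  sig_f <- out$p_F < alpha
  sig_m <- out$p_M < alpha
  out$category <- ifelse(sig_f & sig_m,
                         ifelse(sign(out$rho_F) == sign(out$rho_M),
                                "both-same-direction", "both-opposite-direction"),
                         ifelse(sig_f, "female-only",
                                ifelse(sig_m, "male-only", "ns")))
  attr(out, "skipped") <- skipped
  out
}

# Spearman rho/p/n matrices for all column pairs of X (features) and P
# (phenotypes). Fast path (rank once, correlate) when a pair is complete;
# per-pair ranking otherwise so pairwise-complete ranks stay exact.
.spearman_matrix <- function(X, P) {
  n_obs <- crossprod(!is.na(X), !is.na(P))      # complete pairs per (f, p)
  RX <- apply(X, 2, .avg_rank)
  RP <- apply(P, 2, .avg_rank)
  suppressWarnings(rho <- stats::cor(RX, RP, use = "pairwise.complete.obs"))
  # redo pairs with missing data: ranks must be computed on complete cases
  redo <- which(n_obs < nrow(X) & n_obs >= 3, arr.ind = TRUE)
  for (k in seq_len(nrow(redo))) {
    i <- redo[k, 1]; j <- redo[k, 2]
    st <- spearman_test(X[, i], P[, j])
    rho[i, j] <- st$rho
  }
  rho[n_obs < 3] <- NA_real_
  sd0 <- outer(apply(RX, 2, stats::sd) == 0, apply(RP, 2, stats::sd) == 0, `|`)
  rho[sd0 & n_obs == nrow(X)] <- NA_real_
  p <- .spearman_t_p(rho, n_obs)
  p[is.na(rho)] <- NA_real_
  list(rho = rho, p = p, n = n_obs)
}

#' Summarize correlation dimorphism categories
#'
#' @param results Output of [spearman_by_sex()].
#' @return One-row tibble: `n_tested`, `n_significant` (union over sexes =
#'   sum of the four non-ns categories), `pct_significant` (of tested, one
#'   decimal), per-category counts, and `pct_both_same` /
#'   `pct_both_opposite` as percentages of the significant correlations.
#' @export
categorize_summary <- function(results) {
  cnt <- function(k) sum(results$category == k)
  n_sig <- sum(results$category != "ns")
  n <- nrow(results)
  tibble::tibble(
    n_tested = n,
    n_significant = n_sig,
    pct_significant = if (n == 0) 0 else round(100 * n_sig / n, 1),
    n_female_only = cnt("female-only"),
    n_male_only = cnt("male-only"),
    n_both_same = cnt("both-same-direction"),
    n_both_opposite = cnt("both-opposite-direction"),
    pct_both_same =
      if (n_sig == 0) 0 else round(100 * cnt("both-same-direction") / n_sig, 1),
    pct_both_opposite =
      if (n_sig == 0) 0 else round(100 * cnt("both-opposite-direction") / n_sig, 1))
}

#' Cluster-level metabolite-phenotype association matrix
#'
#' For every (phenotype, sex, cluster) cell, runs the chemical-cluster
#' enrichment of that sex's correlation p-values ([enrich_clusters()]) and
#' signs the -log10 KS p by the median rho of the cluster's significant
#' members -- the long-format table behind a red/blue association heatmap.
#' The tested cluster set is fixed globally (clusters with at least
#' `min_size` annotated features), so the output has exactly
#' |phenotypes| x |tested clusters| x 2 rows; cells where a cluster has no
#' member p-values for that phenotype carry `NA`.
#'
#' @param results Output of [spearman_by_sex()].
#' @param clusters Named character vector feature id -> cluster label.
#' @param alpha Member-level significance.
#' @param min_size Minimum cluster size.
#' @return Tibble: `phenotype_id`, `cluster`, `sex`, `size`, `ks_p`,
#'   `signed_score` (sign(median rho of significant members) x
#'   -log10 ks_p; 0-signed when no member is significant).
#' @export
cluster_phenotype_matrix <- function(results, clusters, alpha = 0.05,
                                     min_size = 3) {
  feat_univ <- unique(results$feature_id)
  cl_univ <- clusters[feat_univ]
  sizes <- table(cl_univ[!is.na(cl_univ)])
  tested <- sort(as.character(names(sizes)[sizes >= min_size]))
  phenos <- unique(results$phenotype_id)
  empty <- tibble::tibble(phenotype_id = character(), cluster = character(),
                          sex = character(), size = integer(),
                          ks_p = double(), signed_score = double())
  if (!length(tested) || !length(phenos)) return(empty)
  grid <- expand.grid(phenotype_id = phenos, cluster = tested,
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  rows <- lapply(phenos, function(ph) {
    sub <- results[results$phenotype_id == ph, ]
    lapply(c("F", "M"), function(s) {
      p <- if (s == "F") sub$p_F else sub$p_M
      rho <- if (s == "F") sub$rho_F else sub$rho_M
      names(p) <- names(rho) <- sub$feature_id
      enr <- enrich_clusters(p, sign(rho), clusters,
                             alpha = alpha, min_size = min_size)
      med_rho <- vapply(enr$cluster, function(g) {
        ids <- sub$feature_id[!is.na(cl_univ[sub$feature_id]) &
                                cl_univ[sub$feature_id] == g]
        sig <- ids[p[ids] < alpha]
        if (!length(sig)) 0 else stats::median(rho[sig])
      }, numeric(1))
      tibble::tibble(phenotype_id = ph, cluster = enr$cluster, sex = s,
                     size = enr$size, ks_p = enr$ks_p,
                     signed_score = sign(med_rho) * -log10(enr$ks_p))
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  full <- tibble::as_tibble(grid)
  out <- dplyr::left_join(full, out,
                          by = c("phenotype_id", "cluster", "sex"))
  out[order(out$phenotype_id, out$cluster, out$sex), ]
}
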