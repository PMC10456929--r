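# Chemical-cluster enrichment: per-cluster one-sided Kolmogorov-Smirnov
# test of member p-values against uniformity, with BH FDR across clusters.

#' Chemical-cluster enrichment of per-feature p-values
#'
#' For each non-overlapping chemical cluster with at least `min_size`
#' members carrying a defined p-value, tests whether the member p-values
#' are shifted toward zero relative to Uniform(0, 1) with a one-sided
#' Kolmogorov-Smirnov statistic ([ks_uniform()]), then adjusts across the
#' tested clusters by Benjamini-Hochberg. A cluster is conventionally
#' called significant at `ks_p < alpha` or `q_value < alpha`.
#'
#' @param member_p Named numeric vector of per-feature p-values (names =
#'   feature ids).
#' @param member_direction Named numeric vector of per-feature direction
#'   signs (+1 increased, -1 decreased), aligned with `member_p`.
#' @param clusters Named character vector mapping feature id to cluster
#'   label (features absent or with `NA` cluster are excluded from
#'   enrichment only).
#' @param alpha Member-level significance used for the altered/increased
#'   fractions.
#' @param min_size Minimum cluster size tested.
#' @return Tibble with one row per tested cluster: `cluster`, `size`,
#'   `ks_p`, `q_value`, `altered_fraction` (members with p < alpha),
#'   `increased_fraction` (among altered members, fraction with positive
#'   direction; `NA` when none altered), `key_compound` (member with the
#'   smallest p). Clusters below `min_size` are recorded in the
#'   `"excluded"` attribute. Impact-plot coordinates can be derived as
#'   x = direction score, y = -log10(ks_p), size = `size`.
#' @export
enrich_clusters <- function(member_p, member_direction, clusters,
                            alpha = 0.05, min_size = 3) {
  stopifnot(!is.null(names(member_p)))
  keep <- names(member_p)[!is.na(member_p)]
  cl <- clusters[keep]
  keep <- keep[!is.na(cl)]
  cl <- clusters[keep]
  if (!length(keep)) {
    out <- tibble::tibble(cluster = character(), size = integer(),
                          ks_p = double(), q_value = double(),
                          altered_fraction = double(),
                          increased_fraction = double(),
                          key_compound = character())
    attr(out, "excluded") <- character()
    return(out)
  }
  sizes <- table(cl)
  tested <- names(sizes)[sizes >= min_size]
  excluded <- names(sizes)[sizes < min_size]
  rows <- lapply(tested, function(g) {
    ids <- keep[cl == g]
    p <- member_p[ids]
    d <- member_direction[ids]
    ks <- ks_uniform(p)
    alt <- p < alpha
    tibble::tibble(
      cluster = g, size = length(ids), ks_p = ks$p,
      altered_fraction = mean(alt),
      increased_fraction = if (any(alt)) mean(d[alt] > 0) else NA_real_,
      key_compound = ids[which.min(p)])
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$ks_p)
  out <- out[order(out$ks_p), c("cluster", "size", "ks_p", "q_value",
                                "altered_fraction", "increased_fraction",
                                "key_compound")]
  attr(out, "excluded") <- excluded
  out
}
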