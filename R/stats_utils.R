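# Shared statistical primitives: BH step-up, Spearman with t-approximation,
# one-sided uniform KS, and RSS-based nested F machinery.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics p_(1) <= ... <= p_(m),
#' q_(i) = min_{j >= i} min(1, m p_(j) / j). `NA` p-values are left `NA` and
#' excluded from `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pp <- p[ok]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pp)
  o <- order(pp, decreasing = TRUE)          # largest first
  adj <- pmin(1, cummin(m / seq(m, 1) * pp[o]))
  q[ok] <- adj[order(o)]
  q
}

# Average ranks (ties share the mean rank); NA stays NA.
.avg_rank <- function(x) rank(x, ties.method = "average", na.last = "keep")

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the Pearson correlation of average ranks on pairwise
#' complete observations. The two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom; for
#' n < 10 an exact permutation p-value is computed instead (all n!
#' permutations of one vector).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, `n` (complete pairs). `rho` is `NA` when
#'   either variable is constant on the complete pairs.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- .avg_rank(x); ry <- .avg_rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    p <- .spearman_perm_p(rx, ry, rho)
  } else {
    p <- .spearman_t_p(rho, n)
  }
  list(rho = rho, p = p, n = n)
}

.spearman_t_p <- function(rho, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

# Exact two-sided permutation p for small n (enumerates all permutations).
.spearman_perm_p <- function(rx, ry, rho_obs) {
  perms <- .all_permutations(length(ry))
  ry_c <- ry - mean(ry); rx_c <- rx - mean(rx)
  denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  rs <- apply(perms, 1, function(idx) sum(rx_c * ry_c[idx]) / denom)
  mean(abs(rs) >= abs(rho_obs) - 1e-12)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' One-sided Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' Tests whether a vector of p-values is shifted toward small values
#' relative to the uniform distribution (the enrichment direction of
#' interest): D+ = max_i (i/n - p_(i)).
#'
#' @param p Numeric vector of p-values.
#' @return List with `statistic` (D+) and `p` (one-sided).
#' @export
ks_uniform <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p <- p[!is.na(p)]
  if (length(p) < 1) return(list(statistic = NA_real_, p = NA_real_))
  kt <- suppressWarnings(
    stats::ks.test(p, "punif", alternative = "greater"))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

# Residual sums of squares of every column of Y under design X, via QR.
.rss_matrix <- function(X, Y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(rep(NA_real_, ncol(Y)))
  colSums(qr.resid(qrx, Y)^2)
}

#' Nested-model F test by ordinary least squares
#'
#' Fits the full and null linear models by least squares and compares them
#' with F = ((RSS0 - RSS1) / d_extra) / (RSS1 / df_resid), where d_extra is
#' the number of additional parameters in the full model.
#'
#' @param y Numeric response vector.
#' @param data Data frame of model variables.
#' @param full,null Model formulas (right-hand sides over `data`); `null`
#'   must be nested in `full`.
#' @return The p-value, with attributes `statistic`, `df1`, `df2`. `NA` (with
#'   a warning) when the full design is rank deficient.
#' @export
nested_f_test <- function(y, data, full, null) {
  X1 <- stats::model.matrix(full, data)
  X0 <- stats::model.matrix(null, data)
  if (ncol(X0) >= ncol(X1)) stop("`null` must be strictly nested in `full`")
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    warning("rank-deficient full design; p undefined")
    return(structure(NA_real_, statistic = NA_real_, df1 = NA, df2 = NA))
  }
  rss1 <- sum(qr.resid(q1, y)^2)
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(fstat)) fstat <- 0
  fstat <- max(fstat, 0)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  structure(p, statistic = fstat, df1 = df1, df2 = df2)
}

# Vectorized pooled (or Welch) two-group comparison across columns of a
# matrix: rows of `a` are group-1 samples, rows of `b` group 2.
.two_group_test <- function(a, b, welch = FALSE) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tval <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p[se2 == 0] <- 1                     # degenerate: no variance at all
  list(p = p, estimate = m1 - m2, mean1 = m1, mean2 = m2)
}
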