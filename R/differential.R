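#' Assemble per-sample editing levels and coverage for a site catalog
#'
#' @param counts_per_sample named list of `base_counts` from
#'   [count_at_sites()] on one shared catalog.
#' @param catalog the `site_catalog` used.
#' @return object of class `sample_levels`: `levels` and `coverage`
#'   matrices (sites x samples; level is `NA` where the informative
#'   coverage is zero), plus `sites` (catalog data frame).
#' @export
sample_levels <- function(counts_per_sample, catalog) {
  stopifnot(length(counts_per_sample) >= 1L)
  lv <- vapply(counts_per_sample, site_level, numeric(nrow(catalog)))
  m_inf <- vapply(counts_per_sample, function(x) {
    m <- base_count_matrix(x)
    as.numeric(ifelse(x$strand == "+", m[, "A"] + m[, "G"], m[, "T"] + m[, "C"]))
  }, numeric(nrow(catalog)))
  lv <- matrix(lv, nrow = nrow(catalog),
               dimnames = list(NULL, names(counts_per_sample)))
  cov <- matrix(m_inf, nrow = nrow(catalog),
                dimnames = list(NULL, names(counts_per_sample)))
  structure(list(levels = lv, coverage = cov, sites = as.data.frame(catalog)),
            class = "sample_levels")
}

#' Construct sample levels from plain matrices
#' @param levels,coverage sites x samples matrices.
#' @param sites data frame of site annotation (one row per matrix row).
#' @return a `sample_levels` object.
#' @export
sample_levels_from_matrices <- function(levels, coverage, sites = NULL) {
  stopifnot(all(dim(levels) == dim(coverage)))
  if (is.null(sites))
    sites <- data.frame(chrom = "site", pos = seq_len(nrow(levels)) - 1L)
  structure(list(levels = levels, coverage = coverage, sites = sites),
            class = "sample_levels")
}

#' Coverage-eligible sites for differential testing
#'
#' A site is eligible when, in each group separately, at least
#' `ceiling(min_frac * n_group)` samples (or `min_samples`, when given as
#' an absolute count) have coverage at least `min_cov`.
#'
#' @param group1,group2 `sample_levels` objects over the same site list.
#' @param min_cov minimum per-sample read coverage (default 10).
#' @param min_frac minimum fraction of samples per group meeting it
#'   (default 0.5).
#' @param min_samples absolute per-group sample count overriding
#'   `min_frac` when non-`NULL`.
#' @return integer vector of eligible site row indices.
#' @export
eligible_sites <- function(group1, group2, min_cov = 10L, min_frac = 0.5,
                           min_samples = NULL) {
  n1 <- ncol(group1$coverage); n2 <- ncol(group2$coverage)
  if (n1 == 0L || n2 == 0L) stop2("both groups must contain samples")
  need1 <- if (is.null(min_samples)) ceiling(min_frac * n1) else min_samples
  need2 <- if (is.null(min_samples)) ceiling(min_frac * n2) else min_samples
  ok1 <- rowSums(group1$coverage >= min_cov) >= need1
  ok2 <- rowSums(group2$coverage >= min_cov) >= need2
  which(ok1 & ok2)
}

#' Two-tailed Mann-Whitney U test
#'
#' `U = #\{(i,j): x_i < y_j\} + 1/2 #ties`. The two-sided p-value is exact
#' (full enumeration of rank assignments) when `n1 + n2 <= 12` and there
#' are no ties, otherwise a normal approximation with tie and continuity
#' corrections is used.
#'
#' @param x,y numeric samples (missing values dropped).
#' @return list with `U`, `p_value` and `method` (`"exact"`/`"normal"`).
#' @export
mw_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop2("mw_test needs at least one observation per group")
  U <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 + n2 <= 12L && !ties) {
    # exact null distribution of U by enumerating which ranks go to y
    ranks_y <- combn(n1 + n2, n2)
    u_all <- colSums(ranks_y) - n2 * (n2 + 1) / 2
    # two-sided: double the smaller tail (null distribution is symmetric)
    p <- min(1, 2 * mean(u_all <= min(U, n1 * n2 - U) + 1e-9))
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    tie_tab <- table(r)
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' sorted ascending, `adj_(k) = min_{j >= k} p_(j) m / j`, capped at 1,
#' returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential editing table
#'
#' For each coverage-eligible site: delta editing (mean of group 2 minus
#' mean of group 1, so with groups given in (reference, comparison) order a
#' positive delta means more editing in the comparison group), the
#' Mann-Whitney U statistic and two-sided p, and Benjamini-Hochberg
#' adjusted p over the eligible set. Rows are sorted by adjusted p.
#'
#' @param group1,group2 `sample_levels` over the same sites.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param min_cov,min_frac,min_samples eligibility rules, see
#'   [eligible_sites()].
#' @return data frame of class `diff_table`: site annotation plus
#'   `mean1, mean2, delta, n1, n2, U, p_value, p_adj, direction`
#'   (`up` = higher in group 2, `down` = lower, `ns` otherwise).
#' @export
diff_table <- function(group1, group2, alpha = 0.05, min_cov = 10L,
                       min_frac = 0.5, min_samples = NULL) {
  idx <- eligible_sites(group1, group2, min_cov, min_frac, min_samples)
  out <- diff_test_rows(group1, group2, idx, min_cov)
  finalize_diff_table(out, alpha)
}

diff_test_rows <- function(group1, group2, idx, min_cov) {
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    x <- group1$levels[i, ]; x <- x[!is.na(x) & group1$coverage[i, ] >= min_cov]
    y <- group2$levels[i, ]; y <- y[!is.na(y) & group2$coverage[i, ] >= min_cov]
    if (length(x) == 0L || length(y) == 0L) next
    tst <- mw_test(x, y)
    site <- group1$sites[i, , drop = FALSE]
    rows[[k]] <- cbind(site,
                       data.frame(site_index = i,
                                  mean1 = mean(x), mean2 = mean(y),
                                  delta = mean(y) - mean(x),
                                  n1 = length(x), n2 = length(y),
                                  U = tst$U, p_value = tst$p_value,
                                  stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

finalize_diff_table <- function(out, alpha) {
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(site_index = integer(), mean1 = numeric(),
                      mean2 = numeric(), delta = numeric(), n1 = integer(),
                      n2 = integer(), U = numeric(), p_value = numeric(),
                      p_adj = numeric(), direction = character())
    class(out) <- c("diff_table", "data.frame")
    return(out)
  }
  out$p_adj <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$p_adj < alpha,
                          ifelse(out$delta > 0, "up", "down"), "ns")
  out <- out[order(out$p_adj, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Coverage-ranked Wilcoxon differential procedure
#'
#' Variant procedure: sites are ranked by total read coverage (descending)
#' and the rank-sum test is applied only where at least `min_samples`
#' samples per group meet the depth requirement; the same U/BH machinery
#' as [diff_table()] is used.
#'
#' @param group1,group2 `sample_levels` over the same sites.
#' @param min_cov required per-sample depth (default 10).
#' @param min_samples minimum qualifying samples per group (default 5).
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @return a `diff_table` with a `total_coverage` column, ordered by
#'   descending coverage.
#' @export
ranked_wilcoxon <- function(group1, group2, min_cov = 10L, min_samples = 5L,
                            alpha = 0.05) {
  total_cov <- rowSums(group1$coverage) + rowSums(group2$coverage)
  ok <- rowSums(group1$coverage >= min_cov) >= min_samples &
    rowSums(group2$coverage >= min_cov) >= min_samples
  idx <- which(ok)[order(total_cov[ok], decreasing = TRUE)]
  out <- diff_test_rows(group1, group2, idx, min_cov)
  out <- finalize_diff_table(out, alpha)
  if (nrow(out)) {
    out$total_coverage <- total_cov[out$site_index]
    out <- out[order(out$total_coverage, decreasing = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$total_coverage <- numeric()
  }
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, n = 10L, ...) {
  cat(sprintf("<diff_table> %d tested site(s), %d significant\n",
              nrow(x), sum(x$direction != "ns")))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}
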