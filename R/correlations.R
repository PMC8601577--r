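#' Bonferroni-corrected significance threshold for a test family
#'
#' @param family_size Number of tests in the family: 13 for one-per-subtest
#'   comparisons, 26 for both age cohorts, 78 for all subtest pairs
#'   (13 choose 2).
#' @param alpha Family-wise error rate (default .05).
#' @return The per-test threshold `alpha / family_size`.
#' @examples
#' round(bonferroni_threshold(13), 4)  # 0.0038
#' @export
bonferroni_threshold <- function(family_size, alpha = 0.05) {
  stopifnot(family_size >= 1)
  alpha / family_size
}

#' Pairwise Pearson correlation matrix with Bonferroni control
#'
#' All pairwise correlations between subtest accuracy columns, computed on
#' complete pairwise observations, with two-sided p-values and a
#' significance mask at the Bonferroni-corrected threshold alpha / C(m, 2)
#' (.05 / 78 for the 13 subtests). Pairs with fewer than 4 complete rows
#' are returned as `NA` (unavailable).
#'
#' @param accuracies Numeric data.frame/matrix, one column per subtest.
#' @param alpha Family-wise error rate (default .05).
#' @return List of class `corr_matrix_result`: symmetric matrices `r`, `p`,
#'   `n`, logical `significant`, and `alpha_family`.
#' @export
pearson_matrix_bonferroni <- function(accuracies, alpha = 0.05) {
  x <- as.matrix(accuracies)
  m <- ncol(x)
  family <- choose(m, 2)
  r <- p <- nmat <- matrix(NA_real_, m, m,
                           dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1; diag(p) <- 0
  diag(nmat) <- colSums(!is.na(x))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      ok <- stats::complete.cases(x[, c(i, j)])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 4) next
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  thr <- bonferroni_threshold(family, alpha)
  structure(list(r = r, p = p, n = nmat, alpha_family = thr,
                 significant = !is.na(p) & p < thr),
            class = "corr_matrix_result")
}

#' Partial correlation matrix controlling for a severity covariate
#'
#' First-order partial Pearson correlations between subtest accuracies,
#' removing variance shared with an independent severity measure (e.g. the
#' total of an established aphasia battery):
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' Each pairwise computation uses rows complete for x, y and z. Two-sided
#' p-values use the t distribution with n - 3 degrees of freedom; the
#' Bonferroni family is the same as for the raw matrix. A pair in which a
#' variable is collinear with the covariate (|r| = 1) is undefined and
#' returned `NA`.
#'
#' @param accuracies Numeric data.frame/matrix, one column per subtest.
#' @param covariate Numeric vector (one value per row of `accuracies`).
#' @param alpha Family-wise error rate (default .05).
#' @return List of class `corr_matrix_result` (see
#'   [pearson_matrix_bonferroni()]).
#' @export
partial_corr_matrix <- function(accuracies, covariate, alpha = 0.05) {
  x <- as.matrix(accuracies)
  if (length(covariate) != nrow(x)) {
    stop("covariate must have one value per participant row", call. = FALSE)
  }
  m <- ncol(x)
  family <- choose(m, 2)
  r <- p <- nmat <- matrix(NA_real_, m, m,
                           dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      ok <- stats::complete.cases(cbind(x[, c(i, j)], covariate))
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 5) next
      rxy <- stats::cor(x[ok, i], x[ok, j])
      rxz <- stats::cor(x[ok, i], covariate[ok])
      ryz <- stats::cor(x[ok, j], covariate[ok])
      if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) next
      pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      pr <- min(1, max(-1, pr))
      df <- nij - 3
      tval <- pr * sqrt(df / (1 - pr^2))
      r[i, j] <- r[j, i] <- pr
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tval), df)
    }
  }
  thr <- bonferroni_threshold(family, alpha)
  structure(list(r = r, p = p, n = nmat, alpha_family = thr,
                 significant = !is.na(p) & p < thr),
            class = "corr_matrix_result")
}

#' @export
print.corr_matrix_result <- function(x, ...) {
  m <- ncol(x$r)
  cat(sprintf(
    "Correlation matrix over %d measures; Bonferroni threshold %.4g; %d of %d pairs significant\n",
    m, x$alpha_family, sum(x$significant[upper.tri(x$significant)]),
    choose(m, 2)))
  invisible(x)
}

#' Long (heat-map-ready) format for a correlation matrix result
#'
#' @param x A `corr_matrix_result`.
#' @return Data.frame: `var1`, `var2`, `r`, `p`, `n`, `significant`, upper
#'   triangle only.
#' @export
corr_matrix_long <- function(x) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(var1 = rownames(x$r)[idx[, 1]], var2 = colnames(x$r)[idx[, 2]],
             r = x$r[idx], p = x$p[idx], n = x$n[idx],
             significant = x$significant[idx], stringsAsFactors = FALSE)
}

#' Welch's unequal-variances t-test for two groups
#'
#' Thin wrapper over [stats::t.test()] (two-sided, `var.equal = FALSE`,
#' Satterthwaite degrees of freedom) returning the quantities used in group
#' comparisons; pair with [bonferroni_threshold()] for families of 13 (one
#' cohort) or 26 (both cohorts) subtest comparisons.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2, positive variance).
#' @return List: `t`, `df`, `p`, group means.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop("both groups have zero variance; Welch test undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Fisher's exact test on an impaired/normal by subgroup table
#'
#' Exact two-sided test of association in a 2x2 contingency table, e.g.
#' counts of patients above/below a subtest cutoff in two clinical
#' subgroups. Delegates to [stats::fisher.test()] (hypergeometric
#' enumeration).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact p-value.
#' @export
fisher_exact_cutoff <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop("a 2x2 matrix of non-negative integer counts is required",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("empty row/column margin; association undefined", call. = FALSE)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Kruskal-Wallis plus Dunn's post-hoc age-group pooling
#'
#' Tests whether preliminary age groups differ on a score and recommends
#' which groups can be pooled into cohorts: the omnibus Kruskal-Wallis test
#' (tie-corrected) is followed by pairwise Dunn z tests on the joint ranks
#' with Holm adjustment, and groups connected by non-significant pairwise
#' differences are merged (connected components of the non-significance
#' graph).
#'
#' @param scores Numeric vector of scores.
#' @param groups Factor/character of group labels (each group n >= 2).
#' @param alpha Significance level for pooling decisions (default .05).
#' @return List: `kw` (`H`, `df`, `p`), data.frame `dunn` (`group1`,
#'   `group2`, `z`, `p`, `p_holm`, `significant`), and `pooling` — a list of
#'   character vectors, the recommended merged groups.
#' @export
kruskal_dunn_pooling <- function(scores, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  kw <- stats::kruskal.test(scores, factor(groups))
  n <- length(scores)
  rk <- rank(scores)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, groups, mean)
  n_g <- table(groups)
  pairs <- utils::combn(lv, 2)
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     stringsAsFactors = FALSE)
  dunn$z <- mapply(function(g1, g2) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[g1] + 1 / n_g[g2]))
    (mean_rank[g1] - mean_rank[g2]) / se
  }, dunn$group1, dunn$group2)
  dunn$p <- 2 * stats::pnorm(-abs(dunn$z))
  dunn$p_holm <- stats::p.adjust(dunn$p, method = "holm")
  dunn$significant <- dunn$p_holm < alpha
  # merge groups joined by non-significant pairwise differences
  parent <- stats::setNames(lv, lv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(dunn))) {
    if (!dunn$significant[i]) {
      parent[find(dunn$group1[i])] <- find(dunn$group2[i])
    }
  }
  roots <- vapply(lv, find, character(1))
  pooling <- unname(split(lv, roots))
  list(kw = list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value),
       dunn = dunn, pooling = pooling)
}
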