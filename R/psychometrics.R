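#' Item passing rates (difficulty indices)
#'
#' The passing rate of an item is its mean score across patients,
#' normalized by the per-item maximum, giving a difficulty index in `[0, 1]`.
#' Computed on patient data: control performance is near ceiling and
#' uninformative about item difficulty.
#'
#' @param matrix Numeric participants x items matrix of item scores
#'   (patients only). `NA`s are dropped per item.
#' @param item_max Per-item maximum score (scalar or per-item vector).
#' @return Named numeric vector of per-item rates in `[0, 1]`.
#' @export
item_passing_rates <- function(matrix, item_max = 1) {
  matrix <- as.matrix(matrix)
  if (any(colSums(!is.na(matrix)) == 0)) {
    stop("item(s) with no observed scores: ",
         paste(which(colSums(!is.na(matrix)) == 0), collapse = ", "),
         call. = FALSE)
  }
  rates <- colMeans(matrix, na.rm = TRUE) / item_max
  if (any(rates < 0 | rates > 1)) {
    stop("scores exceed the declared item_max", call. = FALSE)
  }
  rates
}

#' Corrected item-total correlations (discriminability indices)
#'
#' Pearson correlation of each item with the subtest total excluding that
#' item. Items correlating below 0.2 with the rest of their subtest are
#' flagged as poorly discriminating. Zero-variance items have an undefined
#' correlation; they are returned as `NA`, flagged, and excluded from any
#' summary, with a warning.
#'
#' @param matrix Numeric participants x items matrix (complete rows).
#' @param flag_below Discriminability flag threshold (default 0.2).
#' @return Data.frame: `item`, `r`, `flagged` (r below threshold or
#'   undefined).
#' @export
corrected_item_total <- function(matrix, flag_below = 0.2) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 3) {
    stop("item-total correlations need at least 3 participants",
         call. = FALSE)
  }
  total <- rowSums(matrix)
  r <- vapply(seq_len(ncol(matrix)), function(j) {
    item <- matrix[, j]
    if (stats::sd(item) == 0) return(NA_real_)
    stats::cor(item, total - item)
  }, numeric(1))
  if (anyNA(r)) {
    warning("zero-variance item(s) have undefined item-total correlation: ",
            paste(which(is.na(r)), collapse = ", "), call. = FALSE)
  }
  data.frame(item = colnames(matrix) %||% seq_along(r), r = r,
             flagged = is.na(r) | r < flag_below, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Internal-consistency reliability of a subtest's item scores:
#' alpha = k/(k-1) * (1 - sum(var_item)/var_total). The default confidence
#' interval uses Feldt's F-distribution method; a nonparametric bootstrap
#' over participants is available as an alternative. Rows with missing
#' values are dropped (listwise). Items with zero variance contribute
#' nothing to covariance and are retained; a total score with zero variance
#' is an error.
#'
#' @param matrix Numeric participants x items matrix.
#' @param conf Confidence level (default 0.95).
#' @param ci `"feldt"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @return List of class `reliability_estimate`: `statistic`, `value`,
#'   `ci_low`, `ci_high`, `n`, `k`.
#' @export
cronbach_alpha <- function(matrix, conf = 0.95, ci = c("feldt", "bootstrap"),
                           n_boot = 1000) {
  ci <- match.arg(ci)
  matrix <- as.matrix(matrix)
  matrix <- matrix[stats::complete.cases(matrix), , drop = FALSE]
  n <- nrow(matrix); k <- ncol(matrix)
  if (k < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (n < 3) stop("alpha needs at least 3 complete rows", call. = FALSE)
  alpha_of <- function(m) {
    vt <- stats::var(rowSums(m))
    if (vt == 0) stop("total score has zero variance; alpha undefined",
                      call. = FALSE)
    (ncol(m) / (ncol(m) - 1)) * (1 - sum(apply(m, 2, stats::var)) / vt)
  }
  a <- alpha_of(matrix)
  lo <- (1 - conf) / 2
  if (ci == "feldt") {
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    ci_low <- 1 - (1 - a) * stats::qf(1 - lo, df1, df2)
    ci_high <- 1 - (1 - a) * stats::qf(lo, df1, df2)
  } else {
    boots <- vapply(seq_len(n_boot), function(i) {
      alpha_of(matrix[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    qs <- stats::quantile(boots, c(lo, 1 - lo), names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  }
  reliability_estimate("cronbach_alpha", a, ci_low, ci_high, n, k = k)
}

#' Intraclass correlation ICC(A,1): two-way random, absolute agreement,
#' single measure
#'
#' The reliability coefficient used for inter-rater and test-retest
#' analyses: participants and raters (or sessions) are both treated as
#' random effects and systematic differences between columns count against
#' agreement. From the two-way ANOVA mean squares (rows = participants,
#' columns = raters/sessions):
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#' The confidence interval uses the F-based formulas of McGraw & Wong with
#' Satterthwaite denominator degrees of freedom.
#'
#' @param ratings Numeric participants x raters (or sessions) matrix;
#'   rows with missing values are dropped (listwise).
#' @param conf Confidence level (default 0.95).
#' @return List of class `reliability_estimate`: `statistic`, `value`,
#'   `ci_low`, `ci_high`, `n`, `k`.
#' @examples
#' m <- cbind(c(1, 3, 5, 7), c(2, 3, 5, 8))
#' icc_a1(m)$value
#' @export
icc_a1 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("ICC needs at least 2 raters/sessions", call. = FALSE)
  if (n < 3) stop("ICC needs at least 3 participants", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) {
    stop("zero between-participant variance; ICC undefined", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  lo <- (1 - conf) / 2
  fl <- stats::qf(1 - lo, n - 1, v)
  fu <- stats::qf(1 - lo, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  est <- reliability_estimate("icc_a1", icc, ci_low, ci_high, n, k = k)
  est$ms <- c(msr = msr, msc = msc, mse = mse)
  est
}

reliability_estimate <- function(statistic, value, ci_low, ci_high, n,
                                 k = NA_integer_) {
  structure(list(statistic = statistic, value = value,
                 ci_low = min(ci_low, value), ci_high = max(ci_high, value),
                 n = n, k = k),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f, 95%% CI [%.3f, %.3f] (n = %d)\n",
              x$statistic, x$value, x$ci_low, x$ci_high, x$n))
  invisible(x)
}
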