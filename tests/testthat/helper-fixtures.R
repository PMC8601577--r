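# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (explicit sums, enumeration) so they share no code
# path with the implementation they check.

# type-7 quantile from the order-statistic definition
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# two-way ANOVA mean squares via stats::aov -- an independent route to the
# ICC(A,1) components
anova_ms_oracle <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  c(msr = tab["subj", "Mean Sq"], msc = tab["rater", "Mean Sq"],
    mse = tab["Residuals", "Mean Sq"])
}

# exhaustive ROC threshold scan: every midpoint, every observed value, and
# far sentinels, positive = value <= threshold
roc_scan_oracle <- function(nhi, pwa) {
  vals <- sort(unique(c(nhi, pwa)))
  cand <- sort(unique(c(vals, (vals[-1] + vals[-length(vals)]) / 2,
                        min(vals) - 1, max(vals) + 1)))
  j <- vapply(cand, function(th) mean(pwa <= th) + mean(nhi > th),
              numeric(1))
  list(best_j = max(j),
       best_at = cand[j == max(j)])
}

# two-sided Fisher p by full hypergeometric enumeration over tables with
# the observed margins
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one complete, perfectly scored battery for one participant in the trial
# dialect; individual tests then degrade specific items
perfect_trials <- function(participant_id = "p01", group = "PWA",
                           age_cohort = "young") {
  cat13 <- subtest_catalogue()
  sr_words <- attr(cat13, "sr_word_counts")
  rows <- lapply(SUBTEST_IDS, function(st) {
    def <- cat13[cat13$subtest_id == st, ]
    n_units <- switch(st, discourse_comprehension = 16L,
                      discourse_production = 1L, def$n_items)
    d <- data.frame(participant_id = participant_id, group = group,
                    age_cohort = age_cohort, subtest_id = st,
                    item_id = sprintf("i%02d", seq_len(n_units)),
                    response = NA, code = NA_character_,
                    word_codes = NA_character_, order_error = NA,
                    criteria = NA_character_, ratings = NA_character_,
                    stringsAsFactors = FALSE)
    if (def$rule %in% c("binary", "naming") ||
        startsWith(def$rule, "discourse_comprehension")) {
      d$response <- 1
    } else if (def$rule == "repetition") {
      d$code <- "correct"
    } else if (def$rule == "sentence_repetition") {
      d$word_codes <- vapply(sr_words, function(nw)
        paste(rep("correct", nw), collapse = ";"), "")
      d$order_error <- 0
    } else if (def$rule == "criteria") {
      d$criteria <- "1;1;1;1"
    } else if (def$rule == "ratings") {
      d$ratings <- "5;5;5;5"
    }
    d
  })
  do.call(rbind, rows)
}

# independent vectorized re-derivation of the sentence-repetition accuracy
# distribution under the control model (young cohort): used as the
# large-sample reference for cutoff recovery checks
sr_ref_draw <- function(n, spec) {
  b <- spec$subtest_params[
    spec$subtest_params$subtest_id == "sentence_repetition", ]
  theta <- rnorm(n, spec$nhi_theta_mean, spec$nhi_theta_sd) +
    rnorm(n, 0, b$resid_sd)
  nw <- attr(subtest_catalogue(), "sr_word_counts")
  z <- qnorm((seq_along(nw) - 0.5) / length(nw))
  total <- matrix(0, n, length(nw))
  for (s in seq_along(nw)) {
    p <- plogis(b$a * (theta - (b$b0 + b$spread * z[s])))
    ncor <- rbinom(n, nw[s], p)
    half <- rbinom(n, nw[s] - ncor, spec$paraphasia_share)
    ord <- runif(n) < plogis(-(theta + 1))
    total[, s] <- pmax(ncor + 0.5 * half - ord, 0)
  }
  100 * rowSums(total) / sum(nw)
}

tiny_spec <- function(seed, ...) {
  cohort_spec(n_nhi_young = 12, n_nhi_elderly = 8, n_pwa_young = 10,
              n_pwa_elderly = 8, seed = seed, ...)
}
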