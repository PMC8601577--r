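#' Remove aberrant control scores before cutoff derivation
#'
#' A control score is an outlier iff it is below 90 percent AND more than
#' three standard deviations below the mean of its age cohort, both
#' statistics computed on the full input in a single pass (no iterative
#' re-removal). The rule is applied per subtest and per age cohort to
#' control data only; the GAQ is never subjected to it, since averaging
#' across subtests already damps single aberrant values.
#'
#' @param control_scores Numeric vector of control accuracies (percent) for
#'   one subtest and one age cohort.
#' @return List with `kept` and `removed` numeric vectors.
#' @examples
#' remove_norm_outliers(c(rep(100, 20), 85))$removed  # 85
#' @export
remove_norm_outliers <- function(control_scores) {
  if (length(control_scores) == 0) {
    stop("no control scores supplied", call. = FALSE)
  }
  if (length(control_scores) < 3) {
    stop("outlier screening needs at least 3 control scores", call. = FALSE)
  }
  m <- mean(control_scores)
  s <- stats::sd(control_scores)
  out <- control_scores < 90 & (m - control_scores) > 3 * s
  list(kept = control_scores[!out], removed = control_scores[out])
}

#' Subtest impairment cutoff from the control 5th percentile
#'
#' The cutoff for impaired performance on a subtest is the 5th percentile of
#' the (outlier-screened) control scores of the matching age cohort;
#' performance at or below it is abnormal, since 95% of controls score
#' higher. When the 5th percentile equals the subtest maximum -- as happens
#' for near-ceiling subtests -- even a perfect score would be labelled
#' impaired, so the cutoff is adjusted down to the next achievable score
#' below the maximum on the subtest's score lattice (23/24 = 95.83% for a
#' 24-item one-point subtest).
#'
#' @param kept_scores Control accuracies (percent) after
#'   [remove_norm_outliers()].
#' @param definition One catalogue row; used for the lattice adjustment.
#' @param qtype Quantile convention passed to [stats::quantile()]
#'   (default type 7, linear interpolation between order statistics).
#' @return Cutoff percent (full precision).
#' @examples
#' cat13 <- subtest_catalogue()
#' noun <- cat13[cat13$subtest_id == "noun_comprehension", ]
#' compute_subtest_cutoff(rep(100, 30), noun)  # 95.8333...
#' @export
compute_subtest_cutoff <- function(kept_scores, definition, qtype = 7) {
  if (length(kept_scores) < 2) {
    stop("cutoff derivation needs at least 2 control scores", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(kept_scores, 0.05, type = qtype))
  if (cutoff >= 100) {
    cutoff <- next_achievable_accuracy(definition)
  }
  cutoff
}

#' Is a subtest performance impaired?
#'
#' Performance at or below the cutoff is abnormal.
#'
#' @param accuracy Accuracy percent.
#' @param cutoff Cutoff percent.
#' @return Logical vector, `TRUE` = impaired.
#' @export
classify_subtest_performance <- function(accuracy, cutoff) {
  accuracy <= cutoff
}

#' Severity bands from the impaired patient distribution
#'
#' Severity ranks are derived from patients with abnormal performance (at or
#' below the cutoff) on the measure, with the two age cohorts pooled to
#' increase sample size; the pooled bands are shared by both cohorts even
#' though cutoffs stay cohort-specific. The scores are split into three
#' approximately equal ranges at their 34th and 67th percentiles.
#'
#' @param impaired_scores Accuracies (percent) of patients at or below the
#'   cutoff, pooled across age cohorts.
#' @param qtype Quantile convention (default type 7).
#' @return Named numeric vector `c(band_34 =, band_67 =)`.
#' @export
derive_severity_bands <- function(impaired_scores, qtype = 7) {
  if (length(impaired_scores) < 3) {
    stop("severity banding needs at least 3 impaired scores; ",
         "pool more patients or skip banding for this measure",
         call. = FALSE)
  }
  q <- stats::quantile(impaired_scores, c(0.34, 0.67), type = qtype)
  c(band_34 = unname(q[1]), band_67 = unname(q[2]))
}

#' Assign a severity rank to one accuracy score
#'
#' Given a complete norm entry, a score X maps to exactly one rank:
#' normal if X > cutoff; mild if 67th percentile <= X <= cutoff; moderate if
#' 34th percentile < X < 67th percentile; severe if X <= 34th percentile.
#' When the two band percentiles coincide the moderate interval is empty and
#' a score at the common value is severe (the `<= band_34` rule has
#' precedence).
#'
#' @param accuracy Accuracy percent (vectorized).
#' @param norm List or one-row data.frame with `cutoff`, `band_34`,
#'   `band_67`.
#' @return Factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @examples
#' n <- list(cutoff = 90, band_34 = 40, band_67 = 70)
#' assign_severity(c(95, 90, 55, 40), n)
#' @export
assign_severity <- function(accuracy, norm) {
  if (is.na(norm$cutoff) || is.na(norm$band_34) || is.na(norm$band_67)) {
    stop("incomplete norm entry: cutoff and both bands are required",
         call. = FALSE)
  }
  if (norm$band_34 > norm$band_67) {
    stop("invalid norm entry: band_34 > band_67", call. = FALSE)
  }
  out <- ifelse(accuracy > norm$cutoff, "normal",
         ifelse(accuracy <= norm$band_34, "severe",
         ifelse(accuracy < norm$band_67, "moderate", "mild")))
  factor(out, levels = c("normal", "mild", "moderate", "severe"))
}

#' Build the full normative table from control and patient profiles
#'
#' For every subtest and age cohort: screen control outliers, take the
#' control 5th percentile as the cutoff (with the next-achievable-score
#' adjustment at ceiling). For the GAQ: select the diagnostic cutoff by ROC
#' per cohort, without outlier removal. Severity bands for each measure come
#' from the pooled impaired patients of both cohorts, so rows of the same
#' measure share `band_34`/`band_67` while cutoffs stay cohort-specific.
#'
#' @param profiles Data.frame as from [participant_profiles()]: `group`
#'   (`NHI`/`PWA`), `age_cohort` (`young`/`elderly`), the 13 subtest
#'   accuracy columns and `gaq`.
#' @param qtype Quantile convention (default type 7).
#' @param dc_mode Discourse-comprehension mode for lattice adjustment.
#' @return A `norm_table`: data.frame with one row per measure x cohort
#'   (`measure`, `age_cohort`, `cutoff`, `band_34`, `band_67`,
#'   `n_controls_used`, `n_outliers_removed`) plus metadata attributes
#'   (`qtype`, `version`, cohort sizes) and the per-cohort [fit_roc()]
#'   results as attribute `"roc"`.
#' @export
build_norm_table <- function(profiles, qtype = 7,
                             dc_mode = c("pair", "statement")) {
  dc_mode <- match.arg(dc_mode)
  cat13 <- subtest_catalogue(dc_mode)
  cohorts <- c("young", "elderly")
  rows <- list()
  roc_fits <- list()
  for (measure in c(SUBTEST_IDS, "gaq")) {
    cuts <- numeric(0)
    for (ac in cohorts) {
      nhi <- profiles[profiles$group == "NHI" & profiles$age_cohort == ac,
                      measure]
      nhi <- nhi[!is.na(nhi)]
      if (measure == "gaq") {
        pwa <- profiles[profiles$group == "PWA" & profiles$age_cohort == ac,
                        "gaq"]
        roc <- fit_roc(nhi, pwa[!is.na(pwa)])
        roc$age_cohort <- ac
        roc_fits[[ac]] <- roc
        cutoff <- roc$selected_cutoff
        kept <- nhi; removed <- numeric(0)
      } else {
        scr <- remove_norm_outliers(nhi)
        kept <- scr$kept; removed <- scr$removed
        cutoff <- compute_subtest_cutoff(kept, catalogue_entry(measure, cat13),
                                         qtype = qtype)
      }
      cuts[ac] <- cutoff
      rows[[length(rows) + 1]] <- data.frame(
        measure = measure, age_cohort = ac, cutoff = cutoff,
        band_34 = NA_real_, band_67 = NA_real_,
        n_controls_used = length(kept),
        n_outliers_removed = length(removed),
        stringsAsFactors = FALSE)
    }
    # pooled severity bands across cohorts, cohort-specific cutoffs
    pwa_all <- profiles[profiles$group == "PWA", c("age_cohort", measure)]
    pwa_all <- pwa_all[!is.na(pwa_all[[measure]]), ]
    impaired <- pwa_all[[measure]][pwa_all[[measure]] <=
                                     cuts[pwa_all$age_cohort]]
    if (length(impaired) >= 3) {
      bands <- derive_severity_bands(impaired, qtype = qtype)
      k <- length(rows)
      for (j in c(k - 1, k)) {
        rows[[j]]$band_34 <- bands[["band_34"]]
        rows[[j]]$band_67 <- bands[["band_67"]]
      }
    }
  }
  norms <- do.call(rbind, rows)
  attr(norms, "qtype") <- qtype
  attr(norms, "dc_mode") <- dc_mode
  attr(norms, "version") <- NORM_TABLE_VERSION
  attr(norms, "n_nhi") <- table(profiles$age_cohort[profiles$group == "NHI"])
  attr(norms, "n_pwa") <- table(profiles$age_cohort[profiles$group == "PWA"])
  attr(norms, "roc") <- roc_fits
  class(norms) <- c("norm_table", "data.frame")
  norms
}

NORM_TABLE_VERSION <- "1"

#' Classify one participant profile against a norm table
#'
#' Flags aphasia when the GAQ is at or below the cohort's ROC-selected
#' diagnostic cutoff, and assigns a severity rank to every subtest and to
#' the GAQ. A missing GAQ (incomplete battery) yields `aphasia_flag = NA`:
#' presence of aphasia is ascertained only from the full composite.
#'
#' @param profile One-row data.frame (see [participant_profiles()]).
#' @param norms A `norm_table` from [build_norm_table()].
#' @return List: `participant_id`, `age_cohort`, `aphasia_flag`,
#'   `gaq_severity`, and data.frame `subtests` (`subtest_id`, `accuracy`,
#'   `cutoff`, `impaired`, `severity`).
#' @export
classify_participant <- function(profile, norms) {
  stopifnot(nrow(profile) == 1)
  ac <- profile$age_cohort
  sub <- lapply(SUBTEST_IDS, function(st) {
    ne <- norms[norms$measure == st & norms$age_cohort == ac, ]
    acc <- profile[[st]]
    data.frame(subtest_id = st, accuracy = acc, cutoff = ne$cutoff,
               impaired = classify_subtest_performance(acc, ne$cutoff),
               severity = as.character(assign_severity(acc, ne)),
               stringsAsFactors = FALSE)
  })
  ng <- norms[norms$measure == "gaq" & norms$age_cohort == ac, ]
  gaq <- profile$gaq
  list(participant_id = profile$participant_id,
       age_cohort = ac,
       aphasia_flag = if (is.na(gaq)) NA else gaq <= ng$cutoff,
       gaq = gaq,
       gaq_severity = if (is.na(gaq)) NA_character_ else
         as.character(assign_severity(gaq, ng)),
       subtests = do.call(rbind, sub))
}
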