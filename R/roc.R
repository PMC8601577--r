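#' ROC analysis for the GAQ diagnostic cutoff
#'
#' Fits the empirical ROC of the rule "GAQ at or below threshold indicates
#' aphasia" over candidate thresholds placed at the midpoints between
#' consecutive distinct pooled GAQ values, plus -Inf/+Inf sentinels (no
#' positives / all positives). The diagnostic cutoff is the threshold
#' maximizing sensitivity + specificity (Youden-type selection); ties are
#' broken toward the larger threshold, favouring sensitivity at matched
#' sums. Performed separately per age cohort by [build_norm_table()];
#' control outliers are not removed for this analysis, so the full range of
#' control performance enters the cutoff.
#'
#' @param gaq_nhi GAQ values of the control (NHI) group.
#' @param gaq_pwa GAQ values of the patient (PWA) group.
#' @return A `roc_result` list: `thresholds`, `sens`, `spec` (parallel
#'   vectors), `selected_cutoff`, `selected_sens`, `selected_spec`, group
#'   sizes.
#' @examples
#' r <- fit_roc(c(96, 97, 99), c(40, 60, 80))
#' c(r$selected_sens, r$selected_spec)  # perfect separation: 1 1
#' @export
fit_roc <- function(gaq_nhi, gaq_pwa) {
  if (length(gaq_nhi) == 0 || length(gaq_pwa) == 0) {
    stop("both groups must be non-empty for ROC analysis", call. = FALSE)
  }
  pooled <- sort(unique(c(gaq_nhi, gaq_pwa)))
  thresholds <- c(-Inf,
                  if (length(pooled) > 1)
                    (pooled[-1] + pooled[-length(pooled)]) / 2,
                  Inf)
  sens <- vapply(thresholds, function(th) mean(gaq_pwa <= th), numeric(1))
  spec <- vapply(thresholds, function(th) mean(gaq_nhi > th), numeric(1))
  j <- sens + spec
  # ties broken toward the larger threshold
  best <- max(which(j == max(j)))
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 selected_cutoff = thresholds[best],
                 selected_sens = sens[best], selected_spec = spec[best],
                 n_nhi = length(gaq_nhi), n_pwa = length(gaq_pwa)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC cutoff selection (positive = GAQ <= threshold)\n")
  cat(sprintf("  n: %d controls, %d patients\n", x$n_nhi, x$n_pwa))
  cat(sprintf("  selected cutoff: %.2f (sens %.3f, spec %.3f)\n",
              x$selected_cutoff, x$selected_sens, x$selected_spec))
  invisible(x)
}

#' Sensitivity and specificity of a fixed GAQ cutoff
#'
#' Evaluates the classifier "GAQ at or below cutoff = aphasia" against true
#' group labels: sensitivity is the fraction of patients flagged (TP rate),
#' specificity the fraction of controls not flagged (TN rate).
#'
#' @param gaq_values Numeric GAQ values.
#' @param labels Character/factor labels, each `"NHI"` or `"PWA"`.
#' @param cutoff The diagnostic cutoff.
#' @return List: `sensitivity`, `specificity`, and confusion counts `tp`,
#'   `fn`, `tn`, `fp`.
#' @examples
#' evaluate_classifier(c(95, 85, 70), c("NHI", "PWA", "PWA"), 90)
#' @export
evaluate_classifier <- function(gaq_values, labels, cutoff) {
  labels <- as.character(labels)
  if (!all(labels %in% c("NHI", "PWA"))) {
    stop("labels must be 'NHI' or 'PWA'", call. = FALSE)
  }
  if (length(gaq_values) != length(labels)) {
    stop("gaq_values and labels differ in length", call. = FALSE)
  }
  positive <- gaq_values <= cutoff
  tp <- sum(positive & labels == "PWA")
  fn <- sum(!positive & labels == "PWA")
  fp <- sum(positive & labels == "NHI")
  tn <- sum(!positive & labels == "NHI")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}
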