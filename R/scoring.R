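#' Score a binary (one-point) item
#'
#' Comprehension subtests are scored automatically on the tablet: a correct
#' choice earns 1, an incorrect one 0. Naming subtests are also one point
#' per item: a correct response earns 1 and every error type 0, so a naming
#' response may be given either as a logical flag or as a verbal-response
#' code. A single allowed repetition of the stimulus carries no penalty and
#' is not represented in the score.
#'
#' @param response Either a logical/0-1 correctness flag, or one of the
#'   verbal-response codes (`"correct"`, `"phonological_paraphasia"`,
#'   `"word_form_error"`, `"omission"`, `"other_error"`) for naming items.
#' @return An item score list with `points` (0 or 1) and `max_points` (1).
#' @examples
#' score_binary_item(TRUE)$points            # 1
#' score_binary_item("other_error")$points   # 0
#' @export
score_binary_item <- function(response) {
  if (is.logical(response) || (is.numeric(response) && response %in% c(0, 1))) {
    pts <- as.numeric(response)
  } else if (is.character(response)) {
    if (!response %in% REPETITION_CODES) {
      stop("illegal response code '", response, "' for a binary item",
           call. = FALSE)
    }
    pts <- as.numeric(response == "correct")
  } else {
    stop("binary item response must be logical, 0/1, or a response code",
         call. = FALSE)
  }
  item_score(pts, 1)
}

#' Score a single-word or nonword repetition item
#'
#' A correctly repeated target earns 1 point; a phonological paraphasia
#' (more than half of the target spared and the target still recognizable,
#' a judgement encoded by the coder in the annotation) earns 0.5; every
#' other error type, including omissions, earns 0.
#'
#' @param code One verbal-response code (see [score_binary_item()]).
#' @return Item score list: `points` in \{0, 0.5, 1\}, `max_points` 1.
#' @examples
#' score_repetition_item("phonological_paraphasia")$points  # 0.5
#' @export
score_repetition_item <- function(code) {
  if (!is.character(code) || length(code) != 1 || !code %in% REPETITION_CODES) {
    stop("unknown repetition code: '", paste(code, collapse = ","), "'",
         call. = FALSE)
  }
  pts <- switch(code, correct = 1, phonological_paraphasia = 0.5, 0)
  item_score(pts, 1)
}

#' Score a sentence repetition item from per-word codes
#'
#' Every content and function word of the target sentence is coded
#' separately: 1 point if repeated correctly, 0.5 for a phonological
#' paraphasia or a word-form error, 0 for omissions and other errors. Any
#' word-order alteration (order changes, repetitions, omissions or
#' insertions that change the order) incurs a single one-point penalty,
#' applied at most once per sentence regardless of how many order-altering
#' events the coder recorded. The sentence score is the word-point sum minus
#' the penalty, floored at zero; the maximum is the word count.
#'
#' @param word_codes Character vector of verbal-response codes, one per word
#'   of the target sentence.
#' @param order_error Logical: did any word-order alteration occur?
#' @return Item score list with `points` and `max_points = length(word_codes)`.
#' @examples
#' score_sentence_repetition(rep("correct", 6), order_error = TRUE)$points # 5
#' @export
score_sentence_repetition <- function(word_codes, order_error = FALSE) {
  if (length(word_codes) == 0) {
    stop("sentence repetition item has an empty word list", call. = FALSE)
  }
  bad <- setdiff(word_codes, REPETITION_CODES)
  if (length(bad) > 0) {
    stop("unknown repetition code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  word_pts <- c(correct = 1, phonological_paraphasia = 0.5,
                word_form_error = 0.5, omission = 0, other_error = 0)
  pts <- sum(word_pts[word_codes]) - as.numeric(isTRUE(as.logical(order_error)))
  item_score(max(pts, 0), length(word_codes))
}

#' Score a sentence production item from its four criteria
#'
#' Each elicited sentence is judged on four binary criteria: consistency
#' with the syntactic prime, grammaticality, lexical-semantic adequacy, and
#' other aspects of phrase appropriateness. Each criterion met earns one
#' point; the item score is the number met (0-4).
#'
#' @param criteria Logical (or 0/1) vector of exactly four criterion
#'   judgements.
#' @return Item score list: `points` in 0..4, `max_points` 4.
#' @examples
#' score_sentence_production_item(c(TRUE, TRUE, FALSE, TRUE))$points  # 3
#' @export
score_sentence_production_item <- function(criteria) {
  criteria <- as.logical(criteria)
  if (length(criteria) != 4 || anyNA(criteria)) {
    stop("sentence production requires exactly 4 criterion booleans",
         call. = FALSE)
  }
  item_score(sum(criteria), 4)
}

#' Score the discourse production item from its four rating scales
#'
#' The single picture-elicited narrative is rated on four 5-point scales
#' (higher is better): fluency, grammatical complexity, paraphasias, and
#' informational content. The item score is the sum of the four ratings,
#' so it ranges 4-20 and the accuracy floor is structurally 20%, not 0.
#'
#' @param ratings Integer vector of exactly four ratings, each in 1..5.
#' @return Item score list: `points` in 4..20, `max_points` 20.
#' @examples
#' score_discourse_production(c(3, 4, 2, 5))$points  # 14
#' @export
score_discourse_production <- function(ratings) {
  if (length(ratings) != 4) {
    stop("discourse production requires exactly 4 ratings", call. = FALSE)
  }
  if (anyNA(ratings) || any(ratings != round(ratings)) ||
      any(ratings < 1) || any(ratings > 5)) {
    stop("discourse production ratings must be integers in 1..5",
         call. = FALSE)
  }
  item_score(sum(ratings), 20)
}

#' Score discourse comprehension statements with pair gating
#'
#' The story is probed by 16 verification statements grouped into 8 pairs
#' that refer to the same story element. Under the default pair-gated rule
#' (a safeguard against guessing in the yes/no format) one credit is earned
#' per pair only when both statements are answered correctly, giving a
#' maximum of 8. The `"statement"` mode instead credits each statement
#' individually (maximum 16), matching the tablet's automatic per-response
#' registration.
#'
#' @param responses Logical (or 0/1) vector of per-statement correctness,
#'   in presentation order; consecutive statements form a pair.
#' @param mode `"pair"` (default) or `"statement"`.
#' @return A list of item score lists, one per credit unit.
#' @examples
#' r <- rep(TRUE, 16); r[3] <- FALSE
#' sum(vapply(score_discourse_comprehension(r), `[[`, 0, "points"))  # 7
#' @export
score_discourse_comprehension <- function(responses,
                                          mode = c("pair", "statement")) {
  mode <- match.arg(mode)
  responses <- as.logical(responses)
  if (anyNA(responses)) {
    stop("discourse comprehension responses must be logical/0-1",
         call. = FALSE)
  }
  if (mode == "statement") {
    return(lapply(as.numeric(responses), item_score, max_points = 1))
  }
  if (length(responses) %% 2 != 0) {
    stop("pair-gated scoring needs an even number of statements ",
         "(each pair has exactly 2)", call. = FALSE)
  }
  pair_of <- rep(seq_len(length(responses) / 2), each = 2)
  credits <- tapply(responses, pair_of, all)
  lapply(as.numeric(credits), item_score, max_points = 1)
}

item_score <- function(points, max_points) {
  stopifnot(points >= 0, points <= max_points)
  list(points = points, max_points = max_points)
}

#' Subtest accuracy from item scores
#'
#' Accuracy is the percentage of points earned out of the maximum possible
#' over all of the subtest's items. Items never attempted (e.g. a subtest
#' abandoned after persistent no-responses) are counted as incorrect: the
#' denominator always reflects the full item set of the catalogue
#' definition.
#'
#' @param scores List of item score lists (`points`, `max_points`) for the
#'   items actually scored.
#' @param definition One catalogue row (see [subtest_catalogue()]).
#' @return A one-row data.frame: `subtest_id`, `raw_total`, `max_total`,
#'   `accuracy` (percent, full precision).
#' @examples
#' cat13 <- subtest_catalogue()
#' noun <- cat13[cat13$subtest_id == "noun_comprehension", ]
#' s <- c(lapply(1:23, function(i) score_binary_item(TRUE)),
#'        list(score_binary_item(FALSE)))
#' subtest_accuracy(s, noun)$accuracy  # 95.8333...
#' @export
subtest_accuracy <- function(scores, definition) {
  pts <- vapply(scores, `[[`, numeric(1), "points")
  if (length(scores) > definition$n_items) {
    stop(definition$subtest_id, ": ", length(scores),
         " item scores exceed the defined ", definition$n_items, " items",
         call. = FALSE)
  }
  raw <- sum(pts)
  max_total <- definition$max_total
  if (definition$rule == "sentence_repetition") {
    # variable per-item maxima: observed word counts, canonical counts for
    # unattempted items
    mx <- vapply(scores, `[[`, numeric(1), "max_points")
    canon <- attr(subtest_catalogue(), "sr_word_counts")
    if (length(mx) < definition$n_items) {
      mx <- c(mx, canon[seq(length(mx) + 1, definition$n_items)])
    }
    max_total <- sum(mx)
  }
  if (raw > max_total) {
    stop(definition$subtest_id, ": raw total ", raw,
         " exceeds maximum ", max_total, call. = FALSE)
  }
  data.frame(subtest_id = definition$subtest_id, raw_total = raw,
             max_total = max_total, accuracy = 100 * raw / max_total,
             stringsAsFactors = FALSE)
}

#' General Aphasia Quotient (GAQ)
#'
#' The GAQ summarizes overall language impairment as the unweighted mean of
#' the 13 subtest accuracy percentages, ranging 0-100. It is defined only
#' when all 13 subtests were administered (fully or partially); with an
#' explicitly named subset a GAQ-proxy is computed instead, as done for
#' retest sessions covering part of the battery.
#'
#' @param accuracies Named numeric vector of subtest accuracies (percent);
#'   names are subtest ids.
#' @param proxy_subset Optional character vector of subtest ids: compute the
#'   GAQ-proxy over exactly these subtests.
#' @return The GAQ (or proxy) percent; a proxy carries attribute
#'   `"gaq_proxy"` listing the subtests averaged.
#' @examples
#' compute_gaq(setNames(rep(100, 13), SUBTEST_IDS))  # 100
#' compute_gaq(c(object_naming = 80, action_naming = 60),
#'             proxy_subset = c("object_naming", "action_naming"))  # 70
#' @export
compute_gaq <- function(accuracies, proxy_subset = NULL) {
  if (is.null(proxy_subset)) {
    missing <- setdiff(SUBTEST_IDS, names(accuracies)[!is.na(accuracies)])
    if (length(missing) > 0) {
      stop("GAQ requires all 13 subtest accuracies; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(mean(accuracies[SUBTEST_IDS]))
  }
  missing <- setdiff(proxy_subset, names(accuracies)[!is.na(accuracies)])
  if (length(missing) > 0) {
    stop("GAQ-proxy subset not fully available; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- mean(accuracies[proxy_subset])
  attr(out, "gaq_proxy") <- proxy_subset
  out
}

#' Score a long-format trial table into per-participant subtest results
#'
#' Applies the battery's scoring rules row by row to a trial table in the
#' package's CSV dialect (see [read_trial_csv()]) and aggregates to one row
#' per participant and subtest. Multi-part payloads (per-word codes,
#' criteria, ratings, discourse-comprehension statements) are carried in the
#' columns described under [read_trial_csv()]. Reaction times, if present,
#' are ignored.
#'
#' @param trials Trial data.frame (columns `participant_id`, `group`,
#'   `age_cohort`, `subtest_id`, `item_id` plus payload columns).
#' @param dc_mode Discourse-comprehension mode, see [subtest_catalogue()].
#' @return Data.frame with one row per participant x administered subtest:
#'   ids, labels, `raw_total`, `max_total`, `accuracy`.
#' @export
score_trials <- function(trials, dc_mode = c("pair", "statement")) {
  dc_mode <- match.arg(dc_mode)
  cat13 <- subtest_catalogue(dc_mode)
  validate_trials(trials)
  out <- list()
  for (pid in unique(trials$participant_id)) {
    ptr <- trials[trials$participant_id == pid, , drop = FALSE]
    for (st in unique(ptr$subtest_id)) {
      rows <- ptr[ptr$subtest_id == st, , drop = FALSE]
      def <- catalogue_entry(st, cat13)
      scores <- score_subtest_rows(rows, def, dc_mode)
      res <- subtest_accuracy(scores, def)
      res$participant_id <- pid
      res$group <- rows$group[1]
      res$age_cohort <- rows$age_cohort[1]
      out[[length(out) + 1]] <- res
    }
  }
  out <- do.call(rbind, out)
  out[, c("participant_id", "group", "age_cohort", "subtest_id",
          "raw_total", "max_total", "accuracy")]
}

score_subtest_rows <- function(rows, def, dc_mode) {
  rule <- def$rule
  if (rule %in% c("binary", "naming")) {
    lapply(rows$response, score_binary_item)
  } else if (rule == "repetition") {
    lapply(rows$code, score_repetition_item)
  } else if (rule == "sentence_repetition") {
    lapply(seq_len(nrow(rows)), function(i) {
      score_sentence_repetition(split_field(rows$word_codes[i]),
                                rows$order_error[i])
    })
  } else if (rule == "criteria") {
    lapply(rows$criteria, function(x)
      score_sentence_production_item(as.numeric(split_field(x))))
  } else if (rule == "ratings") {
    lapply(rows$ratings, function(x)
      score_discourse_production(as.numeric(split_field(x))))
  } else if (startsWith(rule, "discourse_comprehension")) {
    # statements must be scored in presentation order for pair grouping
    rows <- rows[order_items(rows$item_id), , drop = FALSE]
    score_discourse_comprehension(rows$response, dc_mode)
  } else {
    stop("no scorer for rule '", rule, "'", call. = FALSE)
  }
}

split_field <- function(x) strsplit(as.character(x), ";", fixed = TRUE)[[1]]

order_items <- function(item_id) {
  num <- suppressWarnings(as.integer(gsub("\\D", "", item_id)))
  if (anyNA(num)) order(item_id) else order(num)
}

#' Participant profiles with GAQ from scored trials
#'
#' Pivots scored subtest results to one row per participant with the 13
#' accuracy columns and the GAQ. Participants missing any subtest get
#' `gaq = NA` with a warning naming them: the GAQ is defined only over the
#' complete battery.
#'
#' @param scored Output of [score_trials()].
#' @return Data.frame: `participant_id`, `group`, `age_cohort`, one accuracy
#'   column per subtest id, `gaq`.
#' @export
participant_profiles <- function(scored) {
  pids <- unique(scored$participant_id)
  prof <- data.frame(participant_id = pids, stringsAsFactors = FALSE)
  meta <- scored[!duplicated(scored$participant_id),
                 c("participant_id", "group", "age_cohort")]
  prof <- merge(prof, meta, by = "participant_id", sort = FALSE)
  for (st in SUBTEST_IDS) {
    sub <- scored[scored$subtest_id == st, c("participant_id", "accuracy")]
    names(sub)[2] <- st
    prof <- merge(prof, sub, by = "participant_id", all.x = TRUE, sort = FALSE)
  }
  acc <- as.matrix(prof[, SUBTEST_IDS])
  complete <- rowSums(is.na(acc)) == 0
  prof$gaq <- ifelse(complete, rowMeans(acc), NA_real_)
  if (any(!complete)) {
    warning("GAQ omitted for participant(s) with incomplete batteries: ",
            paste(prof$participant_id[!complete], collapse = ", "),
            call. = FALSE)
  }
  prof
}

#' Round accuracies half-up to two decimals for presentation
#'
#' All internal computation keeps full precision; scores are rounded only
#' when presented. Rounding is half-up (95.835 -> 95.84), not banker's.
#'
#' @param x Numeric vector of percentages.
#' @return `x` rounded half-up to 2 decimals.
#' @examples
#' present_accuracy(100 * 23 / 24)  # 95.83
#' @export
present_accuracy <- function(x) {
  floor(x * 100 + 0.5) / 100
}
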