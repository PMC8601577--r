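#' Subtest catalogue for the 13-subtest aphasia battery
#'
#' Static description of the battery: one row per subtest with its language
#' domain, number of scored items, per-item maximum, scoring rule and the
#' score lattice step. The battery covers three domains: auditory
#' comprehension (6 subtests, scored automatically as the participant
#' responds on the tablet), repetition (3) and oral production (4, scored by
#' a trained rater from recorded responses).
#'
#' Discourse comprehension is a special case: 16 verification statements are
#' grouped into 8 pairs probing the same story element, and under the
#' default pair-gated rule one credit is earned per pair (both statements
#' correct), so `n_items = 8`. Sentence repetition items are whole sentences
#' whose maximum equals their word count; the catalogue carries the
#' instrument's canonical word counts (six 4-word and six 7-word sentences,
#' `max_total = 66`) used when annotations omit unattempted items.
#'
#' @param dc_mode Discourse-comprehension scoring mode: `"pair"` (default,
#'   one credit per statement pair) or `"statement"` (one credit per
#'   statement, 16 items).
#' @return A data.frame with columns `subtest_id`, `domain`, `n_items`,
#'   `item_max`, `rule`, `step`, `max_total`, carrying the canonical
#'   sentence-repetition word counts as attribute `"sr_word_counts"`.
#' @examples
#' cat13 <- subtest_catalogue()
#' stopifnot(nrow(cat13) == 13, sum(cat13$domain == "comprehension") == 6)
#' @export
subtest_catalogue <- function(dc_mode = c("pair", "statement")) {
  dc_mode <- match.arg(dc_mode)
  dc_n <- if (dc_mode == "pair") 8L else 16L
  cat13 <- data.frame(
    subtest_id = SUBTEST_IDS,
    domain = c(rep("comprehension", 6), rep("repetition", 3),
               rep("production", 4)),
    n_items = c(22L, 24L, 24L, 24L, 24L, dc_n, 24L, 24L, 12L, 24L, 24L,
                24L, 1L),
    item_max = c(1, 1, 1, 1, 1, 1, 1, 1, NA, 1, 1, 4, 20),
    rule = c("binary", "binary", "binary", "binary", "binary",
             paste0("discourse_comprehension_", dc_mode),
             "repetition", "repetition", "sentence_repetition",
             "naming", "naming", "criteria", "ratings"),
    step = c(1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  sr_words <- c(4L, 4L, 4L, 4L, 4L, 4L, 7L, 7L, 7L, 7L, 7L, 7L)
  cat13$max_total <- cat13$n_items * cat13$item_max
  cat13$max_total[cat13$subtest_id == "sentence_repetition"] <- sum(sr_words)
  attr(cat13, "sr_word_counts") <- sr_words
  attr(cat13, "dc_mode") <- dc_mode
  cat13
}

#' @rdname subtest_catalogue
#' @format `SUBTEST_IDS` is the character vector of the 13 subtest
#'   identifiers in canonical battery order.
#' @export
SUBTEST_IDS <- c(
  "nonword_discrimination", "lexical_decision", "noun_comprehension",
  "verb_comprehension", "sentence_comprehension", "discourse_comprehension",
  "nonword_repetition", "word_repetition", "sentence_repetition",
  "object_naming", "action_naming", "sentence_production",
  "discourse_production"
)

# Legal verbal-response codes for manually scored subtests.
REPETITION_CODES <- c("correct", "phonological_paraphasia",
                      "word_form_error", "omission", "other_error")

catalogue_entry <- function(subtest_id, catalogue = subtest_catalogue()) {
  i <- match(subtest_id, catalogue$subtest_id)
  if (is.na(i)) {
    stop("unknown subtest_id: '", subtest_id, "'", call. = FALSE)
  }
  catalogue[i, , drop = FALSE]
}

#' Largest achievable accuracy strictly below the subtest maximum
#'
#' Implements the next-achievable-score rule used when a normative cutoff
#' coincides with a perfect score: the cutoff is lowered to the highest
#' score actually attainable below the maximum, given the subtest's score
#' lattice (binary subtests: max - 1 point; half-point repetition lattices:
#' max - 0.5).
#'
#' @param definition One catalogue row (see [subtest_catalogue()]).
#' @return Accuracy percent of the next achievable score below maximum.
#' @examples
#' cat13 <- subtest_catalogue()
#' noun <- cat13[cat13$subtest_id == "noun_comprehension", ]
#' next_achievable_accuracy(noun)  # 23/24 as percent
#' @export
next_achievable_accuracy <- function(definition) {
  100 * (definition$max_total - definition$step) / definition$max_total
}
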