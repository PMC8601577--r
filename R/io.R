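TRIAL_CSV_VERSION <- "aphasiometry_trials_v1"
NORM_CSV_VERSION <- "aphasiometry_norms_v1"

TRIAL_REQUIRED_COLS <- c("participant_id", "group", "age_cohort",
                         "subtest_id", "item_id")
TRIAL_PAYLOAD_COLS <- c("response", "code", "word_codes", "order_error",
                        "criteria", "ratings")

#' Read a long-format trial CSV
#'
#' Reads the package's trial dialect: RFC-4180 CSV, UTF-8, preceded by a
#' versioned header line (`#aphasiometry_trials_v1`). One row per scored
#' trial (per statement for discourse comprehension) with the identifier
#' columns `participant_id`, `group`, `age_cohort`, `subtest_id`, `item_id`
#' and payload columns by scoring rule: `response` (0/1) for comprehension,
#' `code` for word/nonword repetition and naming, `word_codes` +
#' `order_error` for sentence repetition (semicolon-joined per-word codes),
#' `criteria` for sentence production (four semicolon-joined 0/1), and
#' `ratings` for discourse production (four semicolon-joined 1-5). An
#' `rt_ms` reaction-time column may be present; it is parsed and retained
#' but never used in scoring.
#'
#' Validation failures (missing columns, illegal codes, out-of-range
#' ratings, duplicate trials) are reported with row numbers.
#'
#' @param path File path.
#' @return Validated trial data.frame.
#' @export
read_trial_csv <- function(path) {
  first <- readLines(path, n = 1, encoding = "UTF-8")
  if (!identical(sub("^#", "", first), TRIAL_CSV_VERSION)) {
    stop("not a recognized trial file: expected header line '#",
         TRIAL_CSV_VERSION, "', found '", first, "'", call. = FALSE)
  }
  trials <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8",
                            colClasses = "character")
  for (col in c("response", "order_error", "rt_ms")) {
    if (col %in% names(trials)) {
      trials[[col]] <- suppressWarnings(as.numeric(trials[[col]]))
    }
  }
  validate_trials(trials)
  trials
}

#' Write a trial table in the package's CSV dialect
#'
#' @param trials Trial data.frame (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trials, path) {
  validate_trials(trials)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", TRIAL_CSV_VERSION), con)
  utils::write.csv(trials, con, row.names = FALSE, na = "")
  invisible(path)
}

validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_REQUIRED_COLS, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_st <- !trials$subtest_id %in% SUBTEST_IDS
  if (any(bad_st)) {
    stop("unknown subtest_id at row(s) ",
         paste(utils::head(which(bad_st), 5), collapse = ", "), ": ",
         paste(unique(trials$subtest_id[bad_st]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$subtest_id, trials$item_id)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, subtest, item) trial(s) at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  }
  cat13 <- subtest_catalogue()
  rule <- cat13$rule[match(trials$subtest_id, cat13$subtest_id)]
  check_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      stop(what, " at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  is_resp <- rule %in% c("binary", "naming") |
    startsWith(rule, "discourse_comprehension")
  if ("response" %in% names(trials)) {
    check_rows(is_resp & !trials$response %in% c(0, 1),
               "response must be 0/1")
  } else {
    check_rows(is_resp, "missing 'response' column for comprehension rows")
  }
  if (any(rule == "repetition")) {
    check_rows(rule == "repetition" & !trials$code %in% REPETITION_CODES,
               "illegal repetition code")
  }
  if (any(rule == "sentence_repetition")) {
    i <- which(rule == "sentence_repetition")
    bad <- logical(nrow(trials))
    bad[i] <- vapply(trials$word_codes[i], function(x)
      any(!split_field(x) %in% REPETITION_CODES), logical(1))
    check_rows(bad, "illegal word code in sentence repetition")
    check_rows(rule == "sentence_repetition" &
                 !trials$order_error %in% c(0, 1),
               "order_error must be 0/1")
  }
  if (any(rule == "criteria")) {
    i <- which(rule == "criteria")
    bad <- logical(nrow(trials))
    bad[i] <- vapply(trials$criteria[i], function(x) {
      v <- suppressWarnings(as.numeric(split_field(x)))
      length(v) != 4 || anyNA(v) || !all(v %in% c(0, 1))
    }, logical(1))
    check_rows(bad, "criteria must be four semicolon-joined 0/1 values")
  }
  if (any(rule == "ratings")) {
    i <- which(rule == "ratings")
    bad <- logical(nrow(trials))
    bad[i] <- vapply(trials$ratings[i], function(x) {
      v <- suppressWarnings(as.numeric(split_field(x)))
      length(v) != 4 || anyNA(v) || any(v != round(v) | v < 1 | v > 5)
    }, logical(1))
    check_rows(bad, "ratings must be four integers in 1..5")
  }
  invisible(trials)
}

#' Write / read a normative table with metadata
#'
#' Norm tables round-trip losslessly through CSV with metadata carried in
#' `#key: value` comment lines after the version line (quantile convention,
#' discourse-comprehension mode, cohort sizes, table version). Reading
#' re-validates the band invariants (`band_34 <= band_67`); a table missing
#' some measure is read with a warning, and GAQ classification against it
#' will refuse until complete.
#'
#' @param norms A `norm_table` (see [build_norm_table()]).
#' @param path File path.
#' @return `write_norm_table`: `path` invisibly; `read_norm_table`: a
#'   `norm_table`.
#' @export
write_norm_table <- function(norms, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#", NORM_CSV_VERSION),
    paste0("#qtype: ", attr(norms, "qtype")),
    paste0("#dc_mode: ", attr(norms, "dc_mode")),
    paste0("#n_nhi: ", paste(attr(norms, "n_nhi"), collapse = ",")),
    paste0("#n_pwa: ", paste(attr(norms, "n_pwa"), collapse = ","))
  ), con)
  df <- as.data.frame(norms)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_norm_table
#' @export
read_norm_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!identical(lines[1], paste0("#", NORM_CSV_VERSION))) {
    stop("norm table version mismatch: expected '#", NORM_CSV_VERSION,
         "', found '", lines[1], "'", call. = FALSE)
  }
  meta_lines <- grep("^#", lines, value = TRUE)[-1]
  meta <- stats::setNames(
    sub("^#[^:]+: ?", "", meta_lines),
    sub(":.*$", "", sub("^#", "", meta_lines)))
  body <- lines[!grepl("^#", lines)]
  norms <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  bad <- !is.na(norms$band_34) & !is.na(norms$band_67) &
    norms$band_34 > norms$band_67
  if (any(bad)) {
    stop("invalid norm table: band_34 > band_67 for ",
         paste(norms$measure[bad], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(SUBTEST_IDS, "gaq"), norms$measure)
  if (length(missing) > 0) {
    warning("norm table incomplete; missing measure(s): ",
            paste(missing, collapse = ", "),
            "; classification will refuse until complete", call. = FALSE)
  }
  attr(norms, "qtype") <- as.numeric(meta[["qtype"]])
  attr(norms, "dc_mode") <- meta[["dc_mode"]]
  for (key in c("n_nhi", "n_pwa")) {
    if (!is.na(meta[key])) {
      attr(norms, key) <- as.integer(strsplit(meta[[key]], ",")[[1]])
    }
  }
  attr(norms, "version") <- NORM_TABLE_VERSION
  class(norms) <- c("norm_table", "data.frame")
  norms
}

#' Write participant profiles as schema-versioned JSON
#'
#' @param profiles Data.frame from [participant_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_json <- function(profiles, path) {
  payload <- list(schema = "aphasiometry_profiles_v1",
                  generated = "aphasiometry",
                  profiles = profiles)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read participant profiles written by [write_profiles_json()]
#'
#' @param path JSON path.
#' @return Profiles data.frame.
#' @export
read_profiles_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "aphasiometry_profiles_v1")) {
    stop("profile schema mismatch: ", payload$schema, call. = FALSE)
  }
  payload$profiles
}
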