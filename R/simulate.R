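#' Specification of a synthetic control/patient cohort
#'
#' Defines the generative model used to emulate the standardization study's
#' populations. Each participant has a latent language ability theta shared
#' across subtests, plus a small stable subtest-specific residual ability
#' (task demands such as pragmatics, memory, or priming that are not part
#' of the common language factor). Items follow a logistic model with
#' guessing and lapse asymptotes: success probability
#' `guess + (1 - guess - lapse) * plogis(a * (theta - b_j))`, with per-item
#' difficulties `b_j = b0 + spread * z_j` spaced on fixed normal quantiles
#' so item difficulty ranges are a property of the instrument, not of the
#' random draw. Forced-choice comprehension formats guess at chance;
#' open-ended repetition/production items do not. Multi-point items
#' (sentence-production criteria, discourse-production ratings) use
#' binomial thresholds on the same latent scale. Controls and patients
#' differ only in their theta distribution; elderly participants carry a
#' theta penalty on the four age-sensitive subtests (discourse
#' comprehension, nonword repetition, sentence repetition, sentence
#' production) and an increased lapse rate on discourse comprehension.
#'
#' The default parameters were calibrated once, numerically, so that under
#' `theta ~ N(0, 1)` patient item passing-rate family means sit mid-range
#' of the observed families (comprehension 0.77-0.94, repetition 0.51-0.75,
#' production 0.44-0.64), per-subtest internal consistency approaches the
#' battery's reliability profile, and the control distribution reproduces
#' the reported diagnostic separation (near-ceiling performance except on
#' the discourse and sentence-production subtests).
#'
#' @param n_nhi_young,n_nhi_elderly Control cohort sizes (defaults 69/37).
#' @param n_pwa_young,n_pwa_elderly Patient cohort sizes (defaults 44/41).
#' @param pwa_theta_mean,pwa_theta_sd Patient latent-trait distribution.
#' @param nhi_theta_mean,nhi_theta_sd Control latent-trait distribution.
#' @param elderly_penalty Theta shift subtracted on the four age-sensitive
#'   subtests for elderly participants (both groups).
#' @param elderly_lapse Additional lapse probability for elderly
#'   participants on subtests with a nonzero lapse rate (discourse
#'   comprehension): attention and memory slips increase with age even when
#'   linguistic ability is intact.
#' @param paraphasia_share Probability that a failed repetition target
#'   surfaces as a half-credit phonological paraphasia rather than a
#'   zero-credit error.
#' @param subtest_params Optional replacement parameter table
#'   (`subtest_id`, `a`, `b0`, `spread`, and optionally `resid_sd`,
#'   `guess`, `lapse`, which default to 0); see
#'   [default_subtest_params()].
#' @param seed Mandatory integer root seed; per-participant sub-seeds are
#'   derived from it so regeneration is byte-identical.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nhi_young = 69, n_nhi_elderly = 37,
                        n_pwa_young = 44, n_pwa_elderly = 41,
                        pwa_theta_mean = 0, pwa_theta_sd = 1,
                        nhi_theta_mean = 3.0, nhi_theta_sd = 0.45,
                        elderly_penalty = 0.6,
                        elderly_lapse = 0.03,
                        paraphasia_share = 0.4,
                        subtest_params = NULL,
                        seed) {
  if (missing(seed) || is.na(seed)) {
    stop("a root seed is mandatory for reproducibility", call. = FALSE)
  }
  counts <- c(n_nhi_young, n_nhi_elderly, n_pwa_young, n_pwa_elderly)
  if (any(counts < 0)) stop("cohort sizes must be >= 0", call. = FALSE)
  if (pwa_theta_sd < 0 || nhi_theta_sd < 0) {
    stop("theta scales must be >= 0", call. = FALSE)
  }
  params <- subtest_params %||% default_subtest_params()
  for (col in c("resid_sd", "guess", "lapse")) {
    if (!col %in% names(params)) params[[col]] <- 0
  }
  if (any(params$a <= 0)) stop("discriminations must be > 0", call. = FALSE)
  if (any(params$resid_sd < 0)) {
    stop("residual factor sds must be >= 0", call. = FALSE)
  }
  if (any(params$guess < 0 | params$lapse < 0 |
            params$guess + params$lapse >= 1)) {
    stop("guess/lapse rates must be >= 0 with guess + lapse < 1",
         call. = FALSE)
  }
  structure(list(
    n_nhi_young = n_nhi_young, n_nhi_elderly = n_nhi_elderly,
    n_pwa_young = n_pwa_young, n_pwa_elderly = n_pwa_elderly,
    pwa_theta_mean = pwa_theta_mean, pwa_theta_sd = pwa_theta_sd,
    nhi_theta_mean = nhi_theta_mean, nhi_theta_sd = nhi_theta_sd,
    elderly_penalty = elderly_penalty,
    elderly_lapse = elderly_lapse,
    paraphasia_share = paraphasia_share,
    subtest_params = params,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @details `default_subtest_params()` returns the frozen calibration table.
#'   Per subtest: discrimination `a` (matched to each subtest's
#'   internal-consistency level), difficulty `b0` (solves the mean patient
#'   item passing-rate target under the full latent model), item `spread`,
#'   the sd of a stable subtest-specific residual ability factor
#'   (`resid_sd`: task demands not shared with the common language factor,
#'   e.g. pragmatics/memory for discourse, priming for sentence
#'   production), the chance-level `guess` floor of forced-choice formats,
#'   and the attentional `lapse` rate. Item difficulties are
#'   `b0 + spread * qnorm((j - 0.5) / n)`.
#' @export
default_subtest_params <- function() {
  data.frame(
    subtest_id = SUBTEST_IDS,
    a = c(3.5, 3.5, 2.5, 2, 2.5, 3, 2, 2, 2, 2, 2, 2, 1),
    b0 = c(-0.504, -0.805, -1.789, -1.698, -0.613, -1.344, 0.303, -0.740,
           -0.382, -0.412, -0.205, -0.078, 0.519),
    spread = c(0.9, 0.9, 0.5, 0.5, 0.9, 0.7, 0.9, 0.9, 0.7, 0.9, 0.9,
               0.8, 0.3),
    resid_sd = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.8, 0.3, 0.3, 0.4, 0.3, 0.3,
                 0.6, 0.6),
    # forced-choice comprehension formats guess at chance (same/different
    # and yes/no: .5; four-picture matching: .25); open-ended repetition,
    # naming and production have no guessing floor. The discourse
    # comprehension lapse rate models attention/memory slips on the
    # 16-statement story that occur regardless of language ability.
    guess = c(0.5, 0.5, 0.25, 0.25, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0),
    lapse = c(0, 0, 0, 0, 0, 0.05, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

AGE_SENSITIVE_SUBTESTS <- c("discourse_comprehension", "nonword_repetition",
                            "sentence_repetition", "sentence_production")

item_difficulties <- function(spec, subtest_id, n_items) {
  p <- spec$subtest_params[spec$subtest_params$subtest_id == subtest_id, ]
  z <- stats::qnorm((seq_len(n_items) - 0.5) / n_items)
  list(a = p$a, b = p$b0 + p$spread * z,
       guess = if ("guess" %in% names(p)) p$guess else 0,
       lapse = if ("lapse" %in% names(p)) p$lapse else 0)
}

#' Simulate a full synthetic cohort
#'
#' Draws all participants of the specification (controls and patients, both
#' age cohorts), generates every trial-level response, and scores them.
#' [simulate_nhi()] and [simulate_pwa()] generate only one group.
#'
#' @param spec A [cohort_spec()].
#' @param groups Which groups to generate (default both).
#' @return List of class `synthetic_cohort`: `participants` (ids, labels,
#'   latent theta), `profiles` (accuracies + GAQ, as
#'   [participant_profiles()]), `items` (per-subtest participant x item
#'   score matrices), `ann` (raw annotations for trial export), `spec`.
#' @export
simulate_cohort <- function(spec, groups = c("NHI", "PWA")) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- data.frame(
    group = rep(c("NHI", "NHI", "PWA", "PWA"),
                c(spec$n_nhi_young, spec$n_nhi_elderly,
                  spec$n_pwa_young, spec$n_pwa_elderly)),
    age_cohort = rep(c("young", "elderly", "young", "elderly"),
                     c(spec$n_nhi_young, spec$n_nhi_elderly,
                       spec$n_pwa_young, spec$n_pwa_elderly)),
    stringsAsFactors = FALSE)
  plan$participant_id <- sprintf("%s_%s_%03d", tolower(plan$group),
                                 plan$age_cohort,
                                 stats::ave(seq_len(nrow(plan)),
                                            plan$group, plan$age_cohort,
                                            FUN = seq_along))
  # per-participant sub-seeds from the root seed: regeneration is identical
  # and independent of which groups are requested
  set.seed(spec$seed)
  plan$sub_seed <- sample.int(.Machine$integer.max - 1, nrow(plan))
  # seeds for the stable subtest-specific residual factors: kept with the
  # participant so retest sessions reuse the same residual abilities
  plan$resid_seed <- sample.int(.Machine$integer.max - 1, nrow(plan))
  plan$theta <- ifelse(
    plan$group == "NHI",
    stats::rnorm(nrow(plan), spec$nhi_theta_mean, spec$nhi_theta_sd),
    stats::rnorm(nrow(plan), spec$pwa_theta_mean, spec$pwa_theta_sd))
  plan <- plan[plan$group %in% groups, , drop = FALSE]
  if (nrow(plan) == 0) stop("no participants requested", call. = FALSE)
  sim <- generate_participants(plan, spec)
  sim$spec <- spec
  class(sim) <- "synthetic_cohort"
  sim
}

#' @rdname simulate_cohort
#' @export
simulate_nhi <- function(spec) simulate_cohort(spec, groups = "NHI")

#' @rdname simulate_cohort
#' @export
simulate_pwa <- function(spec) simulate_cohort(spec, groups = "PWA")

generate_participants <- function(plan, spec, theta_override = NULL) {
  n <- nrow(plan)
  cat13 <- subtest_catalogue()
  sr_words <- attr(cat13, "sr_word_counts")
  theta <- theta_override %||% plan$theta
  resid <- t(vapply(plan$resid_seed, function(s) {
    set.seed(s)
    stats::rnorm(length(SUBTEST_IDS)) * spec$subtest_params$resid_sd
  }, numeric(length(SUBTEST_IDS))))
  items <- list()
  ann <- list()
  for (st in SUBTEST_IDS) {
    def <- catalogue_entry(st, cat13)
    th <- theta + resid[, match(st, SUBTEST_IDS)] -
      ifelse(plan$age_cohort == "elderly" & st %in% AGE_SENSITIVE_SUBTESTS,
             spec$elderly_penalty, 0)
    ip <- item_difficulties(spec, st, switch(
      st, discourse_comprehension = 16L, discourse_production = 4L,
      def$n_items))
    lapse_i <- ip$lapse + ifelse(ip$lapse > 0 &
                                   plan$age_cohort == "elderly",
                                 spec$elderly_lapse %||% 0, 0)
    pmat <- ip$guess + (1 - ip$guess - lapse_i) *
      stats::plogis(ip$a * outer(th, ip$b, `-`))
    gen <- switch(
      def$rule,
      binary = ,
      naming = {
        resp <- draw_per_participant(plan, pmat, function(p, r)
          r(length(p)) < p)
        list(score = resp * 1, ann = list(response = resp))
      },
      repetition = {
        codes <- draw_per_participant(plan, pmat, function(p, r) {
          u1 <- r(length(p)); u2 <- r(length(p))
          ifelse(u1 < p, "correct",
                 ifelse(u2 < spec$paraphasia_share,
                        "phonological_paraphasia", "other_error"))
        })
        score <- matrix(c(correct = 1, phonological_paraphasia = 0.5,
                          word_form_error = 0.5, omission = 0,
                          other_error = 0)[codes], nrow = n)
        list(score = score, ann = list(code = codes))
      },
      sentence_repetition = {
        gen_sentence_repetition(plan, pmat, th, sr_words, spec)
      },
      criteria = {
        # four criteria per sentence with fixed criterion offsets
        offs <- c(0, 0.15, -0.15, 0.3)
        crit <- array(NA, c(n, def$n_items, 4))
        for (k in 1:4) {
          pk <- stats::plogis(ip$a * (outer(th, ip$b + offs[k], `-`)))
          crit[, , k] <- draw_per_participant(plan, pk, function(p, r)
            r(length(p)) < p, stream = k)
        }
        list(score = apply(crit, c(1, 2), sum),
             ann = list(criteria = crit))
      },
      ratings = {
        ratings <- draw_per_participant(plan, pmat, function(p, r) {
          1 + stats::qbinom(r(length(p)), 4, p)
        })
        list(score = matrix(rowSums(ratings), ncol = 1),
             ann = list(ratings = ratings))
      },
      discourse_comprehension_pair = {
        resp <- draw_per_participant(plan, pmat, function(p, r)
          r(length(p)) < p)
        pair <- resp[, seq(1, 15, 2), drop = FALSE] &
          resp[, seq(2, 16, 2), drop = FALSE]
        list(score = pair * 1, ann = list(response = resp))
      },
      stop("no generator for rule ", def$rule))
    items[[st]] <- gen$score
    ann[[st]] <- gen$ann
  }
  profiles <- plan[, c("participant_id", "group", "age_cohort")]
  for (st in SUBTEST_IDS) {
    def <- catalogue_entry(st, cat13)
    profiles[[st]] <- 100 * rowSums(items[[st]]) / def$max_total
  }
  profiles$gaq <- rowMeans(as.matrix(profiles[, SUBTEST_IDS]))
  part <- plan[, c("participant_id", "group", "age_cohort", "sub_seed",
                   "resid_seed")]
  part$theta <- theta
  list(participants = part, profiles = profiles, items = items, ann = ann)
}

# Runs `fn(p_row, runif)` once per participant under that participant's
# sub-seed (offset by `stream` so different payload parts reuse nothing).
draw_per_participant <- function(plan, pmat, fn, stream = 0) {
  out <- NULL
  for (i in seq_len(nrow(plan))) {
    set.seed((plan$sub_seed[i] + stream) %% .Machine$integer.max)
    row <- fn(pmat[i, ], stats::runif)
    if (is.null(out)) {
      out <- matrix(row, nrow = nrow(plan), ncol = length(row), byrow = TRUE)
    }
    out[i, ] <- row
  }
  out
}

gen_sentence_repetition <- function(plan, pmat, th, sr_words, spec) {
  n <- nrow(plan)
  n_sent <- length(sr_words)
  codes <- vector("list", n)
  order_err <- matrix(FALSE, n, n_sent)
  score <- matrix(0, n, n_sent)
  word_pts <- c(correct = 1, phonological_paraphasia = 0.5,
                word_form_error = 0.5, omission = 0, other_error = 0)
  for (i in seq_len(n)) {
    set.seed((plan$sub_seed[i] + 7L) %% .Machine$integer.max)
    p_ord <- stats::plogis(-(th[i] + 1))
    sent <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      nw <- sr_words[s]
      u1 <- stats::runif(nw); u2 <- stats::runif(nw); u3 <- stats::runif(nw)
      wc <- ifelse(u1 < pmat[i, s], "correct",
            ifelse(u2 < spec$paraphasia_share,
                   ifelse(u3 < 0.5, "phonological_paraphasia",
                          "word_form_error"),
                   ifelse(u3 < 0.5, "omission", "other_error")))
      oe <- stats::runif(1) < p_ord
      sent[[s]] <- wc
      order_err[i, s] <- oe
      score[i, s] <- max(sum(word_pts[wc]) - as.numeric(oe), 0)
    }
    codes[[i]] <- sent
  }
  list(score = score,
       ann = list(word_codes = codes, order_error = order_err))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$participants$group, x$participants$age_cohort)
  cat("Synthetic cohort (seed ", x$spec$seed, ")\n", sep = "")
  print(tab)
  invisible(x)
}

#' Second-rater annotations for the manually scored subtests
#'
#' Emulates an independent trained rater re-scoring the recorded verbal
#' responses of the repetition and production subtests (comprehension
#' subtests are scored automatically by the application and have no rater
#' component). The second rater's item scores are the first rater's
#' perturbed on each subtest's legal score lattice: one-point and half-point
#' items move one lattice step up or down with probability `flip_prob`
#' (clamped to the legal range), discourse-production ratings are shifted
#' by `rating_shift` plus Gaussian noise of sd `rating_sd` and re-clamped to
#' 1..5.
#'
#' @param sim A `synthetic_cohort`.
#' @param rater_model List: `flip_prob` (default .05), `rating_sd`
#'   (default .7), `rating_shift` (default 0) — a nonzero shift models a
#'   systematically stricter/more lenient rater, penalized by absolute-
#'   agreement ICC but not by consistency.
#' @param subtests Expressive subtests to re-rate (default all repetition
#'   and production subtests). Requesting a comprehension subtest is an
#'   error.
#' @param seed Seed for the rater-noise stream.
#' @return List of per-subtest second-rater score matrices, plus
#'   `accuracies`: data.frame of per-participant subtest accuracies for
#'   rater 1 and rater 2, ready for [icc_a1()].
#' @export
simulate_raters <- function(sim, rater_model = list(), subtests = NULL,
                            seed = sim$spec$seed + 1L) {
  rm_ <- utils::modifyList(list(flip_prob = 0.05, rating_sd = 0.7,
                                rating_shift = 0), rater_model)
  if (rm_$flip_prob < 0 || rm_$rating_sd < 0) {
    stop("rater noise parameters must be >= 0", call. = FALSE)
  }
  cat13 <- subtest_catalogue()
  expressive <- cat13$subtest_id[cat13$domain != "comprehension"]
  subtests <- subtests %||% expressive
  if (any(!subtests %in% expressive)) {
    stop("comprehension subtests are scored automatically by the ",
         "application; rater noise applies only to: ",
         paste(expressive, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  rater2 <- list()
  acc <- list()
  for (st in subtests) {
    def <- catalogue_entry(st, cat13)
    s1 <- sim$items[[st]]
    if (st == "discourse_production") {
      r1 <- sim$ann[[st]]$ratings
      r2 <- round(r1 + rm_$rating_shift +
                    stats::rnorm(length(r1), 0, rm_$rating_sd))
      r2 <- pmin(pmax(r2, 1), 5)
      s2 <- matrix(rowSums(r2), ncol = 1)
    } else if (st == "sentence_repetition") {
      sr_words <- attr(cat13, "sr_word_counts")
      mx <- matrix(sr_words, nrow(s1), length(sr_words), byrow = TRUE)
      s2 <- perturb_lattice(s1, mx, def$step, rm_)
    } else {
      mx <- matrix(def$item_max, nrow(s1), ncol(s1))
      s2 <- perturb_lattice(s1, mx, def$step, rm_)
    }
    rater2[[st]] <- s2
    acc[[st]] <- data.frame(
      participant_id = sim$participants$participant_id, subtest_id = st,
      rater1 = 100 * rowSums(s1) / def$max_total,
      rater2 = 100 * rowSums(s2) / def$max_total,
      stringsAsFactors = FALSE)
  }
  list(rater2 = rater2, accuracies = do.call(rbind, acc),
       rater_model = rm_)
}

perturb_lattice <- function(s, mx, step, rm_) {
  move <- matrix(stats::runif(length(s)) < rm_$flip_prob, nrow(s))
  dir <- matrix(sign(stats::runif(length(s)) - 0.5), nrow(s))
  s2 <- s + move * dir * step
  pmin(pmax(s2, 0), mx)
}

#' Retest session for a chronic cohort
#'
#' Regenerates every trial at a second session for the same participants,
#' whose latent ability at session 2 is `theta + N(0, session_sd)` — the
#' stability assumption for chronic-phase patients with no treatment
#' between sessions. All item draws are fresh, so even `session_sd = 0`
#' yields test-retest disagreement wherever item-level randomness matters
#' (the mechanism that depresses retest reliability of near-ceiling
#' subtests despite their high internal consistency).
#'
#' @param sim A `synthetic_cohort` (chronic phase assumed).
#' @param session_sd Sd of the latent-trait session wobble (default 0.3).
#' @param seed Seed for the session-2 draws.
#' @return A `synthetic_cohort` for session 2 (same participants).
#' @export
simulate_retest <- function(sim, session_sd = 0.3,
                            seed = sim$spec$seed + 2L) {
  if (session_sd < 0) stop("session_sd must be >= 0", call. = FALSE)
  plan <- sim$participants
  set.seed(seed)
  plan$sub_seed <- sample.int(.Machine$integer.max - 1, nrow(plan))
  theta2 <- plan$theta + stats::rnorm(nrow(plan), 0, session_sd)
  out <- generate_participants(plan, sim$spec, theta_override = theta2)
  out$spec <- sim$spec
  class(out) <- "synthetic_cohort"
  out
}

#' Concurrent severity measure correlated with the latent trait
#'
#' Emulates an established aphasia battery's total score for the patient
#' group: a linear function of the latent trait plus calibrated noise, on a
#' 0-100 scale. The noise sd is chosen from the observed GAQ-theta
#' correlation so that `cor(GAQ, external)` lands near `target_r` in large
#' samples.
#'
#' @param sim A `synthetic_cohort` containing patients.
#' @param target_r Target Pearson correlation with the GAQ, in (0, 1)
#'   (default .925).
#' @param seed Seed for the noise stream.
#' @return Data.frame: `participant_id`, `external_total` (patients only).
#' @export
simulate_concurrent_severity <- function(sim, target_r = 0.925,
                                         seed = sim$spec$seed + 3L) {
  if (target_r <= 0 || target_r >= 1) {
    stop("target_r must be in (0, 1)", call. = FALSE)
  }
  pwa <- sim$participants$group == "PWA"
  if (!any(pwa)) stop("cohort contains no patients", call. = FALSE)
  theta <- sim$participants$theta[pwa]
  gaq <- sim$profiles$gaq[pwa]
  r_tg <- stats::cor(theta, gaq)
  if (r_tg <= target_r) {
    stop("target_r exceeds the GAQ-theta correlation (", round(r_tg, 3),
         "); unattainable by adding noise", call. = FALSE)
  }
  noise_sd <- sqrt((r_tg / target_r)^2 - 1)
  set.seed(seed)
  ext <- 50 + 12 * (theta + stats::rnorm(length(theta), 0, noise_sd))
  data.frame(participant_id = sim$participants$participant_id[pwa],
             external_total = pmin(pmax(ext, 0), 100),
             stringsAsFactors = FALSE)
}

#' Export a synthetic cohort as a long trial table
#'
#' Emits the exact trial-CSV dialect consumed by [score_trials()] /
#' [read_trial_csv()], one row per scored trial (per statement for
#' discourse comprehension), with multi-part payloads serialized as
#' semicolon-joined fields.
#'
#' @param sim A `synthetic_cohort`.
#' @return Trial data.frame.
#' @export
as_trial_data <- function(sim) {
  cat13 <- subtest_catalogue()
  part <- sim$participants
  rows <- list()
  for (st in SUBTEST_IDS) {
    def <- catalogue_entry(st, cat13)
    a <- sim$ann[[st]]
    n <- nrow(part)
    base <- function(n_items) data.frame(
      participant_id = rep(part$participant_id, each = n_items),
      group = rep(part$group, each = n_items),
      age_cohort = rep(part$age_cohort, each = n_items),
      subtest_id = st,
      item_id = rep(sprintf("%s_%02d", abbreviate_id(st), seq_len(n_items)),
                    n),
      response = NA, code = NA_character_, word_codes = NA_character_,
      order_error = NA, criteria = NA_character_, ratings = NA_character_,
      stringsAsFactors = FALSE)
    df <- switch(
      def$rule,
      binary = , naming = {
        d <- base(ncol(a$response))
        d$response <- as.integer(t(a$response)); d
      },
      discourse_comprehension_pair = {
        d <- base(ncol(a$response))
        d$response <- as.integer(t(a$response)); d
      },
      repetition = {
        d <- base(ncol(a$code)); d$code <- as.vector(t(a$code)); d
      },
      sentence_repetition = {
        d <- base(length(attr(cat13, "sr_word_counts")))
        d$word_codes <- unlist(lapply(a$word_codes, vapply, paste,
                                      "", collapse = ";"))
        d$order_error <- as.integer(t(a$order_error)); d
      },
      criteria = {
        d <- base(dim(a$criteria)[2])
        cmat <- apply(a$criteria, c(1, 2), function(v)
          paste(as.integer(v), collapse = ";"))
        d$criteria <- as.vector(t(cmat)); d
      },
      ratings = {
        d <- base(1)
        d$ratings <- apply(a$ratings, 1, paste, collapse = ";"); d
      })
    rows[[st]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

abbreviate_id <- function(st) {
  paste(substr(strsplit(st, "_", fixed = TRUE)[[1]], 1, 2), collapse = "")
}
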