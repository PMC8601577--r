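test_that("cohort specification validates its inputs", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(n_nhi_young = -1, seed = 1), ">= 0")
  expect_error(cohort_spec(pwa_theta_sd = -2, seed = 1), ">= 0")
  sp <- tiny_spec(3)
  expect_s3_class(sp, "cohort_spec")
  expect_equal(nrow(sp$subtest_params), 13)
})

test_that("identical (spec, seed) regenerate identical datasets", {
  a <- simulate_cohort(tiny_spec(101))
  b <- simulate_cohort(tiny_spec(101))
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$items, b$items)
  c <- simulate_cohort(tiny_spec(102))
  expect_false(identical(a$profiles$gaq, c$profiles$gaq))
  # generating only one group reproduces the same participants as the full
  # cohort (per-participant sub-streams)
  full <- simulate_cohort(tiny_spec(101))
  nhi <- simulate_nhi(tiny_spec(101))
  keep <- full$participants$group == "NHI"
  expect_equal(nhi$profiles$gaq, full$profiles$gaq[keep])
})

test_that("all generated scores live on each subtest's legal lattice", {
  sim <- simulate_cohort(tiny_spec(103))
  cat13 <- subtest_catalogue()
  for (st in SUBTEST_IDS) {
    def <- cat13[cat13$subtest_id == st, ]
    s <- sim$items[[st]]
    expect_true(all(s >= 0))
    expect_true(all(abs(s / def$step - round(s / def$step)) < 1e-9),
                label = paste(st, "on lattice"))
    if (st == "sentence_repetition") {
      expect_true(all(s <= matrix(attr(cat13, "sr_word_counts"),
                                  nrow(s), 12, byrow = TRUE)))
    } else {
      expect_true(all(s <= def$item_max))
    }
  }
  expect_true(all(sim$profiles$discourse_production >= 20))
})

test_that("higher latent ability stochastically raises every accuracy", {
  lo <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                 n_pwa_young = 150, n_pwa_elderly = 0,
                                 pwa_theta_mean = -1, seed = 104))
  hi <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                 n_pwa_young = 150, n_pwa_elderly = 0,
                                 pwa_theta_mean = 1, seed = 104))
  for (st in SUBTEST_IDS) {
    expect_gt(mean(hi$profiles[[st]]), mean(lo$profiles[[st]]))
  }
  # extreme ability reaches the ceiling everywhere except discourse
  # comprehension, whose lapse rate caps even unimpaired performance;
  # with lapses disabled the ceiling is exact
  ceiling_sim <- simulate_pwa(cohort_spec(
    n_nhi_young = 0, n_nhi_elderly = 0, n_pwa_young = 5, n_pwa_elderly = 0,
    pwa_theta_mean = 30, pwa_theta_sd = 0, seed = 105))
  expect_true(all(ceiling_sim$profiles[
    , setdiff(SUBTEST_IDS, "discourse_comprehension")] == 100))
  nolapse <- default_subtest_params()
  nolapse$lapse <- 0
  exact <- simulate_pwa(cohort_spec(
    n_nhi_young = 0, n_nhi_elderly = 0, n_pwa_young = 5, n_pwa_elderly = 0,
    pwa_theta_mean = 30, pwa_theta_sd = 0, subtest_params = nolapse,
    seed = 105))
  expect_true(all(exact$profiles$gaq == 100))
  # extreme impairment floors: open-ended subtests at their structural
  # floor, forced-choice comprehension at chance level
  floor_sim <- simulate_pwa(cohort_spec(
    n_nhi_young = 0, n_nhi_elderly = 0, n_pwa_young = 40, n_pwa_elderly = 0,
    pwa_theta_mean = -30, pwa_theta_sd = 0, seed = 105))
  expect_true(all(floor_sim$profiles$discourse_production == 20))
  # at floor every repetition target fails; the paraphasia share still
  # earns half credit, so the expected floor is paraphasia_share / 2
  expect_equal(mean(floor_sim$profiles$word_repetition), 20, tolerance = 0.1)
  expect_true(all(floor_sim$profiles$sentence_production == 0))
  expect_equal(mean(floor_sim$profiles$noun_comprehension), 25,
               tolerance = 0.15)
  expect_equal(mean(floor_sim$profiles$lexical_decision), 50,
               tolerance = 0.1)
})

test_that("patient passing-rate family means land in the observed ranges", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 250, n_pwa_elderly = 250,
                                  seed = 106))
  cat13 <- subtest_catalogue()
  rates <- vapply(SUBTEST_IDS, function(st) {
    def <- cat13[cat13$subtest_id == st, ]
    im <- if (st == "sentence_repetition")
      attr(cat13, "sr_word_counts") else def$item_max
    mean(item_passing_rates(sim$items[[st]], im))
  }, numeric(1))
  fam <- split(rates, cat13$domain[match(names(rates), cat13$subtest_id)])
  expect_gt(mean(fam$comprehension), 0.77)
  expect_lt(mean(fam$comprehension), 0.94)
  expect_gt(mean(fam$repetition), 0.51)
  expect_lt(mean(fam$repetition), 0.75)
  expect_gt(mean(fam$production), 0.44)
  expect_lt(mean(fam$production), 0.64)
})

test_that("controls perform near ceiling except discourse/sentence production", {
  sim <- simulate_nhi(cohort_spec(n_nhi_young = 200, n_nhi_elderly = 0,
                                  n_pwa_young = 0, n_pwa_elderly = 0,
                                  seed = 107))
  binary_comp <- c("nonword_discrimination", "lexical_decision",
                   "noun_comprehension", "verb_comprehension",
                   "sentence_comprehension")
  for (st in binary_comp) {
    expect_gte(median(sim$profiles[[st]]), 95)
  }
  # the off-ceiling subtests show real variance in controls
  for (st in c("discourse_production", "sentence_production")) {
    expect_lt(median(sim$profiles[[st]]), 100)
    expect_gt(sd(sim$profiles[[st]]), 1)
  }
})

test_that("elderly controls score lower only on age-sensitive subtests", {
  sim <- simulate_nhi(cohort_spec(n_nhi_young = 400, n_nhi_elderly = 400,
                                  n_pwa_young = 0, n_pwa_elderly = 0,
                                  seed = 108))
  pr <- sim$profiles
  young <- pr$age_cohort == "young"
  for (st in c("discourse_comprehension", "nonword_repetition",
               "sentence_repetition", "sentence_production")) {
    expect_gt(mean(pr[[st]][young]) - mean(pr[[st]][!young]), 0.5)
  }
  # a non-age-sensitive subtest shows no such gap
  expect_lt(abs(mean(pr$noun_comprehension[young]) -
                  mean(pr$noun_comprehension[!young])), 0.5)
})

test_that("simulated trials round-trip through the scoring engine", {
  sim <- simulate_cohort(cohort_spec(n_nhi_young = 3, n_nhi_elderly = 2,
                                     n_pwa_young = 3, n_pwa_elderly = 2,
                                     seed = 109))
  trials <- as_trial_data(sim)
  prof <- participant_profiles(score_trials(trials))
  prof <- prof[match(sim$profiles$participant_id, prof$participant_id), ]
  for (st in SUBTEST_IDS) {
    expect_equal(prof[[st]], sim$profiles[[st]], tolerance = 1e-12,
                 label = st)
  }
  expect_equal(prof$gaq, sim$profiles$gaq, tolerance = 1e-12)
})

test_that("noise-free raters agree perfectly; noisy raters are penalized", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 20, n_pwa_elderly = 0,
                                  seed = 110))
  clean <- simulate_raters(sim, list(flip_prob = 0, rating_sd = 0))
  for (st in unique(clean$accuracies$subtest_id)) {
    sub <- clean$accuracies[clean$accuracies$subtest_id == st, ]
    expect_equal(icc_a1(cbind(sub$rater1, sub$rater2))$value, 1)
  }
  expect_error(simulate_raters(sim, subtests = "noun_comprehension"),
               "scored automatically")
  expect_error(simulate_raters(sim, list(flip_prob = -0.1)), ">= 0")
})

test_that("a shift-only rater keeps consistency but loses absolute agreement", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 40, n_pwa_elderly = 0,
                                  seed = 111))
  shifted <- simulate_raters(sim, list(flip_prob = 0, rating_sd = 0,
                                       rating_shift = 1),
                             subtests = "discourse_production")
  sub <- shifted$accuracies
  # keep narratives whose ratings cannot hit the 5-point clamp after +1
  keep <- apply(sim$ann$discourse_production$ratings, 1, max) <= 4
  m <- cbind(sub$rater1, sub$rater2)[keep, ]
  expect_equal(cor(m[, 1], m[, 2]), 1, tolerance = 1e-12)  # consistency
  expect_lt(icc_a1(m)$value, 1)                             # agreement
})

test_that("calibrated rater noise lands ICC in the variance-component band", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 300, n_pwa_elderly = 0,
                                  seed = 112))
  flip <- 0.05
  noisy <- simulate_raters(sim, list(flip_prob = flip),
                           subtests = "word_repetition")
  sub <- noisy$accuracies
  m <- cbind(sub$rater1, sub$rater2)
  # a lattice flip changes an item by +-0.5 w.p. flip (half blocked at the
  # boundary scores); accuracy-scale noise variance per rater is at most
  # flip * (100 * 0.5 / 24)^2 * 24 and at least half that
  v_max <- flip * (100 * 0.5)^2 / 24
  sig_b <- var(sub$rater1)
  band <- range(sig_b / (sig_b + v_max), sig_b / (sig_b + v_max / 4))
  icc <- icc_a1(m)$value
  expect_gt(icc, band[1] - 0.05)
  expect_lt(icc, band[2] + 0.02)
})

test_that("retest regenerates sessions under the stability assumption", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 60, n_pwa_elderly = 0,
                                  seed = 113))
  s2 <- simulate_retest(sim, session_sd = 0.3)
  expect_equal(s2$participants$participant_id,
               sim$participants$participant_id)
  # no systematic session effect: paired t on GAQ non-significant
  expect_gt(t.test(sim$profiles$gaq, s2$profiles$gaq, paired = TRUE)$p.value,
            0.05)
  # session_sd = 0 still shows item-level wobble but high GAQ agreement
  s0 <- simulate_retest(sim, session_sd = 0)
  expect_false(identical(s0$profiles$gaq, sim$profiles$gaq))
  expect_gt(icc_a1(cbind(sim$profiles$gaq, s0$profiles$gaq))$value, 0.9)
  expect_error(simulate_retest(sim, session_sd = -1), ">= 0")
})

test_that("concurrent severity totals track the GAQ at the target correlation", {
  sim <- simulate_pwa(cohort_spec(n_nhi_young = 0, n_nhi_elderly = 0,
                                  n_pwa_young = 1000, n_pwa_elderly = 1000,
                                  seed = 114))
  ext <- simulate_concurrent_severity(sim, target_r = 0.9)
  r <- cor(sim$profiles$gaq, ext$external_total)
  expect_equal(r, 0.9, tolerance = 0.03)
  # shuffling breaks the association
  set.seed(115)
  r_sh <- cor(sim$profiles$gaq, sample(ext$external_total))
  expect_lt(abs(r_sh), 0.1)
  expect_error(simulate_concurrent_severity(sim, target_r = 1.2), "(0, 1)")
  expect_true(all(ext$external_total >= 0 & ext$external_total <= 100))
})
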