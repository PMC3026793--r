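test_that("participant generation matches the configured cohort", {
  cfg <- generativeConfig(nControls = 25, nCP = 13)
  p <- generateParticipants(cfg, seed = 42)
  expect_equal(nrow(p), 38)
  expect_equal(sum(p$group == "control"), 25)
  expect_equal(sum(p$group == "CP"), 13)
  expect_true(all(p$age >= 18 & p$age <= 80))
  expect_true(all(p$tv_band %in% 1:4) && all(p$print_band %in% 1:4))
  expect_true(all(p$questionnaire_total >= 15 & p$questionnaire_total <= 75))
  # identical seed reproduces identical tables
  expect_identical(p, generateParticipants(cfg, seed = 42))
  expect_false(identical(p, generateParticipants(cfg, seed = 43)))
})

test_that("ages follow the configured truncated normal", {
  cfg <- generativeConfig(nControls = 10000, nCP = 0)
  p <- generateParticipants(cfg, seed = 7)
  # closed-form mean of N(37.3, 17.9^2) truncated to [18, 80]
  a <- (18 - 37.3) / 17.9; b <- (80 - 37.3) / 17.9
  truncMean <- 37.3 + 17.9 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(p$age) / sqrt(nrow(p))
  expect_lt(abs(mean(p$age) - truncMean), 3 * se)
})

test_that("trial schedules are balanced and sized by the design", {
  sch <- generateTrialSchedule(studyDesign(), seed = 3)
  expect_equal(sum(sch$part == 1), 160)
  expect_equal(sum(sch$part == 2), 160)
  expect_equal(length(unique(sch$stimulus_id)), 20)
  # every stimulus exactly repetitionsPerPart times in every part
  expect_true(all(table(sch$stimulus_id, sch$part) == 8))
  # trial indices are a permutation within each part
  for (pt in 1:2)
    expect_setequal(sch$trial_index[sch$part == pt], 1:160)
  # part 1 rotated, part 2 frontal
  expect_true(all(sch$rotation[sch$part == 1] == "rotated"))
  expect_true(all(sch$rotation[sch$part == 2] == "frontal"))
  # illumination on target trials only
  expect_true(all(is.na(sch$illumination) == (sch$trial_type == "distractor")))
  sml <- generateTrialSchedule(studyDesign(repetitionsPerPart = 1), seed = 1)
  expect_equal(sum(sml$part == 1), 20)
  expect_true(all(table(sml$stimulus_id[sml$part == 1]) == 1))
})

test_that("response simulation follows the logistic model", {
  cfg <- generativeConfig(nControls = 20, nCP = 20)
  parts <- generateParticipants(cfg, seed = 5)
  sch <- generateTrialSchedule(studyDesign(), seed = 5)
  # null model: everything zero -> pooled accuracy 1/2
  e0 <- experimentEffects(intercept = 0, age = 0, trialType = 0,
                          rotation = 0, sdIntercept = 0)
  tr0 <- simulateResponses(parts, sch, e0, seed = 6)
  n <- nrow(tr0)
  expect_lt(abs(mean(tr0$correct) - 0.5), 3 * sqrt(0.25 / n))
  # saturation: huge intercept -> all correct
  eSat <- experimentEffects(intercept = 20, age = 0, trialType = 0,
                            rotation = 0, sdIntercept = 0)
  expect_true(all(simulateResponses(parts, sch, eSat, seed = 7)$correct == 1))
  # case main effect only -> case accuracy = inverse-logit(-1.04)
  eCP <- experimentEffects(intercept = 0, age = 0, trialType = 0,
                           rotation = 0, cp = -1.04, sdIntercept = 0)
  trCP <- simulateResponses(parts, sch, eCP, seed = 8)
  cpIds <- parts$id[parts$group == "CP"]
  acc <- mean(trCP$correct[trCP$participant_id %in% cpIds])
  pTrue <- plogis(-1.04)
  nCP <- sum(trCP$participant_id %in% cpIds)
  expect_lt(abs(acc - pTrue), 3 * sqrt(pTrue * (1 - pTrue) / nCP))
})

test_that("a negative case-by-trial-type effect produces a miss bias", {
  cfg <- generativeConfig(nControls = 5, nCP = 30)
  parts <- generateParticipants(cfg, seed = 9)
  sch <- generateTrialSchedule(studyDesign(), seed = 9)
  tr <- simulateResponses(parts, sch, cfg$faces, seed = 10)
  cc <- confusionCounts(tr, participantId = parts$id[parts$group == "CP"])
  missRate <- sum(cc$misses) / sum(cc$n_target_trials)
  faRate <- sum(cc$false_alarms) / sum(cc$n_distractor_trials)
  expect_gt(missRate, faRate)
})

test_that("famous-face recall responds to media consumption as configured", {
  cfg <- generativeConfig(nControls = 2000, nCP = 2000)
  parts <- generateParticipants(cfg, seed = 11)
  eff <- bfftEffects(tv = 0.4, print = 0.30, cpTv = 0, cpPrint = -0.30,
                     sdIntercept = 0)
  bf <- simulateBfft(parts, nItems = 25, effects = eff, seed = 12)
  rec <- tapply(bf$recalled, bf$participant_id, mean)[parts$id]
  ctl <- parts$group == "control"
  # controls: recall increases monotonically in tv band
  bandMeans <- tapply(rec[ctl], parts$tv_band[ctl], mean)
  expect_true(all(diff(bandMeans) > 0))
  # cases: print effect cancelled by the interaction -> flat in print band
  cp <- parts$group == "CP"
  printMeans <- tapply(rec[cp], parts$print_band[cp], mean)
  expect_lt(max(printMeans) - min(printMeans), 0.04)
  # all effects zero -> recall rate = inverse-logit(intercept)
  eZero <- bfftEffects(intercept = 0.8, age = 0, gender = 0, tv = 0,
                       print = 0, cp = 0, cpTv = 0, cpPrint = 0,
                       sdIntercept = 0)
  bz <- simulateBfft(parts[1:500, ], nItems = 30, effects = eZero, seed = 13)
  expect_lt(abs(mean(bz$recalled) - plogis(0.8)),
            3 * sqrt(0.25 / nrow(bz)))
})

test_that("questionnaire scoring is a validated 15-item sum", {
  expect_identical(scoreQuestionnaire(rep(1, 15)), 15L)
  expect_identical(scoreQuestionnaire(rep(5, 15)), 75L)
  expect_identical(scoreQuestionnaire(rep(1:5, 3)), 45L)
  expect_error(scoreQuestionnaire(rep(3, 14)), "15")
  expect_error(scoreQuestionnaire(c(rep(3, 14), 6)), "1..5")
  expect_error(scoreQuestionnaire(c(rep(3, 14), 0)), "1..5")
})

test_that("case questionnaire totals track latent ability inversely", {
  cfg <- generativeConfig(nControls = 0, nCP = 3000, questionnaireRho = 0.6)
  p <- generateParticipants(cfg, seed = 21)
  expect_lt(cor(p$questionnaire_total, p$latent_intercept), -0.3)
})
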