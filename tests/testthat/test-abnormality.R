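test_that("standardization is exact, affine-invariant and control-anchored", {
  r <- c(-1, 0, 1)
  z <- standardizeScores(r, c(r, -2))
  expect_equal(as.numeric(z), c(-1, 0, 1, -2))
  # control column mean 0, sd 1 by construction
  set.seed(10)
  rc <- rnorm(25, 0.02, 0.05)
  zc <- standardizeScores(rc)
  expect_lt(abs(mean(zc)), 1e-10)
  expect_lt(abs(sd(zc) - 1), 1e-10)
  # affine rescaling of all residuals leaves z unchanged
  a <- 3.7; b <- -0.2
  expect_equal(as.numeric(standardizeScores(a * rc + b)), as.numeric(zc),
               tolerance = 1e-12)
  expect_error(standardizeScores(rep(0.1, 5)), "positive")
})

test_that("case residuals are observed minus expected performance", {
  co <- tinyAggCohort(nCtl = 10, nCP = 5, seed = 12,
                      effects = experimentEffects(cp = -1.2))
  ctl <- co$agg[grepl("^C", co$agg$participant_id), ]
  cases <- co$agg[grepl("^P", co$agg$participant_id), ]
  fit <- fitGlmm(aggSpec(), ctl)
  cr <- caseResiduals(fit, cases)
  expect_equal(cr$residual, cr$observed - cr$expected, tolerance = 1e-12)
  expect_true(all(cr$observed >= 0 & cr$observed <= 1))
  expect_true(all(cr$expected >= 0 & cr$expected <= 1))
  # improving observed performance at fixed covariates raises the residual
  better <- cases
  ix <- better$participant_id == better$participant_id[1]
  better$n_correct[ix] <- pmin(better$n_trials[ix],
                               better$n_correct[ix] + 10)
  cr2 <- caseResiduals(fit, better)
  expect_gt(cr2$residual[1], cr$residual[1])
})

test_that("identical controls give zero leave-one-out residuals", {
  d <- data.frame(participant_id = rep(sprintf("C%02d", 1:6), each = 2),
                  x = rep(c(0, 1), 6),
                  n_correct = rep(c(70L, 50L), 6),
                  n_trials = 100L)
  spec <- modelSpec("n_correct", fixed = "x", random = NULL,
                    group = "participant_id", trials = "n_trials")
  loo <- looControlResiduals(spec, d)
  expect_equal(loo$residual, rep(0, 6), tolerance = 1e-10)
})

test_that("leave-one-out residuals match brute-force per-fold refits", {
  # logistic regression with an age covariate, no latent heterogeneity
  cfg <- generativeConfig(nControls = 12, nCP = 0)
  parts <- generateParticipants(cfg, seed = 16)
  agg <- cpmem:::simulateAggregatedLongTerm(
    parts, experimentEffects(sdIntercept = 0), studyDesign(), seed = 17)
  spec <- modelSpec("n_correct", fixed = c("age", "trial_type", "rotation"),
                    random = NULL, group = "participant_id",
                    trials = "n_trials")
  loo <- looControlResiduals(spec, agg)
  # brute force: direct likelihood maximization per fold via stats::glm
  for (id in parts$id) {
    tr <- agg[agg$participant_id != id, ]
    hd <- agg[agg$participant_id == id, ]
    g <- glm(cbind(n_correct, n_trials - n_correct) ~ age + trial_type +
               rotation, data = tr, family = binomial,
             control = list(epsilon = 1e-12))
    pr <- predict(g, newdata = hd, type = "response")
    res <- sum(hd$n_correct) / sum(hd$n_trials) -
      sum(pr * hd$n_trials) / sum(hd$n_trials)
    expect_equal(loo$residual[loo$participant_id == id], res,
                 tolerance = 1e-6)
  }
})

test_that("leave-one-out residuals are unbiased and wider than plug-in", {
  nC <- 15; nRep <- 30
  looAll <- plugVar <- looVar <- numeric(nRep)
  for (r in seq_len(nRep)) {
    co <- tinyAggCohort(nCtl = nC, seed = 300 + r)
    loo <- looControlResiduals(aggSpec(), co$agg)
    full <- attr(loo, "full_fit")
    plug <- caseResiduals(full, co$agg)
    looAll[r] <- mean(loo$residual)
    looVar[r] <- var(loo$residual)
    plugVar[r] <- var(plug$residual)
  }
  # mean of LOO residuals is zero within Monte Carlo error
  se <- sd(looAll) / sqrt(nRep)
  expect_lt(abs(mean(looAll)), 3 * se)
  # cross-validation inflates the residual variance vs the in-sample fit
  expect_gt(mean(looVar), mean(plugVar))
})

test_that("aggregates re-standardize member means against controls", {
  set.seed(20)
  g <- rep(c("control", "CP"), c(20, 6))
  a <- c(rnorm(20), rnorm(6, -2))
  a <- (a - mean(a[1:20])) / sd(a[1:20])
  m <- cbind(t1 = a, t2 = a, t3 = rnorm(26))
  m[26, "t3"] <- NA
  zt <- zScoreTable(m, g, sprintf("S%02d", 1:26))
  map <- list(category = c(t1 = "perceptual", t2 = "perceptual",
                           t3 = "mnestic"),
              aggregates = list(pair = c("t1", "t2"), solo = c("t3"),
                                all3 = c("t1", "t2", "t3")))
  ag <- aggregateScores(zt, map)
  # two perfectly correlated members: aggregate equals either member
  expect_equal(unname(unclass(ag)[, "pair"]), unname(a), tolerance = 1e-10)
  # single-member aggregate preserves ranks of the member column
  expect_equal(order(unclass(ag)[1:25, "solo"]), order(m[1:25, "t3"]))
  # participant missing a member still receives the mean of the rest
  expect_false(is.na(unclass(ag)[26, "all3"]))
  # participant missing all members is marked missing
  m2 <- m; m2[26, ] <- NA
  zt2 <- zScoreTable(m2, g, sprintf("S%02d", 1:26))
  ag2 <- aggregateScores(zt2, map)
  expect_true(is.na(unclass(ag2)[26, "all3"]))
  expect_error(aggregateScores(zt,
                 list(aggregates = list(none = character(0)))),
               "no existing columns")
  expect_warning(aggregateScores(zt, list(aggregates = list(gone = "zz"))),
                 "skipped")
})

test_that("the modified t-test uses the finite-control correction", {
  d0 <- deficitTest(0, nControls = 25)
  expect_equal(d0$t_statistic, 0)
  expect_equal(d0$p, 0.5)
  expect_false(d0$is_deficit)
  # boundary case engineered from the t quantile
  zb <- qt(0.05, df = 24) * sqrt(26 / 25)
  db <- deficitTest(zb, nControls = 25)
  expect_equal(db$p, 0.05, tolerance = 1e-12)
  # far tail
  expect_true(deficitTest(-5, nControls = 25)$is_deficit)
  expect_false(deficitTest(5, nControls = 25)$is_deficit)  # one-sided
  expect_error(deficitTest(0, nControls = 1), "at least 2")
})

test_that("direction-flipped external scores are negated at ingestion", {
  set.seed(23)
  g <- rep(c("control", "CP"), c(10, 4))
  rt <- c(rnorm(10), rnorm(4, 2))   # larger = slower = worse
  acc <- c(rnorm(10), rnorm(4, -2)) # larger = better
  sc <- cbind(rt_faces = rt, rotation_faces = acc)
  rownames(sc) <- sprintf("S%02d", 1:14)
  zt <- ingestExternalScores(sc, g, flipColumns = "rt_faces")
  # cases end up negative on both columns
  expect_true(all(colMeans(unclass(zt)[11:14, ]) < 0))
  # control anchoring after re-standardization
  expect_lt(max(abs(colMeans(unclass(zt)[1:10, ]))), 1e-10)
  expect_error(ingestExternalScores(sc, g, flipColumns = "nope"),
               "unknown column")
})
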