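test_that("Laplace fits agree with lme4::glmer on shared data", {
  skip_if_not_installed("lme4")
  co <- tinyAggCohort(nCtl = 20, nCP = 10, seed = 2,
                      effects = experimentEffects(cp = -1, sdIntercept = 0.5))
  d <- co$agg
  spec <- aggSpec(c("age", "trial_type", "rotation", "group"))
  f <- fitGlmm(spec, d)
  g <- lme4::glmer(
    cbind(n_correct, n_trials - n_correct) ~ age + trial_type + rotation +
      group + (1 | participant_id),
    data = d, family = binomial)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), unname(lme4::fixef(g)),
               tolerance = 1e-3)
  expect_equal(unname(f$random_sd), sqrt(unname(unlist(lme4::VarCorr(g)))),
               tolerance = 1e-2)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-4)
  # random intercept + slope variant
  d$tt_num <- as.numeric(d$trial_type == "target")
  spec2 <- aggSpec(random = c("intercept", "tt_num"))
  f2 <- fitGlmm(spec2, d)
  g2 <- lme4::glmer(
    cbind(n_correct, n_trials - n_correct) ~ age + trial_type + rotation +
      (1 + tt_num | participant_id),
    data = d, family = binomial)
  expect_equal(unname(f2$coefficients), unname(lme4::fixef(g2)),
               tolerance = 2e-3)
  expect_equal(f2$logLik, as.numeric(logLik(g2)), tolerance = 1e-3)
})

test_that("fits are deterministic and refuse broken inputs", {
  co <- tinyAggCohort(nCtl = 8, seed = 3)
  spec <- aggSpec()
  f1 <- fitGlmm(spec, co$agg)
  f2 <- fitGlmm(spec, co$agg)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$logLik, f2$logLik)
  expect_error(modelSpec("y", c("a", "a:b")), "main effects")
  expect_error(fitGlmm(spec, co$agg[, setdiff(names(co$agg), "age")]),
               "lack required columns")
  expect_error(modelSpec("y", "a", random = "slope_only"), "intercept")
})

test_that("separation is flagged, not silently returned", {
  d <- data.frame(participant_id = rep(letters[1:6], each = 2),
                  x = rep(c(0, 1), 6),
                  n_correct = rep(c(0L, 20L), 6),
                  n_trials = 20L)
  spec <- modelSpec("n_correct", fixed = "x", random = NULL,
                    group = "participant_id", trials = "n_trials")
  f <- suppressWarnings(fitGlmm(spec, d))
  expect_true("possible separation" %in% f$flags)
})

test_that("likelihood-ratio tests compare nested fits correctly", {
  co <- tinyAggCohort(nCtl = 15, nCP = 8, seed = 4)
  d <- co$agg
  s0 <- aggSpec()
  s1 <- aggSpec(c("age", "trial_type", "rotation", "group"))
  s2 <- aggSpec(c("age", "trial_type", "rotation", "group",
                  "group:trial_type", "group:rotation"))
  f0 <- fitGlmm(s0, d); f1 <- fitGlmm(s1, d); f2 <- fitGlmm(s2, d)
  # identical model against itself: D = 0, p = 1
  same <- lrTest(f0, fitGlmm(s0, d))
  expect_equal(same$D, 0, tolerance = 1e-6)
  expect_equal(same$p, 1)
  # parameter counting
  expect_equal(lrTest(f0, f1)$df, 1)
  expect_equal(lrTest(f1, f2)$df, 2)
  # adding parameters never decreases the maximized log-likelihood
  expect_gte(f1$logLik, f0$logLik - 1e-6)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
  # non-nested and mismatched data are refused
  expect_error(lrTest(f1, f0), "not a subset")
  expect_error(lrTest(fitGlmm(s0, d[d$participant_id != "C01", ]), f1),
               "different numbers")
})

test_that("null LR statistics follow their chi-squared reference", {
  lr <- lrTypeIError(nReplicates = 150, seed = 77)
  # Kolmogorov-Smirnov against chi^2_1 (coarse threshold: the chi^2
  # approximation for fixed effects is known to be slightly liberal)
  ks <- suppressWarnings(ks.test(lr$D, function(q) pchisq(q, df = 1)))
  expect_gt(ks$p.value, 0.001)
  se <- sqrt(0.05 * 0.95 / length(lr$p))
  expect_lt(abs(lr$rate - 0.05), 4 * se)
})

test_that("expected-performance predictions marginalise correctly", {
  co <- tinyAggCohort(nCtl = 12, seed = 6)
  spec <- aggSpec()
  f <- fitGlmm(spec, co$agg)
  nd <- co$agg[1:4, ]
  # conditional-at-zero equals the inverse logit of the linear predictor
  fml <- ~ age + trial_type + rotation
  X <- model.matrix(fml, transform(nd,
    trial_type = factor(trial_type, f$xlev$trial_type),
    rotation = factor(rotation, f$xlev$rotation)))
  expect_equal(predictExpected(f, nd, marginal = FALSE),
               as.vector(plogis(X %*% f$coefficients)), tolerance = 1e-12)
  # attenuation: marginal prediction shrinks towards 1/2
  fHi <- f
  fHi$coefficients[] <- c(1, 0, 0, 0)
  fHi$par[1:4] <- c(1, 0, 0, 0)
  fHi$random_sd[] <- 1
  fHi$par[5] <- log(1)
  pm <- predictExpected(fHi, nd[1, ])
  expect_lt(pm, plogis(1))
  # independent oracle: adaptive quadrature of plogis(1 + z) phi(z)
  oracle <- integrate(function(z) plogis(1 + z) * dnorm(z), -Inf, Inf)$value
  expect_equal(pm, oracle, tolerance = 1e-6)
  # symmetric case: zero linear predictor -> exactly 1/2
  fHi$coefficients[] <- 0; fHi$par[1:4] <- 0
  expect_equal(predictExpected(fHi, nd[1, ]), 0.5, tolerance = 1e-10)
  # unknown covariate levels are refused, not silently NA
  ndBad <- nd[1, ]; ndBad$rotation <- "upside_down"
  expect_error(predictExpected(f, ndBad), "unknown level")
})

test_that("the case effect is recovered within its confidence bound", {
  # strong design: many participants, no latent heterogeneity
  cfg <- generativeConfig(nControls = 100, nCP = 100)
  cfg$faces <- experimentEffects(cp = -1.0, cpTrialType = 0,
                                 cpRotation = 0, sdIntercept = 0)
  parts <- generateParticipants(cfg, seed = 14)
  agg <- cpmem:::simulateAggregatedLongTerm(parts, cfg$faces, studyDesign(),
                                            seed = 15)
  spec <- aggSpec(c("age", "trial_type", "rotation", "group"))
  f <- fitGlmm(spec, agg)
  est <- f$coefficients[["groupCP"]]
  se <- sqrt(f$vcov[5, 5])
  expect_lt(abs(est - (-1.0)), 1.96 * se + 1e-8)
})

test_that("posterior summaries satisfy Bernstein-von Mises and are seeded", {
  co <- tinyAggCohort(nCtl = 25, nCP = 13, seed = 8,
                      effects = experimentEffects(cp = -1.0,
                                                  sdIntercept = 0.4))
  spec <- aggSpec(c("age", "trial_type", "rotation", "group"))
  f <- fitGlmm(spec, co$agg)
  ps <- posteriorSummary(spec, co$agg, coefficients = "groupCP",
                         nSamples = 3000, burnin = 1200, seed = 99)
  # flat-prior limit: posterior mode near the Laplace MLE
  expect_lt(abs(ps$posterior_mode - f$coefficients[["groupCP"]]), 0.05)
  # HPDI brackets the mode
  expect_lte(ps$hpdi_low, ps$posterior_mode)
  expect_gte(ps$posterior_mode, ps$hpdi_low)
  expect_lte(ps$posterior_mode, ps$hpdi_high)
  expect_true(attr(ps, "converged"))
  # identical seed -> identical summaries
  ps2 <- posteriorSummary(spec, co$agg, coefficients = "groupCP",
                          nSamples = 3000, burnin = 1200, seed = 99)
  expect_identical(ps$posterior_mode, ps2$posterior_mode)
  expect_identical(ps$hpdi_low, ps2$hpdi_low)
})
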