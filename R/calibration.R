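# ---------------------------------------------------------------------------
# Calibration and recovery studies run on simulated cohorts
# ---------------------------------------------------------------------------

#' Join participant covariates onto a trial table
#'
#' Prepares a trial table for model fitting: merges `group`, `age` (and
#' any further requested covariates) from the participant table and turns
#' group into a factor with controls as the reference level.
#'
#' @param trials trial table.
#' @param participants participant table.
#' @param experiment optional experiment filter.
#' @param covariates participant columns to merge.
#' @return The merged data.frame.
#' @export
prepareModelData <- function(trials, participants, experiment = NULL,
                             covariates = c("group", "age")) {
  if (!is.null(experiment))
    trials <- trials[trials$experiment %in% experiment, , drop = FALSE]
  idx <- match(trials$participant_id, participants$id)
  if (anyNA(idx)) stop("trials reference unknown participants")
  for (cv in covariates) trials[[cv]] <- participants[[cv]][idx]
  if ("group" %in% covariates)
    trials$group <- factor(trials$group, levels = c("control", "CP"))
  trials
}

#' Aggregate Bernoulli trials to binomial counts
#'
#' Collapses a trial-level table to one row per participant and distinct
#' covariate combination, holding the number of correct responses and the
#' number of trials.  The binomial likelihood is unchanged (up to a
#' data-only constant), and model refits become much cheaper.
#'
#' @param spec a Bernoulli-response [modelSpec()].
#' @param data trial table.
#' @return A list: `data` (aggregated data.frame) and `spec` (the matching
#'   aggregated spec with `response = "n_correct"`, `trials = "n_trials"`).
#' @export
aggregateTrials <- function(spec, data) {
  stopifnot(inherits(spec, "cpModelSpec"), is.null(spec$trials))
  vars <- unique(c(spec$group,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   setdiff(spec$random, "intercept")))
  key <- do.call(paste, c(data[vars], list(sep = "\r")))
  idx <- !duplicated(key)
  grpk <- match(key, key[idx])
  out <- data[idx, vars, drop = FALSE]
  out$n_correct <- as.vector(rowsum(as.numeric(data[[spec$response]]), grpk))
  out$n_trials <- as.vector(rowsum(rep(1, nrow(data)), grpk))
  rownames(out) <- NULL
  spec2 <- modelSpec("n_correct", fixed = spec$fixed, random = spec$random,
                     group = spec$group, trials = "n_trials")
  list(data = out, spec = spec2)
}

# default control-model spec for the long-term recognition experiments
longTermNullSpec <- function() {
  modelSpec("correct", fixed = c("age", "trial_type", "rotation"),
            random = "intercept", group = "participant_id")
}

# simulate an aggregated long-term cohort directly at the binomial-cell
# level: each participant contributes one binomial row per trial-type x
# rotation cell with the design's trial counts.  By sufficiency this is
# distributionally identical to drawing every trial and aggregating, and
# it is what the large calibration loops use.
simulateAggregatedLongTerm <- function(participants, effects, design,
                                       seed) {
  set.seed(seed)
  nT <- design$nTargets * design$repetitionsPerPart
  nD <- design$nDistractors * design$repetitionsPerPart
  rotLv <- as.numeric(design$parts == "rotated")
  cells <- expand.grid(trial_type = c("distractor", "target"),
                       part = seq_along(design$parts),
                       stringsAsFactors = FALSE)
  cells$rotation <- ifelse(rotLv[cells$part] == 1, "rotated", "frontal")
  cells$n_trials <- ifelse(cells$trial_type == "target", nT, nD)
  n <- nrow(participants)
  idx <- rep(seq_len(n), each = nrow(cells))
  d <- cells[rep(seq_len(nrow(cells)), times = n), , drop = FALSE]
  d$participant_id <- participants$id[idx]
  d$age <- participants$age[idx]
  d$group <- factor(participants$group[idx], levels = c("control", "CP"))
  isCP <- as.numeric(d$group == "CP")
  tt <- as.numeric(d$trial_type == "target")
  rot <- as.numeric(d$rotation == "rotated")
  eta <- effects$intercept +
    effects$age * (d$age - effects$ageCenter) +
    effects$trialType * tt + effects$rotation * rot +
    effects$cp * isCP + effects$cpTrialType * isCP * tt +
    effects$cpRotation * isCP * rot +
    effects$sdIntercept * participants$latent_intercept[idx] +
    effects$sdTrialSlope * participants$latent_slope[idx] * tt
  d$n_correct <- rbinom(nrow(d), d$n_trials, plogis(eta))
  rownames(d) <- NULL
  d
}

longTermAggSpec <- function(fixed = c("age", "trial_type", "rotation")) {
  modelSpec("n_correct", fixed = fixed, random = "intercept",
            group = "participant_id", trials = "n_trials")
}

#' False-positive rate of the single-case deficit classification
#'
#' Runs the complete abnormality pipeline on held-out control-like
#' participants simulated under the null generative model: each replicate
#' draws `nControls + 1` controls, fits the control model (age, trial
#' type, rotation fixed effects; participant random intercept) on the
#' first `nControls`, computes leave-one-out control residuals, scores
#' the held-out participant's residual as a z-score on the control scale,
#' and applies the one-sided modified t-test at the default 5% cutoff.
#' The returned rate estimates the classifier's type-I error under the
#' generator's default conditions.
#'
#' @param nReplicates number of simulated cohorts.
#' @param nControls control-sample size behind each classification.
#' @param config a [generativeConfig()]; group effects never enter since
#'   all simulated participants are controls.
#' @param design a [studyDesign()].
#' @param seed master seed; replicate r uses `childSeed(seed, r)`.
#' @param alpha one-sided cutoff of the deficit test.
#' @return A list: `rate`, `flags` (logical per replicate), `nReplicates`,
#'   `nControls`, `alpha`.
#' @export
deficitFalsePositiveRate <- function(nReplicates = 2000, nControls = 25,
                                     config = generativeConfig(),
                                     design = studyDesign(),
                                     seed = 1, alpha = 0.05) {
  stopifnot(nReplicates >= 1, nControls >= 3)
  nullCfg <- config
  nullCfg$nControls <- nControls + 1
  nullCfg$nCP <- 0
  spec0 <- longTermAggSpec()
  flags <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    sr <- childSeed(seed, r)
    parts <- generateParticipants(nullCfg, childSeed(sr, "participants"))
    agg <- simulateAggregatedLongTerm(parts, config$faces, design,
                                      childSeed(sr, "responses"))
    heldId <- parts$id[nControls + 1]
    isHeld <- agg$participant_id == heldId
    ctlAgg <- agg[!isHeld, , drop = FALSE]
    loo <- looControlResiduals(spec0, ctlAgg)
    fullFit <- attr(loo, "full_fit")
    case <- caseResiduals(fullFit, agg[isHeld, , drop = FALSE])
    z <- standardizeScores(loo$residual, case$residual)
    flags[r] <- deficitTest(as.numeric(z), nControls, alpha)$is_deficit
  }
  list(rate = mean(flags), flags = flags, nReplicates = nReplicates,
       nControls = nControls, alpha = alpha)
}

#' Type-I error of the likelihood-ratio test for a group main effect
#'
#' Simulates cohorts with case labels but all group effects zero, fits the
#' control nullmodel and the main-effect model, and records the LR-test
#' statistic and p-value per replicate.
#'
#' @param nReplicates number of simulated cohorts.
#' @param config a [generativeConfig()] whose faces group effects are
#'   zeroed internally.
#' @param design a [studyDesign()].
#' @param seed master seed.
#' @return A list: `rate` (fraction of p < alpha), `p` and `D` vectors,
#'   `alpha`.
#' @export
lrTypeIError <- function(nReplicates = 500, config = generativeConfig(),
                         design = studyDesign(), seed = 1, alpha = 0.05) {
  cfg <- config
  cfg$faces$cp <- 0; cfg$faces$cpTrialType <- 0; cfg$faces$cpRotation <- 0
  spec0 <- longTermAggSpec()
  spec1 <- longTermAggSpec(c("age", "trial_type", "rotation", "group"))
  D <- p <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    sr <- childSeed(seed, r)
    parts <- generateParticipants(cfg, childSeed(sr, "participants"))
    agg <- simulateAggregatedLongTerm(parts, cfg$faces, design,
                                      childSeed(sr, "responses"))
    f0 <- fitGlmm(spec0, agg, control = list(vcov = FALSE))
    f1 <- fitGlmm(spec1, agg, start = c(f0$par[1:4], 0, f0$par[5]),
                  control = list(vcov = FALSE))
    lt <- lrTest(f0, f1)
    D[r] <- lt$D; p[r] <- lt$p
  }
  list(rate = mean(p < alpha), p = p, D = D, alpha = alpha)
}

#' Recovery of the case main effect over simulated cohorts
#'
#' Simulates cohorts at the study's design size under the configured case
#' effects, fits the full model (main effect plus case-by-trial-type and
#' case-by-rotation interactions) and records the estimated case main
#' effect per replicate, to quantify estimation bias on the logit scale.
#'
#' @param nReplicates number of simulated cohorts.
#' @param config a [generativeConfig()].
#' @param design a [studyDesign()].
#' @param seed master seed.
#' @return A list: `estimates` (vector), `truth`, `bias`, `se` (Monte
#'   Carlo standard error of the bias).
#' @export
cpEffectRecovery <- function(nReplicates = 100, config = generativeConfig(),
                             design = studyDesign(), seed = 1) {
  spec <- longTermAggSpec(c("age", "trial_type", "rotation", "group",
                            "group:trial_type", "group:rotation"))
  est <- numeric(nReplicates)
  start <- NULL
  for (r in seq_len(nReplicates)) {
    sr <- childSeed(seed, r)
    parts <- generateParticipants(config, childSeed(sr, "participants"))
    agg <- simulateAggregatedLongTerm(parts, config$faces, design,
                                      childSeed(sr, "responses"))
    fit <- fitGlmm(spec, agg, start = start,
                   control = list(vcov = FALSE))
    start <- fit$par
    est[r] <- fit$coefficients[["groupCP"]]
  }
  bias <- mean(est) - config$faces$cp
  list(estimates = est, truth = config$faces$cp, bias = bias,
       se = sd(est) / sqrt(nReplicates))
}

#' Simulate aggregate deficit profiles from planted subtype archetypes
#'
#' Builds case aggregate z-profiles (over the six summary columns) from
#' three planted phenotypic archetypes — a cascading
#' perceptual+associative+mnestic face deficit, a mnestic-only deficit,
#' and a combined face-and-object deficit — plus within-archetype
#' Gaussian noise, together with unimpaired control profiles.  Used to
#' check that complete-linkage clustering of aggregate profiles recovers
#' the planted partition.
#'
#' @param nCP number of cases (split across archetypes round-robin).
#' @param nControls number of control profiles (standard normal noise
#'   around zero).
#' @param noiseSd within-archetype noise sd per cell.
#' @param seed integer seed.
#' @return A list: `ztab` (a [zScoreTable()] of the six aggregate
#'   columns), `archetype` (named integer vector for the cases).
#' @export
simulateArchetypeProfiles <- function(nCP = 13, nControls = 25,
                                      noiseSd = 0.5, seed = 1) {
  set.seed(seed)
  cols <- c("perceptual", "associative", "mnestic",
            "faces_total", "shoes_total", "overall")
  arch <- rbind(
    c(-3.0, -2.5, -2.0, -3.0,  0.0, -2.5),   # apperceptive cascade
    c( 0.0,  0.0, -3.0, -1.5,  0.0, -1.0),   # mnestic only
    c(-2.5, -1.5, -1.0, -2.0, -2.5, -2.5))   # face + object
  colnames(arch) <- cols
  lab <- rep_len(1:3, nCP)
  cp <- arch[lab, , drop = FALSE] +
    matrix(rnorm(nCP * length(cols), 0, noiseSd), nCP)
  ctl <- matrix(rnorm(nControls * length(cols)), nControls)
  m <- rbind(ctl, cp)
  colnames(m) <- cols
  ids <- c(sprintf("C%02d", seq_len(nControls)),
           sprintf("P%02d", seq_len(nCP)))
  group <- rep(c("control", "CP"), c(nControls, nCP))
  zt <- zScoreTable(m, group, ids)
  attr(zt, "aggregates") <- cols
  list(ztab = zt, archetype = setNames(lab, ids[group == "CP"]))
}
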