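# ---------------------------------------------------------------------------
# Synthetic cohorts: participants, trial schedules, binomial responses
# ---------------------------------------------------------------------------

#' Fixed- and random-effect settings for one simulated experiment
#'
#' All effects are on the logit scale of the probability of a correct
#' response.  Age enters centred at `ageCenter` years, so `intercept` is
#' the accuracy logit of an average-aged control on a frontal distractor
#' trial.  Group (case) effects default to zero; the packaged defaults for
#' the long-term face experiment carry a substantial case deficit with a
#' miss-biased case response style (a negative case-by-trial-type
#' interaction makes cases fail on targets more than on distractors).
#'
#' @param intercept baseline accuracy logit.
#' @param age effect per year of age.
#' @param trialType effect of a target (vs distractor) trial.
#' @param rotation effect of a rotated (vs frontal) presentation.
#' @param cp main effect of being a case (CP).
#' @param cpTrialType,cpRotation case-by-trial-type and case-by-rotation
#'   interactions.
#' @param sdIntercept sd of the per-participant random intercept.
#' @param sdTrialSlope sd of an optional per-participant random slope on
#'   trial type (0 disables it).
#' @param ageCenter centring constant for age, years.
#' @return A list of class `cpEffects`.
#' @export
experimentEffects <- function(intercept = 3.0, age = -0.015,
                              trialType = -0.5, rotation = -0.6,
                              cp = 0, cpTrialType = 0, cpRotation = 0,
                              sdIntercept = 0.5, sdTrialSlope = 0,
                              ageCenter = 37.3) {
  stopifnot(sdIntercept >= 0, sdTrialSlope >= 0)
  structure(list(intercept = intercept, age = age, trialType = trialType,
                 rotation = rotation, cp = cp, cpTrialType = cpTrialType,
                 cpRotation = cpRotation, sdIntercept = sdIntercept,
                 sdTrialSlope = sdTrialSlope, ageCenter = ageCenter),
            class = "cpEffects")
}

#' Generative configuration for a simulated case-control cohort
#'
#' Bundles cohort composition, covariate distributions and per-experiment
#' effect settings.  The defaults emulate the study design the package is
#' built around: 25 controls and 13 cases in the one-year recognition test,
#' ages from a truncated normal with mean 37.3 and sd 17.9 years on
#' [18, 80], uniform gender and media-consumption bands, and case effects
#' set to the published posterior estimates (faces: case effect -1.04 with
#' a -1.63 case-by-trial-type interaction and a 0.31 case-by-rotation
#' interaction; shoes: -0.40 with a random trial-type slope; famous-face
#' recall: -0.67 with media-consumption interactions -0.12 and -0.30).
#'
#' @param nControls,nCP cohort sizes (controls / cases), each >= 0 and
#'   together >= 1.
#' @param ageMean,ageSd,ageRange truncated-normal age distribution (years).
#' @param genderP probability of "female".
#' @param tvBandP,printBandP probabilities of media-consumption bands 1-4
#'   (<1 h, 1-2 h, 3-7 h, >7 h per week).
#' @param faces,shoes,bfft [experimentEffects()] for the three experiments;
#'   `bfft` additionally understands fields `gender`, `tv`, `print`,
#'   `cpTv`, `cpPrint` (see [simulateBfft()]).
#' @param questionnaireRho correlation (via a Gaussian copula) between a
#'   case's questionnaire total and their latent face-recognition ability;
#'   negative ability shifts produce higher self-reported difficulty.
#' @param seed default master seed used by [simulateCohort()].
#' @return A list of class `cpGenConfig`.
#' @export
generativeConfig <- function(nControls = 25, nCP = 13,
                             ageMean = 37.3, ageSd = 17.9,
                             ageRange = c(18, 80),
                             genderP = 0.5,
                             tvBandP = rep(0.25, 4),
                             printBandP = rep(0.25, 4),
                             faces = experimentEffects(cp = -1.04,
                                                       cpTrialType = -1.63,
                                                       cpRotation = 0.31),
                             shoes = experimentEffects(intercept = 1.6,
                                                       trialType = -0.7,
                                                       rotation = -0.4,
                                                       cp = -0.40,
                                                       sdTrialSlope = 0.4),
                             bfft = bfftEffects(),
                             questionnaireRho = 0.6,
                             seed = 1L) {
  if (nControls < 0 || nCP < 0 || nControls + nCP < 1)
    stop("cohort sizes must be nonnegative and total at least 1")
  stopifnot(ageSd > 0, length(ageRange) == 2, ageRange[1] > 0,
            abs(sum(tvBandP) - 1) < 1e-8, abs(sum(printBandP) - 1) < 1e-8,
            questionnaireRho >= -1, questionnaireRho <= 1)
  structure(list(nControls = nControls, nCP = nCP, ageMean = ageMean,
                 ageSd = ageSd, ageRange = ageRange, genderP = genderP,
                 tvBandP = tvBandP, printBandP = printBandP,
                 faces = faces, shoes = shoes, bfft = bfft,
                 questionnaireRho = questionnaireRho,
                 seed = as.integer(seed)),
            class = "cpGenConfig")
}

#' Effect settings for the famous-face free-recall simulation
#'
#' Logit-linear effects on per-item recall probability.  Media-consumption
#' bands enter as ordinal numerics 1-4 centred at 2.5.
#'
#' @param intercept recall logit of an average control.
#' @param age effect per year of age (centred at `ageCenter`).
#' @param gender additive effect of being male.
#' @param tv,print effects per media band among controls.
#' @param cp case main effect.
#' @param cpTv,cpPrint case-by-media interactions (a negative value erodes
#'   the media benefit for cases).
#' @param sdIntercept per-participant random-intercept sd.
#' @param ageCenter centring constant for age, years.
#' @return A list of class `cpBfftEffects`.
#' @export
bfftEffects <- function(intercept = 0.8, age = -0.02, gender = 0.1,
                        tv = 0.25, print = 0.30, cp = -0.67,
                        cpTv = -0.12, cpPrint = -0.30,
                        sdIntercept = 0.4, ageCenter = 37.3) {
  stopifnot(sdIntercept >= 0)
  structure(list(intercept = intercept, age = age, gender = gender,
                 tv = tv, print = print, cp = cp, cpTv = cpTv,
                 cpPrint = cpPrint, sdIntercept = sdIntercept,
                 ageCenter = ageCenter),
            class = "cpBfftEffects")
}

#' Generate a simulated participant table
#'
#' Draws controls and cases with ages from the configured truncated normal,
#' categorical gender and media bands, latent standard-normal ability
#' factors (scaled by each experiment's random-effect sds at response
#' simulation time), and a 15-item screening questionnaire whose total
#' correlates negatively with latent ability among cases through a Gaussian
#' copula.
#'
#' @param config a [generativeConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A data.frame with one row per participant: `id`, `group`
#'   (`"control"`/`"CP"`), `age`, `gender`, `tv_band`, `print_band`, 15
#'   rating columns `q1..q15`, `questionnaire_total`, and latent columns
#'   `latent_intercept`, `latent_slope` (standard normal).
#' @export
generateParticipants <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cpGenConfig"))
  set.seed(seed)
  n <- config$nControls + config$nCP
  group <- rep(c("control", "CP"), c(config$nControls, config$nCP))
  id <- sprintf("%s%02d", ifelse(group == "CP", "P", "C"),
                utils::head(c(seq_len(config$nControls),
                              seq_len(config$nCP)), n))
  id <- make.unique(id, sep = "_")
  age <- rtruncnorm(n, config$ageMean, config$ageSd,
                    config$ageRange[1], config$ageRange[2])
  gender <- ifelse(runif(n) < config$genderP, "female", "male")
  tv <- sample.int(4, n, replace = TRUE, prob = config$tvBandP)
  pr <- sample.int(4, n, replace = TRUE, prob = config$printBandP)
  latInt <- rnorm(n)
  latSlp <- rnorm(n)
  # questionnaire: Gaussian copula links case totals to latent ability;
  # the faces case main effect shifts case means upward (more difficulty)
  rho <- config$questionnaireRho
  zq <- -rho * latInt + sqrt(1 - rho^2) * rnorm(n)
  base <- ifelse(group == "CP", 3.4, 1.6)   # mean item rating by group
  ratings <- matrix(0L, n, 15)
  for (k in 1:15) {
    raw <- base + 0.55 * zq + rnorm(n, 0, 0.7)
    ratings[, k] <- pmin(pmax(as.integer(round(raw)), 1L), 5L)
  }
  colnames(ratings) <- paste0("q", 1:15)
  out <- data.frame(id = id, group = group, age = age, gender = gender,
                    tv_band = tv, print_band = pr,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ratings))
  out$questionnaire_total <- apply(ratings, 1, scoreQuestionnaire)
  out$latent_intercept <- latInt
  out$latent_slope <- latSlp
  out
}

#' Score the 15-item screening questionnaire
#'
#' Sums 15 scored items rated 1-5 (dummy items must be excluded before
#' calling); totals range from 15 to 75, larger totals indicating more
#' self-reported difficulty.
#'
#' @param ratings integer vector of exactly 15 ratings in 1..5.
#' @return Integer total in `[15, 75]`.
#' @export
#' @examples
#' scoreQuestionnaire(rep(1, 15))  # 15
#' scoreQuestionnaire(rep(5, 15))  # 75
scoreQuestionnaire <- function(ratings) {
  if (length(ratings) != 15)
    stop("exactly 15 scored ratings are required")
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 5) ||
      any(ratings != round(ratings)))
    stop("ratings must be integers in 1..5")
  as.integer(sum(ratings))
}

#' Default long-term recognition study design
#'
#' Two parts of `repetitionsPerPart * (nTargets + nDistractors)`
#' presentations each; part 1 shows rotated stimuli, part 2 frontal ones.
#' Target presentations carry one of four illumination labels, of which
#' exactly one (`"L1"`) matches the familiarisation illumination.
#'
#' @param nTargets,nDistractors stimulus counts.
#' @param repetitionsPerPart presentations of every stimulus per part.
#' @param parts ordered part condition labels.
#' @param illuminationLevels labels for target-trial illumination.
#' @return A list of class `cpStudyDesign`.
#' @export
studyDesign <- function(nTargets = 4, nDistractors = 16,
                        repetitionsPerPart = 8,
                        parts = c("rotated", "frontal"),
                        illuminationLevels = paste0("L", 1:4)) {
  stopifnot(nTargets >= 1, nDistractors >= 1, repetitionsPerPart >= 1)
  if (length(parts) < 1) stop("parts must not be empty")
  structure(list(nTargets = nTargets, nDistractors = nDistractors,
                 repetitionsPerPart = repetitionsPerPart, parts = parts,
                 illuminationLevels = illuminationLevels),
            class = "cpStudyDesign")
}

#' Generate a randomized, balanced trial schedule
#'
#' For each part, every stimulus appears exactly `repetitionsPerPart`
#' times in an unconstrained random permutation.  Rotation follows the
#' part condition; illumination labels are assigned uniformly to target
#' presentations.
#'
#' @param design a [studyDesign()].
#' @param seed integer seed.
#' @return A data.frame skeleton (no responses) with columns `part`,
#'   `trial_index`, `stimulus_id`, `trial_type`, `rotation`,
#'   `illumination`.
#' @export
generateTrialSchedule <- function(design = studyDesign(), seed = 1) {
  stopifnot(inherits(design, "cpStudyDesign"))
  set.seed(seed)
  stim <- c(sprintf("T%d", seq_len(design$nTargets)),
            sprintf("D%02d", seq_len(design$nDistractors)))
  type <- rep(c("target", "distractor"),
              c(design$nTargets, design$nDistractors))
  perPart <- design$repetitionsPerPart * length(stim)
  parts <- lapply(seq_along(design$parts), function(pi) {
    ord <- sample.int(perPart)
    sid <- rep(stim, design$repetitionsPerPart)[ord]
    tty <- rep(type, design$repetitionsPerPart)[ord]
    ill <- rep(NA_character_, perPart)
    tgt <- tty == "target"
    ill[tgt] <- sample(design$illuminationLevels, sum(tgt), replace = TRUE)
    data.frame(part = pi, trial_index = seq_len(perPart),
               stimulus_id = sid, trial_type = tty,
               rotation = design$parts[pi], illumination = ill,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Simulate binomial trial responses under the logistic mixed model
#'
#' Each trial's correct-response probability is the inverse logit of the
#' linear predictor built from the participant's covariates, the trial's
#' condition labels, and the participant's latent effects scaled by the
#' configured random-effect sds; responses are independent Bernoulli draws
#' given the latent effects.
#'
#' @param participants table from [generateParticipants()].
#' @param schedule table from [generateTrialSchedule()].
#' @param effects an [experimentEffects()].
#' @param experiment experiment label stored in the output.
#' @param seed integer seed.
#' @return A trial table: `participant_id`, `experiment`, `part`,
#'   `trial_index`, `stimulus_id`, `trial_type`, `rotation`,
#'   `illumination`, `response`, `correct`.
#' @export
simulateResponses <- function(participants, schedule, effects,
                              experiment = "faces_longterm", seed = 1) {
  stopifnot(inherits(effects, "cpEffects"))
  need <- c("id", "group", "age", "latent_intercept", "latent_slope")
  miss <- setdiff(need, names(participants))
  if (length(miss) > 0)
    stop("participants lack columns: ", paste(miss, collapse = ", "))
  set.seed(seed)
  n <- nrow(participants)
  nt <- nrow(schedule)
  idx <- rep(seq_len(n), each = nt)
  tr <- schedule[rep(seq_len(nt), times = n), , drop = FALSE]
  isCP <- as.numeric(participants$group[idx] == "CP")
  tt <- as.numeric(tr$trial_type == "target")
  rot <- as.numeric(tr$rotation == "rotated")
  b0 <- effects$sdIntercept * participants$latent_intercept[idx]
  b1 <- effects$sdTrialSlope * participants$latent_slope[idx]
  eta <- effects$intercept +
    effects$age * (participants$age[idx] - effects$ageCenter) +
    effects$trialType * tt + effects$rotation * rot +
    effects$cp * isCP + effects$cpTrialType * isCP * tt +
    effects$cpRotation * isCP * rot + b0 + b1 * tt
  correct <- as.integer(runif(n * nt) < plogis(eta))
  response <- ifelse(tt == 1,
                     ifelse(correct == 1, "target", "nontarget"),
                     ifelse(correct == 1, "nontarget", "target"))
  data.frame(participant_id = participants$id[idx],
             experiment = experiment,
             part = tr$part, trial_index = tr$trial_index,
             stimulus_id = tr$stimulus_id, trial_type = tr$trial_type,
             rotation = tr$rotation, illumination = tr$illumination,
             response = response, correct = correct,
             stringsAsFactors = FALSE)
}

#' Simulate famous-face free-recall outcomes
#'
#' Per-participant Bernoulli recall per item with logit-linear effects of
#' age, gender, media-consumption bands, case status and case-by-media
#' interactions.
#'
#' @param participants table from [generateParticipants()].
#' @param nItems number of portrait items.
#' @param effects a [bfftEffects()].
#' @param seed integer seed.
#' @return A data.frame: `participant_id`, `item_id`, `recalled`.
#' @export
simulateBfft <- function(participants, nItems = 40,
                         effects = bfftEffects(), seed = 1) {
  stopifnot(inherits(effects, "cpBfftEffects"), nItems >= 1)
  if (any(!participants$tv_band %in% 1:4) ||
      any(!participants$print_band %in% 1:4))
    stop("media bands must lie in 1..4")
  set.seed(seed)
  n <- nrow(participants)
  isCP <- as.numeric(participants$group == "CP")
  male <- as.numeric(participants$gender == "male")
  tvc <- participants$tv_band - 2.5
  prc <- participants$print_band - 2.5
  eta <- effects$intercept +
    effects$age * (participants$age - effects$ageCenter) +
    effects$gender * male + effects$tv * tvc + effects$print * prc +
    effects$cp * isCP + effects$cpTv * isCP * tvc +
    effects$cpPrint * isCP * prc +
    effects$sdIntercept * participants$latent_intercept
  pr <- plogis(rep(eta, each = nItems))
  data.frame(participant_id = rep(participants$id, each = nItems),
             item_id = rep(sprintf("F%02d", seq_len(nItems)),
                           times = n),
             recalled = as.integer(runif(n * nItems) < pr),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper generating participants, schedules and responses
#' for the long-term face and shoe experiments plus the famous-face test,
#' each from deterministic substreams of one master seed.
#'
#' @param config a [generativeConfig()].
#' @param design a [studyDesign()] shared by the face and shoe experiments.
#' @param nBfftItems number of famous-face items.
#' @param seed master seed (defaults to `config$seed`).
#' @return A list with elements `participants`, `trials` (faces and shoes
#'   stacked), and `bfft`.
#' @export
simulateCohort <- function(config = generativeConfig(),
                           design = studyDesign(), nBfftItems = 40,
                           seed = config$seed) {
  participants <- generateParticipants(config, childSeed(seed, "participants"))
  schedF <- generateTrialSchedule(design, childSeed(seed, "schedule_faces"))
  schedS <- generateTrialSchedule(design, childSeed(seed, "schedule_shoes"))
  trialsF <- simulateResponses(participants, schedF, config$faces,
                               "faces_longterm",
                               childSeed(seed, "responses_faces"))
  trialsS <- simulateResponses(participants, schedS, config$shoes,
                               "shoes_longterm",
                               childSeed(seed, "responses_shoes"))
  bfft <- simulateBfft(participants, nBfftItems, config$bfft,
                       childSeed(seed, "bfft"))
  list(participants = participants,
       trials = rbind(trialsF, trialsS),
       bfft = bfft)
}
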