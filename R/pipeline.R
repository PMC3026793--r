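# ---------------------------------------------------------------------------
# End-to-end pipeline: simulate -> sdt -> fit -> scores -> cluster -> report
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles every choice the pipeline needs so that a run is fully
#' reproducible from the configuration and one master seed.
#'
#' @param generative a [generativeConfig()].
#' @param design a [studyDesign()].
#' @param nBfftItems famous-face item count.
#' @param categoryMap category/aggregate map, see [categoryMapDefault()].
#' @param dprimeCorrection extreme-rate rule for [dprime()].
#' @param distancePolicy missing-data policy for [pairwiseDistance()].
#' @param alpha one-sided deficit cutoff.
#' @param bayes logical; also compute posterior summaries for the
#'   face-model interaction effects (slower).
#' @param externalShift named numeric: mean z shift of cases in the
#'   simulated external short-term columns.
#' @param seed master seed.
#' @return A list of class `cpPipelineConfig`.
#' @export
pipelineConfig <- function(generative = generativeConfig(),
                           design = studyDesign(),
                           nBfftItems = 40,
                           categoryMap = categoryMapDefault(),
                           dprimeCorrection = "halfN",
                           distancePolicy = "pairwise",
                           alpha = 0.05,
                           bayes = FALSE,
                           externalShift = c(rt_faces = -1.2,
                                             rt_shoes = -0.3,
                                             pt80_faces = -1.2,
                                             pt80_shoes = -0.3,
                                             rotation_faces = -1.3,
                                             rotation_shoes = -0.3,
                                             learn_faces = -1.0,
                                             test_faces = -1.0),
                           seed = 1L) {
  structure(list(generative = generative, design = design,
                 nBfftItems = nBfftItems, categoryMap = categoryMap,
                 dprimeCorrection = dprimeCorrection,
                 distancePolicy = distancePolicy, alpha = alpha,
                 bayes = bayes, externalShift = externalShift,
                 seed = as.integer(seed)),
            class = "cpPipelineConfig")
}

#' Simulate external short-term test z-scores
#'
#' Emulates the ingested short-term battery: eight already-standardized
#' score columns coupled to each participant's latent ability, with
#' case-specific mean shifts.  Speed measures (`rt_*`, `pt80_*`) are
#' emitted on their native direction (larger = slower = worse) and must
#' be sign-flipped at ingestion.
#'
#' @param participants participant table.
#' @param externalShift named case shifts on the deficit-negative scale.
#' @param seed integer seed.
#' @return A numeric matrix, rows = participants.
#' @export
simulateExternalScores <- function(participants,
                                   externalShift = pipelineConfig()$externalShift,
                                   seed = 1) {
  set.seed(seed)
  n <- nrow(participants)
  isCP <- participants$group == "CP"
  out <- matrix(NA_real_, n, length(externalShift),
                dimnames = list(participants$id, names(externalShift)))
  for (j in seq_along(externalShift)) {
    v <- 0.6 * participants$latent_intercept + 0.8 * rnorm(n)
    v[isCP] <- v[isCP] + externalShift[j]
    if (grepl("^(rt|pt80)_", names(externalShift)[j])) v <- -v
    out[, j] <- v
  }
  out
}

# leave-one-out z column for one experiment (controls via individualized
# models, cases via the all-controls fit)
scoreColumn <- function(spec, data, participants) {
  ctlIds <- participants$id[participants$group == "control"]
  agg <- if (is.null(spec$trials)) aggregateTrials(spec, data) else
    list(spec = spec, data = data)
  ctlAgg <- agg$data[agg$data[[spec$group]] %in% ctlIds, , drop = FALSE]
  loo <- looControlResiduals(agg$spec, ctlAgg)
  fullFit <- attr(loo, "full_fit")
  caseAgg <- agg$data[!agg$data[[spec$group]] %in% ctlIds, , drop = FALSE]
  resid <- loo[, c("participant_id", "residual")]
  if (nrow(caseAgg) > 0) {
    cs <- caseResiduals(fullFit, caseAgg)
    resid <- rbind(resid, cs[, c("participant_id", "residual")])
  }
  ctl <- resid$participant_id %in% ctlIds
  z <- standardizeScores(resid$residual[ctl], resid$residual)
  setNames(as.numeric(z), resid$participant_id)[participants$id]
}

#' Run the complete analysis pipeline
#'
#' Simulates (or ingests) a cohort, computes signal-detection summaries,
#' group comparisons, mixed-model fits with likelihood-ratio tests,
#' leave-one-out abnormality z-scores with aggregate categories and
#' deficit calls, clusters deficit profiles, and writes every table to
#' `outDir` together with a manifest of file hashes.  Re-running an
#' identical configuration and seed reproduces identical files.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing); `NULL` skips
#'   writing and returns the objects only.
#' @param ingest optional list with pre-loaded `participants`, `trials`,
#'   `bfft` and `external` tables replacing the simulator (schemas as the
#'   simulated ones; latent columns not required).
#' @return Invisibly, a list with all stage outputs plus `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        ingest = NULL) {
  stopifnot(inherits(config, "cpPipelineConfig"))
  seed <- config$seed
  gen <- config$generative

  # -- stage: simulate / ingest ------------------------------------------
  if (is.null(ingest)) {
    cohort <- simulateCohort(gen, config$design, config$nBfftItems, seed)
    external <- simulateExternalScores(cohort$participants,
                                       config$externalShift,
                                       childSeed(seed, "external"))
  } else {
    cohort <- ingest[c("participants", "trials", "bfft")]
    external <- ingest$external
  }
  participants <- cohort$participants
  nCP <- sum(participants$group == "CP")
  if (nCP == 0)
    warning("no case participants: group comparisons are skipped")

  # -- stage: signal detection -------------------------------------------
  sdt <- sdtSummary(cohort$trials, config$dprimeCorrection)

  # -- stage: group comparisons ------------------------------------------
  groupTests <- list()
  if (nCP > 0) {
    g <- participants$group[match(sdt$participant_id, participants$id)]
    for (ex in unique(sdt$experiment)) {
      k <- sdt$experiment == ex
      er <- rankSumTest(sdt$error_rate[k & g == "control"],
                        sdt$error_rate[k & g == "CP"],
                        alternative = "less")      # controls err less
      dp <- rankSumTest(sdt$dprime[k & g == "control"],
                        sdt$dprime[k & g == "CP"],
                        alternative = "greater")   # controls more sensitive
      groupTests[[paste0(ex, "_error_rate")]] <-
        data.frame(test_name = paste0(ex, "_error_rate"),
                   comparison = "control_vs_CP", W = er$W, n0 = er$n_x,
                   nCP = er$n_y, p = er$p, alternative = er$alternative)
      groupTests[[paste0(ex, "_dprime")]] <-
        data.frame(test_name = paste0(ex, "_dprime"),
                   comparison = "control_vs_CP", W = dp$W, n0 = dp$n_x,
                   nCP = dp$n_y, p = dp$p, alternative = dp$alternative)
    }
  }

  # -- stage: model fits and LR tests ------------------------------------
  faces <- prepareModelData(cohort$trials, participants, "faces_longterm")
  spec0 <- modelSpec("correct", c("age", "trial_type", "rotation"),
                     random = "intercept", group = "participant_id")
  spec1 <- modelSpec("correct", c("age", "trial_type", "rotation", "group"),
                     random = "intercept", group = "participant_id")
  spec2 <- modelSpec("correct", c("age", "trial_type", "rotation", "group",
                                  "group:trial_type", "group:rotation"),
                     random = "intercept", group = "participant_id")
  fits <- list(); lrs <- list(); posterior <- NULL
  if (nCP > 0) {
    a0 <- aggregateTrials(spec0, faces)
    a1 <- aggregateTrials(spec1, faces)
    a2 <- aggregateTrials(spec2, faces)
    fits$faces_null <- fitGlmm(a0$spec, a0$data)
    fits$faces_main <- fitGlmm(a1$spec, a1$data)
    fits$faces_full <- fitGlmm(a2$spec, a2$data)
    lrs$faces_main_vs_null <- lrTest(fits$faces_null, fits$faces_main)
    lrs$faces_full_vs_main <- lrTest(fits$faces_main, fits$faces_full)
    if (isTRUE(config$bayes)) {
      posterior <- posteriorSummary(
        a2$spec, a2$data,
        coefficients = c("groupCP", "trial_typetarget:groupCP",
                         "rotationrotated:groupCP"),
        seed = childSeed(seed, "mcmc"))
    }
  }

  # -- stage: abnormality z-scores ---------------------------------------
  zcols <- list()
  zcols$faces_longterm <- scoreColumn(spec0, faces, participants)
  shoes <- prepareModelData(cohort$trials, participants, "shoes_longterm")
  shoesSpec <- modelSpec("correct", c("age", "trial_type", "rotation"),
                         random = c("intercept", "tt_num"),
                         group = "participant_id")
  shoes$tt_num <- as.numeric(shoes$trial_type == "target")
  zcols$shoes_longterm <- scoreColumn(shoesSpec, shoes, participants)
  bfft <- prepareModelData(cohort$bfft, participants, NULL,
                           c("group", "age", "gender", "tv_band",
                             "print_band"))
  bfftSpec <- modelSpec("recalled",
                        c("age", "gender", "tv_band", "print_band"),
                        random = NULL, group = "participant_id")
  zcols$bfft <- scoreColumn(bfftSpec, bfft, participants)
  zmat <- do.call(cbind, zcols)
  if (!is.null(external)) {
    ext <- ingestExternalScores(external, participants$group,
                                flipColumns = grep("^(rt|pt80)_",
                                                   colnames(external),
                                                   value = TRUE))
    zmat <- cbind(zmat, unclass(ext)[participants$id, , drop = FALSE])
  }
  ztab <- zScoreTable(zmat, participants$group, participants$id)
  ztab <- aggregateScores(ztab, config$categoryMap)
  deficits <- deficitCalls(ztab, config$alpha)

  # questionnaire self-assessment vs overall abnormality among cases
  if (nCP > 0 && "overall" %in% colnames(ztab)) {
    cp <- participants$group == "CP"
    qc <- rankCorrelation(participants$questionnaire_total[cp],
                          unclass(ztab)[cp, "overall"])
    groupTests$questionnaire_overall <-
      data.frame(test_name = "questionnaire_vs_overall_z",
                 comparison = "within_CP", W = NA, n0 = NA, nCP = qc$n,
                 p = qc$p, alternative = "two.sided")
    attr(groupTests, "questionnaire_rho") <- qc$rho
  }

  # -- stage: clustering and report --------------------------------------
  D <- pairwiseDistance(ztab, policy = config$distancePolicy)
  dendro <- completeLinkage(D)
  report <- profileReport(ztab, deficits, dendro)

  gt <- if (length(groupTests) > 0) do.call(rbind, groupTests) else NULL
  if (!is.null(gt))
    attr(gt, "questionnaire_rho") <- attr(groupTests, "questionnaire_rho")
  out <- list(participants = participants, trials = cohort$trials,
              bfft = cohort$bfft, sdt = sdt,
              group_tests = gt,
              fits = fits, lr_tests = lrs, posterior = posterior,
              ztable = ztab, deficits = deficits, distance = D,
              dendrogram = dendro, report = report, config = config)

  # -- stage: write outputs + manifest -----------------------------------
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(outDir, name)
      write.csv(df, path, row.names = FALSE)
      path
    }
    paths <- c(
      wr(participants[, setdiff(names(participants),
                                c("latent_intercept", "latent_slope"))],
         "participants.csv"),
      wr(cohort$trials, "trials.csv"),
      wr(cohort$bfft, "bfft.csv"),
      wr(sdt, "sdt.csv"))
    if (!is.null(out$group_tests))
      paths <- c(paths, wr(out$group_tests, "group_tests.csv"))
    zl <- data.frame(participant_id = rep(rownames(ztab), ncol(ztab)),
                     column = rep(colnames(ztab), each = nrow(ztab)),
                     z = as.vector(unclass(ztab)),
                     is_missing = is.na(as.vector(unclass(ztab))))
    paths <- c(paths, wr(zl, "zscores.csv"),
               wr(deficits, "deficits.csv"),
               wr(report, "profile.csv"))
    if (length(lrs) > 0) {
      lrdf <- do.call(rbind, lapply(names(lrs), function(nm)
        data.frame(comparison = nm, D = lrs[[nm]]$D, df = lrs[[nm]]$df,
                   p = lrs[[nm]]$p)))
      paths <- c(paths, wr(lrdf, "lr_tests.csv"))
    }
    if (length(fits) > 0) {
      fitsJson <- lapply(fits, function(f)
        list(coefficients = as.list(f$coefficients),
             random_sd = as.list(f$random_sd),
             logLik = f$logLik, converged = f$converged,
             n_obs = f$n_obs))
      jp <- file.path(outDir, "fits.json")
      jsonlite::write_json(fitsJson, jp, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, jp)
    }
    dj <- file.path(outDir, "dendrogram.json")
    jsonlite::write_json(list(merge = dendro$merge,
                              height = dendro$height,
                              order = dendro$order,
                              labels = dendro$labels),
                         dj, digits = NA)
    paths <- c(paths, dj)
    manifest <- list(package = "cpmem",
                     version = as.character(packageVersion("cpmem")),
                     seed = seed,
                     files = lapply(setNames(nm = basename(paths)),
                                    function(b)
                                      unname(tools::md5sum(
                                        file.path(outDir, b)))))
    mj <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mj, auto_unbox = TRUE)
    out$manifest <- manifest
  }
  invisible(out)
}
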