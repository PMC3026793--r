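# ---------------------------------------------------------------------------
# Single-case abnormality scores: control-model residuals, leave-one-out
# standardization, category aggregation, modified t-test deficit calls
# ---------------------------------------------------------------------------

# observed and expected proportion correct per participant under a fit;
# expectation is the trial-weighted mean of marginal model predictions
participantResiduals <- function(fit, data, marginal = TRUE) {
  spec <- fit$spec
  ids <- unique(data[[spec$group]])
  m <- if (is.null(spec$trials)) rep(1, nrow(data)) else data[[spec$trials]]
  s <- data[[spec$response]]
  pred <- predictExpected(fit, data, marginal = marginal)
  obs <- rowsum(s * 1, data[[spec$group]])
  tot <- rowsum(m, data[[spec$group]])
  exp_ <- rowsum(pred * m, data[[spec$group]])
  out <- data.frame(participant_id = rownames(obs),
                    observed = obs[, 1] / tot[, 1],
                    expected = exp_[, 1] / tot[, 1],
                    stringsAsFactors = FALSE)
  out$residual <- out$observed - out$expected
  rownames(out) <- NULL
  out[match(ids, out$participant_id), , drop = FALSE]
}

#' Case residuals under a control model
#'
#' For each case participant, the difference between observed performance
#' (proportion correct over their trials) and the performance expected of
#' a control with identical covariates under the control model, with the
#' expectation marginalised over the random effects.  Covariate values
#' outside the range seen by the control fit are flagged in the
#' `extrapolated` column, not refused.
#'
#' @param controlFit a `cpGlmm` fitted on control observations only.
#' @param caseData trial table for the participants to score (any number).
#' @param marginal marginalise predictions over random effects (default).
#' @return A data.frame: `participant_id`, `observed`, `expected`,
#'   `residual`, `extrapolated`.
#' @export
caseResiduals <- function(controlFit, caseData, marginal = TRUE) {
  stopifnot(inherits(controlFit, "cpGlmm"))
  out <- participantResiduals(controlFit, caseData, marginal)
  rng <- attr(controlFit, "age_range")
  out$extrapolated <- FALSE
  if (!is.null(rng) && "age" %in% names(caseData)) {
    ages <- tapply(caseData$age, caseData[[controlFit$spec$group]], mean)
    ages <- ages[out$participant_id]
    out$extrapolated <- ages < rng[1] | ages > rng[2]
  }
  out
}

#' Leave-one-out control residuals
#'
#' For each control participant i, the fixed effects (and random-effect
#' sds) of the control model are re-estimated on all controls except i,
#' and i's residual is computed under that individualized model.  This
#' removes the optimism of in-sample residuals: with a plug-in full-data
#' fit, every control's idiosyncrasies leak into its own expectation and
#' the control residual variance underestimates the variance of a new
#' case's residual.  One model is refitted per control; random-intercept
#' refits reuse the full fit's Hessian as a fixed quasi-Newton metric,
#' falling back to the full optimizer when needed.
#'
#' @param spec a [modelSpec()].
#' @param controlData trial table containing controls only.
#' @param marginal marginalise predictions over random effects (default).
#' @return A data.frame as in [caseResiduals()] (one row per control) with
#'   attributes `full_fit` (the all-controls fit) and `fold_converged`
#'   (logical per fold).
#' @export
looControlResiduals <- function(spec, controlData, marginal = TRUE) {
  stopifnot(inherits(spec, "cpModelSpec"))
  ids <- unique(controlData[[spec$group]])
  if (length(ids) < 3) stop("need at least 3 controls for leave-one-out")
  full <- fitGlmm(spec, controlData)
  if (identical(spec$random, "intercept"))
    return(looWarmIntercept(spec, controlData, full, marginal))
  rows <- vector("list", length(ids))
  conv <- logical(length(ids))
  for (k in seq_along(ids)) {
    keep <- controlData[[spec$group]] != ids[k]
    foldData <- controlData[keep, , drop = FALSE]
    foldFit <- fitGlmm(spec, foldData, start = full$par,
                       control = list(vcov = FALSE, rel.tol = 1e-9))
    conv[k] <- foldFit$converged
    held <- controlData[!keep, , drop = FALSE]
    rows[[k]] <- participantResiduals(foldFit, held, marginal)
  }
  out <- do.call(rbind, rows)
  out$extrapolated <- FALSE
  attr(out, "full_fit") <- full
  attr(out, "fold_converged") <- conv
  if (!all(conv))
    warning(sum(!conv), " leave-one-out fold(s) did not converge")
  out
}

# fast leave-one-out path for random-intercept models: one design build,
# per-fold fixed-metric Newton warm-started at the all-controls optimum
looWarmIntercept <- function(spec, controlData, full, marginal) {
  bd <- buildGlmmData(spec, controlData)
  P <- length(bd$levels)
  p <- ncol(bd$X)
  Hinv <- full$hessInv
  if (is.null(Hinv)) {
    lapFull <- makeLaplace1(bd$X, bd$s, bd$m, bd$pid, P)
    lapFull$fn(full$par)
    H <- numGradHessian(lapFull$gr, full$par)
    Hinv <- tryCatch(solve(H), error = function(e) diag(1e-2, p + 1))
  }
  obs <- expd <- resid <- numeric(P)
  conv <- logical(P)
  for (i in seq_len(P)) {
    k <- bd$pid != i
    pidf <- bd$pid[k]
    pidf[pidf > i] <- pidf[pidf > i] - 1L
    lap <- makeLaplace1(bd$X[k, , drop = FALSE], bd$s[k], bd$m[k],
                        pidf, P - 1L)
    par <- full$par
    ok <- FALSE
    for (it in 1:40) {
      g <- lap$gr(par)
      f0 <- lap$fn(par)
      if (max(abs(g)) < 1e-6 * (1 + abs(f0))) { ok <- TRUE; break }
      step <- -as.vector(Hinv %*% g)
      fac <- 1
      repeat {
        if (lap$fn(par + fac * step) <= f0 + 1e-10) break
        fac <- fac / 2
        if (fac < 1e-6) break
      }
      par <- par + fac * step
    }
    if (!ok) {
      opt <- nlminb(par, lap$fn, lap$gr,
                    control = list(rel.tol = 1e-11, iter.max = 500))
      opt2 <- optim(opt$par, lap$fn, lap$gr, method = "BFGS",
                    control = list(reltol = 1e-13, maxit = 500))
      par <- if (opt2$value < opt$objective) opt2$par else opt$par
      ok <- max(abs(lap$gr(par))) < 1e-4 * (1 + abs(lap$fn(par)))
    }
    conv[i] <- ok
    # held-out participant's observed and expected proportions
    h <- bd$pid == i
    eta <- as.vector(bd$X[h, , drop = FALSE] %*% par[1:p])
    pr <- if (marginal) {
      gh <- ghCache(20)
      as.vector(plogis(outer(eta, sqrt(2) * exp(par[p + 1]) * gh$x,
                             "+")) %*% gh$w / sqrt(pi))
    } else plogis(eta)
    obs[i] <- sum(bd$s[h]) / sum(bd$m[h])
    expd[i] <- sum(pr * bd$m[h]) / sum(bd$m[h])
    resid[i] <- obs[i] - expd[i]
  }
  out <- data.frame(participant_id = bd$levels, observed = obs,
                    expected = expd, residual = resid,
                    extrapolated = FALSE, stringsAsFactors = FALSE)
  attr(out, "full_fit") <- full
  attr(out, "fold_converged") <- conv
  if (!all(conv))
    warning(sum(!conv), " leave-one-out fold(s) did not converge")
  out
}

#' Standardize residuals into abnormality z-scores
#'
#' Transforms residuals into z-scores by subtracting the control residual
#' mean and dividing by the control residual standard deviation, so the
#' control column has mean 0 and sd 1 by construction.  The unconditional
#' control residual variance is used (not a variance conditional on the
#' covariate values).
#'
#' @param controlResiduals numeric vector of control residuals (typically
#'   `looControlResiduals()$residual`).
#' @param residuals numeric vector of residuals to standardize (defaults
#'   to the controls themselves).
#' @return Numeric z-scores; attributes `center` and `scale` carry the
#'   control mean and sd.
#' @export
standardizeScores <- function(controlResiduals, residuals = controlResiduals) {
  mu <- mean(controlResiduals)
  sdv <- sd(controlResiduals)
  if (!is.finite(sdv) || sdv <= 0)
    stop("control residual sd must be positive")
  structure((residuals - mu) / sdv, center = mu, scale = sdv)
}

#' Assemble a participants-by-tests z-score table
#'
#' @param scores data.frame or matrix of z-score columns (one per test;
#'   `NA` marks missing participation, which is distinct from a zero
#'   score).
#' @param group character vector (`"control"`/`"CP"`) aligned with rows.
#' @param participantId row identifiers.
#' @return A `zScoreTable`: numeric matrix with `participant_id` rownames
#'   and attributes `group` and `aggregates` (initially empty).
#' @export
zScoreTable <- function(scores, group, participantId = rownames(scores)) {
  m <- as.matrix(scores)
  stopifnot(is.numeric(m), length(group) == nrow(m),
            length(participantId) == nrow(m))
  rownames(m) <- participantId
  structure(m, group = group, aggregates = character(0),
            class = c("zScoreTable", class(m)))
}

#' @export
print.zScoreTable <- function(x, ...) {
  g <- attr(x, "group")
  cat("z-score table:", nrow(x), "participants (",
      sum(g == "control"), "controls,", sum(g != "control"), "cases ) x",
      ncol(x), "columns\n")
  cat("  aggregate columns:",
      if (length(attr(x, "aggregates")) == 0) "(none)"
      else paste(attr(x, "aggregates"), collapse = ", "), "\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Ingest externally standardized test scores
#'
#' Attaches already-standardized z-score columns (e.g. from short-term
#' test batteries analysed elsewhere) to the cohort, flipping the sign of
#' direction-reversed measures (such as reaction times, where larger
#' means worse) so that worse-than-expected performance is negative
#' everywhere, and re-standardizing each column against the ingested
#' control rows for internal consistency.
#'
#' @param scores data.frame/matrix of z columns, rows = participants.
#' @param group group vector aligned with rows.
#' @param flipColumns column names whose sign must be reversed at
#'   ingestion.
#' @param participantId row identifiers.
#' @return A [zScoreTable()].
#' @export
ingestExternalScores <- function(scores, group, flipColumns = character(0),
                                 participantId = rownames(scores)) {
  m <- as.matrix(scores)
  for (cl in flipColumns) {
    if (!cl %in% colnames(m)) stop("unknown column to flip: ", cl)
    m[, cl] <- -m[, cl]
  }
  ctl <- group == "control"
  for (j in seq_len(ncol(m))) {
    v <- m[ctl, j]
    v <- v[!is.na(v)]
    if (length(v) < 2 || sd(v) <= 0)
      stop("column ", colnames(m)[j], " has no usable control spread")
    m[, j] <- (m[, j] - mean(v)) / sd(v)
  }
  zScoreTable(m, group, participantId)
}

#' Default mapping of tests to deficit categories and aggregates
#'
#' Maps each separate test column to one of the three deficit categories
#' (perceptual, associative, mnestic) and defines the aggregate columns:
#' the three category means, faces-total, shoes-total and an overall mean.
#' Reaction-time and presentation-time tests probe perceptual encoding;
#' rotation and restricted encoding/decoding tests probe
#' percept-to-identity association; the long-term recognition and
#' famous-face tests probe identity memory.
#'
#' @return A list with elements `category` (named character) and
#'   `aggregates` (named list of member-column vectors).
#' @export
categoryMapDefault <- function() {
  category <- c(rt_faces = "perceptual", rt_shoes = "perceptual",
                pt80_faces = "perceptual", pt80_shoes = "perceptual",
                rotation_faces = "associative", rotation_shoes = "associative",
                learn_faces = "associative", test_faces = "associative",
                faces_longterm = "mnestic", shoes_longterm = "mnestic",
                bfft = "mnestic")
  sep <- names(category)
  aggregates <- list(
    perceptual = sep[category == "perceptual"],
    associative = sep[category == "associative"],
    mnestic = sep[category == "mnestic"],
    faces_total = grep("faces|bfft", sep, value = TRUE),
    shoes_total = grep("shoes", sep, value = TRUE),
    overall = sep)
  list(category = category, aggregates = aggregates)
}

#' Add aggregate category columns to a z-score table
#'
#' For every aggregate, each participant's available member-column
#' z-scores are averaged (at least one member required; participants
#' missing all members get a missing value), and the mean column is then
#' re-standardized against the control distribution of that mean, so
#' aggregates live on the same control-referenced z scale as the separate
#' columns.
#'
#' @param ztab a [zScoreTable()] of separate columns.
#' @param map a category map as from [categoryMapDefault()]; aggregates
#'   referencing columns absent from `ztab` use the intersection.
#' @return The `zScoreTable` with aggregate columns appended and recorded
#'   in the `aggregates` attribute.
#' @export
aggregateScores <- function(ztab, map = categoryMapDefault()) {
  stopifnot(inherits(ztab, "zScoreTable"))
  g <- attr(ztab, "group")
  ctl <- g == "control"
  newCols <- list()
  for (nm in names(map$aggregates)) {
    if (length(map$aggregates[[nm]]) == 0)
      stop("aggregate '", nm, "' references no existing columns")
    members <- intersect(map$aggregates[[nm]], colnames(ztab))
    if (length(members) == 0) {
      warning("aggregate '", nm, "' has no member column in the table; ",
              "skipped")
      next
    }
    sub <- unclass(ztab)[, members, drop = FALSE]
    mean_ <- rowMeans(sub, na.rm = TRUE)
    mean_[rowSums(!is.na(sub)) == 0] <- NA
    v <- mean_[ctl & !is.na(mean_)]
    if (length(v) < 2 || sd(v) <= 0)
      stop("aggregate '", nm, "' has no usable control spread")
    newCols[[nm]] <- (mean_ - mean(v)) / sd(v)
  }
  out <- cbind(unclass(ztab), do.call(cbind, newCols))
  structure(out, group = g,
            aggregates = c(attr(ztab, "aggregates"), names(newCols)),
            class = c("zScoreTable", class(out)))
}

#' Modified t-test for single-case deficits
#'
#' Compares one participant's z-score with the control sample that
#' defined the z scale, accounting for the control sample's finite size:
#' `t = z / sqrt((n + 1) / n)` with `df = n - 1`, where n is the number
#' of controls.  The test is one-sided in the deficit direction; a score
#' is called a deficit when it falls below the 5% quantile of that t
#' distribution (configurable via `alpha`).
#'
#' @param z numeric vector of case z-scores (NA allowed, propagated).
#' @param nControls number of controls behind the z scale (>= 2).
#' @param alpha one-sided cutoff level.
#' @return A data.frame: `z`, `t_statistic`, `df`, `p`, `is_deficit`.
#' @export
#' @examples
#' deficitTest(c(0, -5), nControls = 25)
deficitTest <- function(z, nControls, alpha = 0.05) {
  if (nControls < 2) stop("need at least 2 controls")
  tstat <- z / sqrt((nControls + 1) / nControls)
  p <- pt(tstat, df = nControls - 1)
  data.frame(z = z, t_statistic = tstat, df = nControls - 1, p = p,
             is_deficit = !is.na(p) & p < alpha)
}

#' Deficit calls for every cell of a z-score table
#'
#' Applies [deficitTest()] column-wise; the control count per column is
#' the number of non-missing control entries in that column.
#'
#' @param ztab a [zScoreTable()].
#' @param alpha one-sided cutoff level.
#' @return A long data.frame: `participant_id`, `column`, `z`,
#'   `t_statistic`, `df`, `p`, `is_deficit`.
#' @export
deficitCalls <- function(ztab, alpha = 0.05) {
  stopifnot(inherits(ztab, "zScoreTable"))
  g <- attr(ztab, "group")
  out <- lapply(colnames(ztab), function(cl) {
    zc <- unclass(ztab)[, cl]
    n <- sum(g == "control" & !is.na(zc))
    dt <- deficitTest(zc, n, alpha)
    data.frame(participant_id = rownames(ztab), column = cl, dt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
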