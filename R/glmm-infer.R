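#' Likelihood-ratio test of nested binomial mixed models
#'
#' Compares two fits of nested model specifications on the same data by the
#' deviance difference `D = 2 (logLik_alt - logLik_null)`, referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in parameter counts.  For fixed effects in mixed models this chi-squared
#' reference is known to be mildly anti-conservative, which is why
#' significant interaction effects are usually reported together with
#' Bayesian posterior summaries (see [posteriorSummary()]).
#'
#' @param nullFit,altFit `cpGlmm` fits of the null and the alternative
#'   (richer) model on the same observations.
#' @return A `cpLRTest` object with elements `D`, `df` and `p`.
#' @export
lrTest <- function(nullFit, altFit) {
  stopifnot(inherits(nullFit, "cpGlmm"), inherits(altFit, "cpGlmm"))
  if (nullFit$n_obs != altFit$n_obs)
    stop("fits are on different numbers of observations")
  if (!all(nullFit$spec$fixed %in% altFit$spec$fixed))
    stop("null model terms are not a subset of the alternative's")
  df <- altFit$npar - nullFit$npar
  if (df < 0) stop("alternative model has fewer parameters than the null")
  D <- 2 * (altFit$logLik - nullFit$logLik)
  if (D < 0 && D > -1e-6) D <- 0    # optimizer noise on identical models
  p <- if (df == 0) as.numeric(D <= 0) else pchisq(max(D, 0), df,
                                                   lower.tail = FALSE)
  structure(list(D = D, df = df, p = p), class = "cpLRTest")
}

#' @export
print.cpLRTest <- function(x, ...) {
  cat(sprintf("LR test: D = %.3f, df = %d, p = %.4g\n", x$D, x$df, x$p))
  invisible(x)
}

#' Expected correct-response probability under a fitted model
#'
#' Computes the expected probability of a correct response at given
#' covariate values, marginalised over the random effects by Gauss-Hermite
#' quadrature (default) or conditional on random effects equal to zero.
#' Marginalisation matters because the inverse logit is nonlinear: with a
#' positive random-effect sd the marginal probability is attenuated towards
#' one half relative to the conditional probability at zero.
#'
#' @param fit a `cpGlmm`.
#' @param newdata data.frame of covariate rows (no response needed).
#' @param marginal logical; marginalise over random effects (default) or
#'   condition at zero.
#' @param ghPoints number of Gauss-Hermite nodes per random-effect
#'   dimension.
#' @return Numeric vector of probabilities, one per row of `newdata`.
#' @export
predictExpected <- function(fit, newdata, marginal = TRUE, ghPoints = 20) {
  stopifnot(inherits(fit, "cpGlmm"))
  spec <- fit$spec
  fml <- stats::as.formula(paste("~", paste(spec$fixed, collapse = "+")))
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(newdata))
  if (length(miss) > 0)
    stop("newdata lack covariates: ", paste(miss, collapse = ", "))
  nd <- as.data.frame(newdata)
  for (nm in names(fit$xlev)) {
    if (!nm %in% names(nd)) next
    bad <- !is.na(nd[[nm]]) & !nd[[nm]] %in% fit$xlev[[nm]]
    if (any(bad))
      stop("unknown level in covariate '", nm, "': ",
           paste(unique(nd[[nm]][bad]), collapse = ", "))
    nd[[nm]] <- factor(nd[[nm]], levels = fit$xlev[[nm]])
  }
  X <- stats::model.matrix(fml, data = nd)
  if (!identical(colnames(X), names(fit$coefficients)))
    X <- X[, names(fit$coefficients), drop = FALSE]
  eta <- as.vector(X %*% fit$coefficients)
  if (!marginal || length(fit$random_sd) == 0 ||
      all(fit$random_sd < 1e-10)) {
    return(plogis(eta))
  }
  gh <- ghCache(ghPoints)
  if (length(fit$random_sd) == 1) {
    sig <- fit$random_sd[[1]]
    nodes <- sqrt(2) * sig * gh$x
    pm <- plogis(outer(eta, nodes, "+")) %*% gh$w / sqrt(pi)
    return(as.vector(pm))
  }
  # intercept + slope: tensor-product quadrature over (b0, b1)
  slopeVar <- setdiff(spec$random, "intercept")
  if (!slopeVar %in% names(newdata))
    stop("newdata lack random-slope covariate: ", slopeVar)
  zv <- as.numeric(newdata[[slopeVar]])
  p <- length(fit$coefficients)
  t1 <- fit$par[p + 1]; t2 <- fit$par[p + 2]; t3 <- fit$par[p + 3]
  L <- matrix(c(exp(t1), t2, 0, exp(t3)), 2, 2)
  g <- expand.grid(i = seq_len(ghPoints), j = seq_len(ghPoints))
  w2 <- gh$w[g$i] * gh$w[g$j] / pi
  u <- sqrt(2) * cbind(gh$x[g$i], gh$x[g$j]) %*% t(L)  # draws of (b0, b1)
  out <- numeric(length(eta))
  for (r in seq_along(eta)) {
    out[r] <- sum(w2 * plogis(eta[r] + u[, 1] + zv[r] * u[, 2]))
  }
  out
}

# ---------------------------------------------------------------------------
# Bayesian posterior summaries by adaptive Metropolis-within-Gibbs
# ---------------------------------------------------------------------------

#' Posterior modes and 95% HPD intervals for mixed-model coefficients
#'
#' Samples the posterior of a binomial logit mixed model with weakly
#' informative priors: independent normals with very large variance for the
#' fixed effects, and an inverse Wishart with one degree of freedom and
#' inverse scale equal to the unconditional response variance for the
#' random-effect (co)variance.  Sampling is adaptive random-walk
#' Metropolis-within-Gibbs: the fixed-effect block uses a multivariate
#' normal proposal shaped by the Laplace-fit covariance, random effects are
#' updated participant-wise (vectorised), and the random-effect variance is
#' a conjugate Gibbs draw.  Posterior modes are kernel-density peaks of the
#' marginal chains; intervals are shortest intervals containing 95% of the
#' samples.
#'
#' @param spec a [modelSpec()] with a random intercept (optionally plus one
#'   random slope).
#' @param data trial table as for [fitGlmm()].
#' @param coefficients names of fixed effects to summarise (default all).
#' @param nSamples post-burn-in samples to keep.
#' @param burnin adaptation/burn-in iterations to discard.
#' @param seed integer seed; identical seeds reproduce identical summaries.
#' @param priorFixedVar prior variance of each fixed effect.
#' @param rhatMax convergence threshold on the split-chain potential scale
#'   reduction factor; exceeding it raises a warning and flags the result.
#' @return A data.frame of class `cpPosterior` with one row per summarised
#'   coefficient: `coefficient`, `posterior_mode`, `hpdi_low`, `hpdi_high`,
#'   `n_samples`, `seed`, plus attributes `rhat` and `accept_rate`.
#' @export
posteriorSummary <- function(spec, data, coefficients = NULL,
                             nSamples = 4000, burnin = 1500, seed = 1,
                             priorFixedVar = 1e10, rhatMax = 1.05) {
  stopifnot(inherits(spec, "cpModelSpec"), !is.null(spec$random))
  bd <- buildGlmmData(spec, data)
  q <- length(spec$random)
  P <- length(bd$levels)
  p <- ncol(bd$X)
  # unconditional response variance sets the inverse-Wishart scale
  yRate <- bd$s / bd$m
  vy <- var(rep(yRate, bd$m))
  Sprior <- diag(vy, q)
  nu <- 1

  fit <- fitGlmm(spec, data)
  beta <- unname(fit$par[1:p])
  propCov <- fit$vcov
  if (any(!is.finite(propCov))) propCov <- diag(1e-3, p)
  propChol <- chol((2.38^2 / p) * propCov)
  scaleAdapt <- 1

  Z <- if (q == 2) bd$z else rep(0, length(bd$s))
  B <- matrix(0, P, q)
  if (q == 1 && length(fit$modes) == P) B[, 1] <- fit$modes
  if (q == 2 && is.matrix(fit$modes)) B <- fit$modes
  Sig <- diag(pmax(fit$random_sd, 0.05)^2, q)

  perPartLoglik <- function(offB) {
    eta <- offFix + offB
    rowsum(bd$s * eta - bd$m * log1pexp(eta), bd$pid)[, 1]
  }
  offOf <- function(B) {
    if (q == 1) B[bd$pid, 1] else B[bd$pid, 1] + B[bd$pid, 2] * Z
  }

  set.seed(seed)
  keep <- matrix(NA_real_, nSamples, p)
  accB <- 0; accb <- 0; nB <- 0; nb <- 0
  offFix <- as.vector(bd$X %*% beta)
  for (it in seq_len(burnin + nSamples)) {
    # fixed-effect block
    prop <- beta + as.vector(crossprod(propChol, rnorm(p))) * scaleAdapt
    offProp <- as.vector(bd$X %*% prop)
    offB <- offOf(B)
    etaNew <- offProp + offB
    etaOld <- offFix + offB
    la <- sum(bd$s * etaNew - bd$m * log1pexp(etaNew)) -
      sum(bd$s * etaOld - bd$m * log1pexp(etaOld)) +
      sum(beta^2 - prop^2) / (2 * priorFixedVar)
    nB <- nB + 1
    if (log(runif(1)) < la) { beta <- prop; offFix <- offProp; accB <- accB + 1 }
    if (it <= burnin && it %% 50 == 0) {   # adapt proposal scale
      rate <- accB / nB
      scaleAdapt <- scaleAdapt * exp(0.7 * (rate - 0.234))
      accB <- 0; nB <- 0
    }
    # random-effect updates, participant-wise
    Q <- solve(Sig)
    wsd <- 0.5
    for (k in seq_len(q)) {
      propB <- B
      propB[, k] <- B[, k] + rnorm(P, 0, wsd)
      llNew <- perPartLoglik(offOf(propB))
      llOld <- perPartLoglik(offOf(B))
      quadNew <- rowSums((propB %*% Q) * propB)
      quadOld <- rowSums((B %*% Q) * B)
      laB <- llNew - llOld - 0.5 * (quadNew - quadOld)
      acc <- log(runif(P)) < laB
      B[acc, k] <- propB[acc, k]
      accb <- accb + sum(acc); nb <- nb + P
    }
    # Gibbs draw of the random-effect (co)variance: inverse Wishart
    Sscat <- crossprod(B) + Sprior
    W <- rWishart(1, df = nu + P, Sigma = solve(Sscat))[, , 1]
    Sig <- solve(W)
    if (it > burnin) keep[it - burnin, ] <- beta
  }
  colnames(keep) <- names(fit$coefficients)
  if (is.null(coefficients)) coefficients <- colnames(keep)
  bad <- setdiff(coefficients, colnames(keep))
  if (length(bad) > 0)
    stop("unknown coefficients: ", paste(bad, collapse = ", "))
  rows <- lapply(coefficients, function(nm) {
    ch <- keep[, nm]
    dd <- density(ch)
    hp <- hpdInterval(ch, 0.95)
    data.frame(coefficient = nm,
               posterior_mode = dd$x[which.max(dd$y)],
               hpdi_low = hp[1], hpdi_high = hp[2],
               n_samples = nSamples, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rh <- apply(keep[, coefficients, drop = FALSE], 2, splitRhat)
  attr(out, "rhat") <- rh
  attr(out, "accept_rate") <- c(fixed = accB / max(nB, 1),
                                random = accb / max(nb, 1))
  if (any(rh > rhatMax)) {
    warning("split R-hat above ", rhatMax,
            " for: ", paste(names(rh)[rh > rhatMax], collapse = ", "))
    attr(out, "converged") <- FALSE
  } else attr(out, "converged") <- TRUE
  class(out) <- c("cpPosterior", "data.frame")
  out
}

# shortest interval containing `mass` of the samples
hpdInterval <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(mass * n)
  if (k >= n) return(c(xs[1], xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

# split-chain potential scale reduction factor (two halves of one chain)
splitRhat <- function(x) {
  n <- floor(length(x) / 2)
  a <- x[1:n]; b <- x[(n + 1):(2 * n)]
  W <- (var(a) + var(b)) / 2
  mu <- c(mean(a), mean(b))
  Bv <- n * var(mu)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}
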