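# ---------------------------------------------------------------------------
# Nonparametric group tests and correlations
# ---------------------------------------------------------------------------

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney U statistic of the first sample from
#' midranks (reported as `W`, so `0 <= W <= n_x * n_y` and swapping the
#' samples maps `W` to `n_x * n_y - W`).  The p-value is exact by
#' enumeration of rank assignments when both samples have at most 10
#' observations and there are no ties, and a normal approximation with
#' continuity and tie correction otherwise.  Backed by
#' [stats::wilcox.test()].
#'
#' @param x,y numeric samples (x first: by convention the control group,
#'   so "greater" states that controls score higher).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A `cpWilcoxon` object: `W`, `n_x`, `n_y`, `p`, `alternative`,
#'   `exact`.
#' @export
#' @examples
#' rankSumTest(c(3, 4), c(1, 2), alternative = "greater")  # W = 4, p = 1/6
rankSumTest <- function(x, y,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  structure(list(W = unname(wt$statistic), n_x = length(x),
                 n_y = length(y), p = wt$p.value,
                 alternative = alternative, exact = exact),
            class = "cpWilcoxon")
}

#' @export
print.cpWilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum: W = %g, n = (%d, %d), p = %.4g (%s, %s)\n",
              x$W, x$n_x, x$n_y, x$p, x$alternative,
              if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Rank correlation between two measures
#'
#' Spearman's rho on midranks (default), with the p-value from exact
#' permutation when n <= 8 (no ties) and the t approximation otherwise;
#' Pearson's r is available as an option.  Backed by [stats::cor.test()].
#'
#' @param a,b numeric vectors; incomplete pairs are dropped.
#' @param method `"spearman"` or `"pearson"`.
#' @param alternative directional hypothesis, as in [stats::cor.test()].
#' @return A `cpCorrelation` object: `rho`, `p`, `n`, `method`.
#' @export
#' @examples
#' rankCorrelation(1:4, c(1, 3, 2, 4))  # rho = 0.8
rankCorrelation <- function(a, b, method = c("spearman", "pearson"),
                            alternative = "two.sided") {
  method <- match.arg(method)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("constant input vector")
  if (method == "spearman") {
    ties <- any(duplicated(a)) || any(duplicated(b))
    ct <- suppressWarnings(
      cor.test(a, b, method = "spearman", alternative = alternative,
               exact = length(a) <= 8 && !ties))
  } else {
    ct <- cor.test(a, b, method = "pearson", alternative = alternative)
  }
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(a), method = method,
                 alternative = alternative),
            class = "cpCorrelation")
}

#' @export
print.cpCorrelation <- function(x, ...) {
  cat(sprintf("%s correlation: rho = %.3f, n = %d, p = %.4g (%s)\n",
              x$method, x$rho, x$n, x$p, x$alternative))
  invisible(x)
}
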