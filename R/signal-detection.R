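# ---------------------------------------------------------------------------
# Signal-detection summaries: confusion counts, error rates, d-prime
# ---------------------------------------------------------------------------

#' Tabulate hits, misses, false alarms and correct rejections
#'
#' Partitions a recognition trial table into the four signal-detection
#' outcome cells per participant and experiment: hits and misses on target
#' trials, false alarms and correct rejections on distractor trials.
#'
#' @param trials trial table with columns `participant_id`, `experiment`,
#'   `trial_type` (`"target"`/`"distractor"`) and `correct` (0/1).
#' @param participantId,experiment optional filters; with both set the
#'   result has a single row.
#' @param by optional extra grouping columns (e.g. `"part"`).
#' @return A data.frame of class `cpConfusion` with columns
#'   `participant_id`, `experiment`, any `by` columns, `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `n_target_trials`,
#'   `n_distractor_trials`.
#' @export
confusionCounts <- function(trials, participantId = NULL,
                            experiment = NULL, by = NULL) {
  need <- c("participant_id", "experiment", "trial_type", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    stop("trials lack columns: ", paste(miss, collapse = ", "))
  if (!is.null(participantId))
    trials <- trials[trials$participant_id %in% participantId, ]
  if (!is.null(experiment))
    trials <- trials[trials$experiment %in% experiment, ]
  if (nrow(trials) == 0) stop("no trials found for the requested subset")
  keys <- c("participant_id", "experiment", by)
  kdf <- trials[, keys, drop = FALSE]
  tgt <- trials$trial_type == "target"
  agg <- aggregate(cbind(hits = as.numeric(tgt & trials$correct == 1),
                         misses = as.numeric(tgt & trials$correct == 0),
                         false_alarms = as.numeric(!tgt & trials$correct == 0),
                         correct_rejections =
                           as.numeric(!tgt & trials$correct == 1)),
                   by = kdf, FUN = sum)
  agg$n_target_trials <- agg$hits + agg$misses
  agg$n_distractor_trials <- agg$false_alarms + agg$correct_rejections
  class(agg) <- c("cpConfusion", "data.frame")
  agg
}

#' Overall error rate from confusion counts
#'
#' `(misses + false alarms) / total trials`, the raw proportion of wrong
#' responses.
#'
#' @param counts a [confusionCounts()] table (or any data.frame with the
#'   four cells).
#' @return Numeric vector of error rates in `[0, 1]`, one per row.
#' @export
errorRate <- function(counts) {
  tot <- counts$hits + counts$misses + counts$false_alarms +
    counts$correct_rejections
  if (any(tot == 0)) stop("zero trials in at least one row")
  (counts$misses + counts$false_alarms) / tot
}

#' Sensitivity d-prime with extreme-rate correction
#'
#' `d' = qnorm(H) - qnorm(F)`, the distance between the target and
#' distractor familiarity distributions in sd units — a bias-free
#' sensitivity measure, unaffected by a conservative or liberal response
#' criterion.  Hit or false-alarm rates of exactly 0 or 1 are adjusted
#' before the quantile transform: the default `"halfN"` rule replaces 0 by
#' `1/(2N)` and 1 by `1 - 1/(2N)` (N the relevant trial count); the
#' `"loglinear"` rule adds 0.5 to each count and 1 to each denominator on
#' every row.
#'
#' @param counts a [confusionCounts()] table.
#' @param correction `"halfN"` (default) or `"loglinear"`.
#' @return A data.frame with columns `dprime`, `hit_rate_used`,
#'   `fa_rate_used`, `correction_applied`, one row per row of `counts`.
#' @export
#' @examples
#' cc <- data.frame(hits = 21, misses = 4, false_alarms = 4,
#'                  correct_rejections = 21,
#'                  n_target_trials = 25, n_distractor_trials = 25)
#' dprime(cc)  # H = F mirrored around 0.5: d' about 1.989
dprime <- function(counts, correction = c("halfN", "loglinear")) {
  correction <- match.arg(correction)
  nt <- counts$n_target_trials
  nd <- counts$n_distractor_trials
  if (any(nt == 0) || any(nd == 0))
    stop("d-prime needs at least one target and one distractor trial")
  if (correction == "loglinear") {
    H <- (counts$hits + 0.5) / (nt + 1)
    F <- (counts$false_alarms + 0.5) / (nd + 1)
    applied <- rep(TRUE, length(H))
  } else {
    H <- counts$hits / nt
    F <- counts$false_alarms / nd
    hx <- H <= 0 | H >= 1
    fx <- F <= 0 | F >= 1
    H[H <= 0] <- 1 / (2 * nt[H <= 0])
    H[H >= 1] <- 1 - 1 / (2 * nt[H >= 1])
    F[F <= 0] <- 1 / (2 * nd[F <= 0])
    F[F >= 1] <- 1 - 1 / (2 * nd[F >= 1])
    applied <- hx | fx
  }
  data.frame(dprime = qnorm(H) - qnorm(F),
             hit_rate_used = H, fa_rate_used = F,
             correction_applied = applied)
}

#' Per-participant signal-detection summary table
#'
#' Pools parts per participant and experiment (set `perPart = TRUE` for
#' per-part values) and joins counts, error rate and d-prime into the
#' table written as `sdt.csv` by the pipeline.
#'
#' @param trials trial table (see [confusionCounts()]).
#' @param correction extreme-rate correction rule for [dprime()].
#' @param perPart logical; split by part instead of pooling.
#' @return A data.frame with identification columns, the four confusion
#'   cells, `error_rate` and `dprime`.
#' @export
sdtSummary <- function(trials, correction = "halfN", perPart = FALSE) {
  cc <- confusionCounts(trials, by = if (perPart) "part" else NULL)
  dp <- dprime(cc, correction)
  cc$error_rate <- errorRate(cc)
  cc$dprime <- dp$dprime
  class(cc) <- "data.frame"
  cc
}
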