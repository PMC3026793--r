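# small aggregated cohort used across tests: nCtl controls (+ optional CPs),
# binomial cells per trial-type x rotation with the default design counts
tinyAggCohort <- function(nCtl = 10, nCP = 0, seed = 1,
                          effects = experimentEffects(),
                          design = studyDesign()) {
  cfg <- generativeConfig(nControls = nCtl, nCP = nCP)
  parts <- generateParticipants(cfg, childSeed(seed, "p"))
  agg <- cpmem:::simulateAggregatedLongTerm(parts, effects, design,
                                            childSeed(seed, "r"))
  list(participants = parts, agg = agg)
}

aggSpec <- function(fixed = c("age", "trial_type", "rotation"),
                    random = "intercept") {
  modelSpec("n_correct", fixed = fixed, random = random,
            group = "participant_id", trials = "n_trials")
}

# brute-force null distribution of the rank-sum statistic: enumerate all
# ways to assign the pooled ranks to the first sample
enumerateRankSum <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  allW <- apply(sets, 2, function(ix) sum(seq_len(nx + ny)[ix]) -
                  nx * (nx + 1) / 2)
  p <- switch(alternative,
              greater = mean(allW >= W),
              less = mean(allW <= W),
              two.sided = min(1, 2 * min(mean(allW >= W), mean(allW <= W))))
  list(W = W, p = p)
}

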