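# Independent oracles and shared fixtures for the test suite.

# Brute-force permutation oracle for the two-sided Mann-Whitney p-value:
# enumerates every assignment of the pooled ranks to the first group and
# compares rank sums, independently of the package's U-distribution path.
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= obs), mean(ws >= obs)))
}

# tiny noise-free plate set for normalization tests
noisefree_sim <- function(preset = "prochloraz_like", seed = 1, n_bio = 3) {
  assemble_experiment(preset_chemicals()[preset],
                      simulation_config(seed = seed, n_bio = n_bio,
                                        noise_cv = 0))
}

# the shipped per-concentration fixtures transcribed from the published
# results, with the per-chemical ER dilution folds used in those runs
narrative_fixture <- function() {
  calls <- utils::read.csv(system.file("extdata", "narrative_calls.csv",
                                       package = "h295calux"),
                           stringsAsFactors = FALSE)
  viab <- utils::read.csv(system.file("extdata", "narrative_viability.csv",
                                      package = "h295calux"),
                          stringsAsFactors = FALSE)
  list(calls = calls, viability = viab,
       er_fold = c(bpa = 6.25, butylparaben = 200 / 28,
                   default = mean(c(200 / 30, 200 / 28, 200 / 25))),
       ar_fold = 200 / 67)
}

narrative_classification <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- narrative_fixture()
      cache <<- classify_chemicals(fx$calls, fx$viability,
                                   er_fold = fx$er_fold,
                                   ar_fold = fx$ar_fold)
    }
    cache
  }
})
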