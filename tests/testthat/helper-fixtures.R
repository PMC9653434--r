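# Shared fixtures: compact protocols and constructed response tables.
# Timing is shortened relative to the in vivo presets so movie-scale tests
# run in seconds; the generators themselves default to the full protocol.

compactTwophotonSpec <- function(conditions = "odor") {
  twophotonProtocol(baseline_s = 2, stim_s = 2, iti_s = 2,
                    trialsPerBlock = 6, conditions = conditions)
}

compactMovie <- function(params = movieTruthParams(nCells = 20), seed = 3,
                         protoSeed = 2) {
  tt <- generateProtocol(compactTwophotonSpec(), 1, seed = protoSeed)
  generateMovie(tt, params, seed = seed)
}

# Long-format per-trial response table for the population-vector analyses.
# valuesByCondition: named list condition -> cells x odors matrix of mean
# response values (constant across trials; noiseSigma adds iid noise).
makeResponseTable <- function(session, cells, odors, nTrialsPerOdor,
                              valuesByCondition, responsiveMatrix,
                              noiseSigma = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in names(valuesByCondition)) {
    vals <- valuesByCondition[[cond]]
    for (oi in seq_along(odors)) for (ci in seq_along(cells)) {
      rows[[length(rows) + 1L]] <- data.frame(
        session = session, cell = cells[ci], odor = odors[oi],
        trial = seq_len(nTrialsPerOdor),
        value = unname(vals[ci, oi]) +
          stats::rnorm(nTrialsPerOdor, 0, noiseSigma),
        responsive = unname(responsiveMatrix[ci, oi]), condition = cond,
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
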