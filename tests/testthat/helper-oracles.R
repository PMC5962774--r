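# Independent brute-force oracles the fast implementations are checked
# against. These deliberately use naive loops, not the package's code paths.

# all-pairs alignment: for every event, scan every spike
oracle_align <- function(spike_times, event_times, window) {
  lapply(event_times, function(e) {
    rel <- c()
    for (s in spike_times) {
      d <- s - e
      if (d >= window[1] && d < window[2]) rel <- c(rel, d)
    }
    as.numeric(rel)
  })
}

# plug-in MI in bits from a joint count table, cell by cell
oracle_mi_bits <- function(joint) {
  n <- sum(joint)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  mi <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      p <- joint[i, j] / n
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  unname(mi)
}

# per-command unique-candidate matching; valid when inter-command spacing
# exceeds max_lag so each command has at most one admissible actuation
oracle_pair_separated <- function(commands, actuations, max_lag) {
  delays <- c()
  for (cmd in commands) {
    cand <- actuations[actuations >= cmd & actuations < cmd + max_lag]
    if (length(cand) > 0) delays <- c(delays, min(cand) - cmd)
  }
  delays
}

# random spike/event fixture for oracle-equivalence loops
random_trains <- function(seed, duration = 20) {
  set.seed(seed)
  sp <- spike_train(sort(runif(rpois(1, 60), 0, duration)),
                    session_duration = duration)
  ev <- event_train(sort(sample(seq(0.5, duration - 0.5, by = 0.25),
                                rpois(1, 8) + 2)),
                    session_duration = duration)
  list(spikes = sp, events = ev)
}
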