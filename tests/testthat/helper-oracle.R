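# Independent oracles, deliberately written with naive set arithmetic and
# full enumeration rather than through the package's computational paths.

# Set-based pairwise similarity straight from the definitions.
oracle_similarity <- function(inc, i, j, metric) {
  a <- colnames(inc)[inc[i, ] == 1L]
  b <- colnames(inc)[inc[j, ] == 1L]
  int <- length(intersect(a, b))
  switch(metric,
         jaccard = int / length(union(a, b)),
         simpson = int / min(length(a), length(b)),
         ochiai = int / sqrt(length(a) * length(b)))
}

# Objective recomputed from scratch by looping over all site pairs.
oracle_objective <- function(labels, S, gamma, penalty) {
  n <- length(labels)
  F <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (labels[i] == labels[j]) F <- F + S[i, j] + gamma
  F - penalty * sum(table(labels) == 1)
}

# All set partitions of n elements into at most max_blocks blocks,
# as restricted-growth label vectors.
oracle_partitions <- function(n, max_blocks) {
  out <- list()
  rec <- function(lab, used) {
    if (length(lab) == n) { out[[length(out) + 1L]] <<- lab; return() }
    for (c in seq_len(min(used + 1L, max_blocks))) rec(c(lab, c), max(used, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive optimum of the chase objective over <= max_blocks clusters.
oracle_best_objective <- function(S, gamma, penalty, max_blocks = 3L) {
  parts <- oracle_partitions(nrow(S), max_blocks)
  max(vapply(parts, oracle_objective, numeric(1), S = S, gamma = gamma,
             penalty = penalty))
}

# Spherical law of cosines: an algebraically different great-circle formula.
oracle_great_circle <- function(p, q) {
  la1 <- p[1] * pi / 180; la2 <- q[1] * pi / 180
  dl <- (q[2] - p[2]) * pi / 180
  cosv <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(dl)
  acos(pmin(pmax(cosv, -1), 1)) * 6371.0088
}
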