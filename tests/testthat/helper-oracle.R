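# Independent brute-force oracles, written against the definitions rather
# than the package internals: direct prefix enumeration for cut-points and
# a per-probe, per-type check for marker calls.

# Rank k is a cut-point iff, for every type present in ranks 1..k, the
# prefix holds all of that type's replicates.
oracle_cut_points <- function(types) {
  n <- length(types)
  totals <- table(types)
  out <- integer(0)
  for (k in seq_len(n - 1L)) {
    pre <- table(types[seq_len(k)])
    if (all(pre == totals[names(pre)])) out <- c(out, k)
  }
  out
}

# For every probe and every type t: is the set of samples holding the n_t
# largest values (stable descending order) exactly t's replicates? If so,
# recompute the score from raw means: the denominator group is t's
# replicates, the numerator group runs to the next cut-point (or the end).
oracle_markers <- function(x, groups) {
  g <- as.character(groups[colnames(x)])
  totals <- table(g)
  out <- list()
  for (p in seq_len(nrow(x))) {
    v <- x[p, ]
    if (max(v) == min(v)) next  # a flat profile segregates nothing
    ord <- order(v, decreasing = TRUE, method = "radix")
    ty <- g[ord]
    for (t in names(totals)) {
      nt <- totals[[t]]
      if (!setequal(which(g == t), ord[seq_len(nt)])) next
      cuts <- oracle_cut_points(ty)
      if (!length(cuts) || cuts[1L] != nt) next
      k2 <- if (length(cuts) >= 2L) cuts[2L] else length(v)
      out[[length(out) + 1L]] <- data.frame(
        probe_id = rownames(x)[p], marker_type = t,
        score = mean(v[ord][(nt + 1L):k2]) / mean(v[ord][seq_len(nt)]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(probe_id = character(0), marker_type = character(0),
                  score = numeric(0), stringsAsFactors = FALSE)
}

# Random positive expression matrix with occasional planted structure so
# marker calls actually occur.
rand_matrix <- function(n_types, reps, n_probes, plant_frac = 0.3) {
  types <- paste0("t", seq_len(n_types))
  reps <- rep_len(reps, n_types)
  g <- factor(rep(types, times = reps), levels = types)
  names(g) <- paste0(rep(types, times = reps), "_", sequence(reps))
  x <- matrix(stats::rnorm(n_probes * length(g), 7, 1), n_probes, length(g),
              dimnames = list(sprintf("p%03d", seq_len(n_probes)), names(g)))
  planted <- stats::runif(n_probes) < plant_frac
  for (i in which(planted)) {
    t <- sample(types, 1L)
    x[i, g == t] <- x[i, g == t] + stats::runif(1, 0, 4)
  }
  x <- pmax(x, 0.01)
  list(expr = x, groups = g)
}

# Literal BH step-up formula, independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * sorted[i] / i)
    adj[i] <- min(run, 1)
  }
  adj[order(o)]
}
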