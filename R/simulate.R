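# Seeded generator of expression matrices with planted tissue-specific
# markers, plus small hand-crafted fixture profiles. Ground truth from the
# generator backs the validation of every other module.

#' Simulate a normalized expression matrix with planted markers
#'
#' Emulates the input regime the detector is designed for: a log2-scale
#' normalized matrix over a few sample types with a small number of
#' replicates each. Background probe `p` gets `value = base_p + noise`,
#' with `base_p ~ N(baseline_mean, baseline_sd)` drawn once per probe and
#' `noise ~ N(0, noise_sd)` per cell. A planted marker probe for type `t`
#' additionally gets `delta` added to `t`'s samples only — an additive
#' shift on the log2 scale, i.e. a multiplicative fold-change in linear
#' space. For a planted probe the model-expected specificity score is
#' `base_p / (base_p + delta)`.
#'
#' Stray non-positive draws are truncated at a small positive floor (with
#' a message) rather than redrawn, preserving seed reproducibility. Each
#' probe maps to one gene, except a configured fraction of *background*
#' probes mapped ambiguously to two genes; planted probes stay
#' unambiguous so the gene-level truth is exact.
#'
#' Defaults mirror a five-tissue, three-replicate design with strong
#' markers (shift 8x the noise SD).
#'
#' @param n_types number of sample types.
#' @param replicates replicates per type; scalar or vector of length
#'   `n_types` (unequal designs allowed), each >= 2.
#' @param n_background number of background (non-marker) probes.
#' @param n_markers_per_type planted marker probes per type.
#' @param baseline_mean,baseline_sd per-probe baseline distribution,
#'   log2 scale.
#' @param delta marker shift in log2 units (>= 0).
#' @param noise_sd within-probe noise SD, log2 units.
#' @param ambiguous_frac fraction of background probes annotated to two
#'   genes, in \[0, 1\].
#' @param seed RNG seed; the same seed reproduces the output bit for bit.
#' @param types optional type labels; defaults to five human tissue names
#'   for `n_types <= 5`.
#' @return object of class `marker_sim`: list with `expr` (matrix),
#'   `groups` (named factor), `annotation` ([probe_annotation()]), `truth`
#'   (data.frame `probe_id`, `type`, `delta`, `gene_id`,
#'   `expected_score`) and `config`.
#' @examples
#' sim <- simulate_markers(n_background = 200, n_markers_per_type = 5, seed = 1)
#' fit <- detect_markers(sim$expr, sim$groups)
#' fit
#' @export
simulate_markers <- function(n_types = 5L, replicates = 3L,
                             n_background = 2000L, n_markers_per_type = 20L,
                             baseline_mean = 7, baseline_sd = 1,
                             delta = 2, noise_sd = 0.25,
                             ambiguous_frac = 0.1, seed = NULL,
                             types = NULL) {
  if (n_types < 2L) stop("need at least 2 sample types", call. = FALSE)
  replicates <- rep_len(as.integer(replicates), n_types)
  if (any(replicates < 2L))
    stop("each sample type needs at least 2 replicates", call. = FALSE)
  if (delta < 0 || baseline_sd < 0 || noise_sd < 0)
    stop("'delta' and SDs must be non-negative", call. = FALSE)
  if (ambiguous_frac < 0 || ambiguous_frac > 1)
    stop("'ambiguous_frac' must lie in [0, 1]", call. = FALSE)
  if (baseline_mean <= 0)
    stop("'baseline_mean' must be positive (log2-scale intensities); raise the baseline",
         call. = FALSE)
  if (is.null(types)) {
    types <- if (n_types <= 5L)
      c("brain", "heart", "kidney", "liver", "lung")[seq_len(n_types)]
    else paste0("type", seq_len(n_types))
  }
  stopifnot(length(types) == n_types, !anyDuplicated(types))

  if (!is.null(seed)) set.seed(seed)

  sample_type <- rep(types, times = replicates)
  sample_ids <- unlist(lapply(seq_len(n_types), function(i)
    paste(types[i], seq_len(replicates[i]), sep = "_")))
  n_samples <- length(sample_ids)
  n_marker <- n_types * n_markers_per_type
  n_probes <- n_marker + n_background
  probe_ids <- sprintf("P%05d", seq_len(n_probes))
  planted_type <- c(rep(types, each = n_markers_per_type),
                    rep(NA_character_, n_background))

  # draw order is fixed: baselines, then the noise matrix, then the
  # ambiguous-probe choice
  base <- stats::rnorm(n_probes, baseline_mean, baseline_sd)
  n_floor_base <- sum(base <= 0)
  if (n_floor_base) {
    base[base <= 0] <- 0.1
    message(n_floor_base, " baseline draw(s) truncated at 0.1")
  }
  values <- base + matrix(stats::rnorm(n_probes * n_samples, 0, noise_sd),
                          n_probes, n_samples)
  for (i in seq_len(n_marker))
    values[i, sample_type == planted_type[i]] <-
      values[i, sample_type == planted_type[i]] + delta
  n_floor_val <- sum(values <= 0)
  if (n_floor_val) {
    values[values <= 0] <- 0.01
    message(n_floor_val, " expression value(s) truncated at 0.01")
  }
  dimnames(values) <- list(probe_ids, sample_ids)

  gene_id <- sprintf("G%05d", seq_len(n_probes))
  gene_symbol <- sprintf("GENE%d", seq_len(n_probes))
  n_amb <- round(ambiguous_frac * n_background)
  amb <- if (n_amb > 0)
    sample(seq.int(n_marker + 1L, n_probes), n_amb) else integer(0)
  map_probe <- c(probe_ids, probe_ids[amb])
  map_gene <- c(gene_id, sprintf("GA%05d", seq_along(amb)))
  map_sym <- c(gene_symbol, sprintf("GENEA%d", seq_along(amb)))
  annotation <- probe_annotation(map_probe, map_gene, map_sym,
                                 all_probes = probe_ids,
                                 release = "synthetic")

  truth <- data.frame(probe_id = probe_ids[seq_len(n_marker)],
                      type = planted_type[seq_len(n_marker)],
                      delta = delta,
                      gene_id = gene_id[seq_len(n_marker)],
                      expected_score = base[seq_len(n_marker)] /
                        (base[seq_len(n_marker)] + delta),
                      stringsAsFactors = FALSE)
  groups <- factor(sample_type, levels = types)
  names(groups) <- sample_ids
  structure(list(expr = values, groups = groups, annotation = annotation,
                 truth = truth,
                 config = list(n_types = n_types, replicates = replicates,
                               n_background = n_background,
                               n_markers_per_type = n_markers_per_type,
                               baseline_mean = baseline_mean,
                               baseline_sd = baseline_sd, delta = delta,
                               noise_sd = noise_sd,
                               ambiguous_frac = ambiguous_frac,
                               seed = seed, types = types)),
            class = "marker_sim")
}

#' @export
print.marker_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic expression matrix with planted markers\n")
  cat(sprintf("  %d probes (%d planted: %d per type) x %d samples; %d types (%s)\n",
              nrow(x$expr), nrow(x$truth), cfg$n_markers_per_type,
              ncol(x$expr), cfg$n_types,
              paste(sprintf("%s x%d", cfg$types, cfg$replicates),
                    collapse = ", ")))
  cat(sprintf("  baseline N(%g, %g), shift delta = %g, noise SD = %g (log2 scale)\n",
              cfg$baseline_mean, cfg$baseline_sd, cfg$delta, cfg$noise_sd))
  invisible(x)
}

#' Hand-crafted fixture profiles
#'
#' Small deterministic matrices exercising the canonical profile shapes:
#'
#' * `five_tissue`: five tissues x 3 replicates, one probe whose sorted
#'   profile has the liver triplicate on top and the brain triplicate at
#'   the bottom, the middle nine samples interleaved — two cut-points, at
#'   positions 3 and 12; a positive marker for liver (and a negative one
#'   for brain when negative markers are requested).
#' * `all_ties`: every value equal; no cut-point, no marker call.
#' * `interleaved`: two types alternating; no prefix ever completes a
#'   replicate group.
#' * `unequal_replicates`: 2/3/3 design with a marker planted in the
#'   duplicate type, called with its first cut-point at position 2.
#'
#' @return named list; each element is a list with `expr` and `groups`
#'   ready for [detect_markers()].
#' @export
fixture_profiles <- function() {
  tissues5 <- c("liver", "heart", "kidney", "lung", "brain")
  g5 <- factor(rep(tissues5, each = 3), levels = tissues5)
  names(g5) <- paste(rep(tissues5, each = 3), 1:3, sep = "_")
  # sorted order: liver x3, then heart/kidney/lung interleaved, brain x3
  five_tissue_vals <- c(liver_1 = 12.0, liver_2 = 11.6, liver_3 = 11.2,
                 heart_1 = 9.0, kidney_1 = 8.8, lung_1 = 8.6,
                 heart_2 = 8.4, kidney_2 = 8.2, lung_2 = 8.0,
                 heart_3 = 7.8, kidney_3 = 7.6, lung_3 = 7.4,
                 brain_1 = 3.0, brain_2 = 2.8, brain_3 = 2.6)
  five_tissue <- matrix(five_tissue_vals[names(g5)], nrow = 1,
                 dimnames = list("CFB_like", names(g5)))

  ties <- matrix(3, nrow = 1, ncol = length(g5),
                 dimnames = list("flat", names(g5)))

  g2 <- factor(rep(c("a", "b"), 3), levels = c("a", "b"))
  names(g2) <- paste0(rep(c("a", "b"), 3), rep(1:3, each = 2))
  inter <- matrix(c(6, 5.5, 5, 4.5, 4, 3.5), nrow = 1,
                  dimnames = list("zigzag", names(g2)))

  gu <- factor(c("heart", "heart", "kidney", "kidney", "kidney",
                 "liver", "liver", "liver"),
               levels = c("heart", "kidney", "liver"))
  names(gu) <- c("heart_1", "heart_2", "kidney_1", "kidney_2", "kidney_3",
                 "liver_1", "liver_2", "liver_3")
  uneq <- matrix(c(11, 10.5, 6, 5.8, 5.6, 6.1, 5.9, 5.7), nrow = 1,
                 dimnames = list("duo_marker", names(gu)))

  list(five_tissue = list(expr = five_tissue, groups = g5),
       all_ties = list(expr = ties, groups = g5),
       interleaved = list(expr = inter, groups = g2),
       unequal_replicates = list(expr = uneq, groups = gu))
}
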