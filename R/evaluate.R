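# Evaluation against curated marker lists: precision/recall curves, the
# analytic random-selection baseline, a one-vs-rest t-test comparator with
# Benjamini-Hochberg adjustment, and marker-set overlap counts.

# Coerce known markers to a named list of gene-id character vectors.
as_known <- function(known) {
  if (is.data.frame(known)) {
    stopifnot(ncol(known) >= 2L)
    known <- split(as.character(known[[2L]]), as.character(known[[1L]]))
  }
  if (!is.list(known) || is.null(names(known)))
    stop("'known' must be a named list of gene-id vectors or a (type, gene_id) data.frame",
         call. = FALSE)
  lapply(known, function(g) unique(as.character(g)))
}

#' Precision/recall of predicted marker genes against curated markers
#'
#' For each score cutoff the gene-level predictions with best score at or
#' below the cutoff are compared with the curated ("real") markers.
#' Recall is the fraction of real markers identified; precision is the
#' fraction of predicted marker genes that are real markers. Two
#' strategies: `"combined"` pools all tissues' predictions against the
#' pooled known markers of all tissues; `"per_tissue"` compares each
#' tissue's predictions with that tissue's own known markers. Known
#' markers are first restricted to the platform gene universe, so genes
#' absent from the array never count against recall.
#'
#' @param genes gene-level predictions from [rollup_genes()] (columns
#'   `type`, `gene_id`, `best_score`).
#' @param known curated markers: named list (type -> gene ids) or a
#'   data.frame `(type, gene_id)`.
#' @param cutoffs score cutoffs in (0, 1].
#' @param strategy `"combined"` or `"per_tissue"`.
#' @param universe platform gene universe for restricting `known`;
#'   defaults to the `universe` attribute of `genes`. `NULL` disables the
#'   restriction.
#' @param zero_precision with zero predicted genes precision is undefined:
#'   `"omit"` (default) drops the point from the curve, `"one"` reports 1.
#' @return data.frame with columns `strategy`, `cutoff`, `n_predicted`,
#'   `n_identified`, `precision`, `recall`. Per-tissue rows carry
#'   `per_tissue:<type>` as strategy.
#' @export
precision_recall <- function(genes, known, cutoffs = seq(0.1, 1, by = 0.1),
                             strategy = c("combined", "per_tissue"),
                             universe = attr(genes, "universe"),
                             zero_precision = c("omit", "one")) {
  strategy <- match.arg(strategy)
  zero_precision <- match.arg(zero_precision)
  if (any(cutoffs <= 0 | cutoffs > 1))
    stop("cutoffs must lie in (0, 1]", call. = FALSE)
  known <- as_known(known)
  if (!is.null(universe))
    known <- lapply(known, intersect, y = universe)
  if (!length(unlist(known)))
    stop("no known markers left after restriction to the platform universe",
         call. = FALSE)

  point <- function(label, pred, kn, cutoff) {
    n_pred <- length(pred)
    n_id <- length(intersect(pred, kn))
    if (n_pred == 0L && zero_precision == "omit") return(NULL)
    data.frame(strategy = label, cutoff = cutoff, n_predicted = n_pred,
               n_identified = n_id,
               precision = if (n_pred) n_id / n_pred else 1,
               recall = n_id / length(kn), stringsAsFactors = FALSE)
  }

  rows <- list()
  for (ct in sort(cutoffs)) {
    keep <- genes[genes$best_score <= ct, , drop = FALSE]
    if (strategy == "combined") {
      rows[[length(rows) + 1L]] <-
        point("combined", unique(keep$gene_id), unique(unlist(known)), ct)
    } else {
      for (t in names(known)) {
        rows[[length(rows) + 1L]] <-
          point(paste0("per_tissue:", t),
                unique(keep$gene_id[keep$type == t]), known[[t]], ct)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(strategy = character(0), cutoff = numeric(0),
                      n_predicted = integer(0), n_identified = integer(0),
                      precision = numeric(0), recall = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Random-selection precision/recall baseline
#'
#' For a uniformly random selection of `s` genes out of a universe of `N`
#' containing `K` real markers, the number of real markers drawn is
#' hypergeometric, so the expected precision is the constant `K / N` and
#' the expected recall is `s / N` (taking E\[identified\] = s K / N over
#' both K and s as denominators). Returned analytically; an optional
#' seeded Monte-Carlo mode adds empirical means for plotting bands.
#'
#' @param universe_size number of candidate genes `N`.
#' @param known_total number of real markers `K` (`K <= N`).
#' @param sizes selection sizes to evaluate.
#' @param n_draws Monte-Carlo draws per size (0 = analytic only).
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return data.frame with columns `size`, `precision`, `recall` and, when
#'   `n_draws > 0`, `mc_precision`, `mc_recall`.
#' @export
random_baseline <- function(universe_size, known_total, sizes,
                            n_draws = 0L, seed = NULL) {
  if (known_total > universe_size)
    stop("'known_total' cannot exceed 'universe_size'", call. = FALSE)
  if (any(sizes < 0) || any(sizes > universe_size))
    stop("selection sizes must lie in [0, universe_size]", call. = FALSE)
  out <- data.frame(size = sizes,
                    precision = rep(known_total / universe_size, length(sizes)),
                    recall = sizes / universe_size)
  if (n_draws > 0L) {
    if (!is.null(seed)) set.seed(seed)
    mcp <- mcr <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
      s <- sizes[i]
      hits <- if (s == 0L) rep(0L, n_draws)
              else stats::rhyper(n_draws, known_total,
                                 universe_size - known_total, s)
      mcp[i] <- if (s == 0L) NA_real_ else mean(hits / s)
      mcr[i] <- mean(hits / known_total)
    }
    out$mc_precision <- mcp
    out$mc_recall <- mcr
  }
  out
}

#' One-vs-rest t-test marker baseline
#'
#' The conventional comparator: for every sample type each probe is tested
#' with a two-sample t-test of that type's samples against all remaining
#' samples (Welch's unequal-variance form by default; set
#' `var_equal = TRUE` for the pooled form). P-values are adjusted per
#' one-vs-rest comparison with the Benjamini-Hochberg procedure, and a
#' probe is selected as a t-test marker for a type when its adjusted
#' p-value is at most `alpha` and its mean in that type exceeds the mean
#' of the rest.
#'
#' Degenerate probes with zero variance in both groups get p = 1 when the
#' means are equal and p = 0 (flagged) when they differ.
#'
#' @param x,groups as in [detect_markers()].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch's.
#' @param min_replicates minimum replicate count per type.
#' @return object of class `ttest_markers`: a list with `stats` (one row
#'   per probe x type: means, statistic, df, p-values, selection flag),
#'   `alpha`, `var_equal`. Use [ttest_selected()] for the selected calls.
#' @export
ttest_markers <- function(x, groups, alpha = 0.05, var_equal = FALSE,
                          min_replicates = 2L) {
  check_expression(x)
  g <- as_grouping(groups, min_replicates = min_replicates)
  check_consistent(x, g)
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  gl <- as.character(g[colnames(x)])

  per_type <- lapply(levels(g), function(t) {
    in_t <- gl == t
    n1 <- sum(in_t); n0 <- sum(!in_t)
    x1 <- x[, in_t, drop = FALSE]; x0 <- x[, !in_t, drop = FALSE]
    m1 <- rowMeans(x1); m0 <- rowMeans(x0)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
    d <- m1 - m0
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      se2 <- sp2 * (1 / n1 + 1 / n0)
      df <- rep(n1 + n0 - 2, length(d))
    } else {
      a1 <- v1 / n1; a0 <- v0 / n0
      se2 <- a1 + a0
      df <- se2^2 / (a1^2 / (n1 - 1) + a0^2 / (n0 - 1))
    }
    tt <- d / sqrt(se2)
    p <- 2 * stats::pt(-abs(tt), df)
    degen <- se2 == 0
    if (any(degen)) {
      zero_d <- degen & d == 0
      p[zero_d] <- 1; tt[zero_d] <- 0
      p[degen & d != 0] <- 0
      df[degen] <- NA_real_
    }
    data.frame(probe_id = rownames(x), type = t, mean_type = m1,
               mean_rest = m0, statistic = tt, df = df, p_value = p,
               p_adjusted = stats::p.adjust(p, method = "BH"),
               degenerate = degen, stringsAsFactors = FALSE, row.names = NULL)
  })
  stats_tab <- do.call(rbind, per_type)
  stats_tab$selected <- stats_tab$p_adjusted <= alpha &
    stats_tab$mean_type > stats_tab$mean_rest
  structure(list(stats = stats_tab, alpha = alpha, var_equal = var_equal,
                 types = levels(g), n_probes = nrow(x)),
            class = "ttest_markers")
}

#' @export
print.ttest_markers <- function(x, ...) {
  cat(sprintf("One-vs-rest %s t-test markers (BH-adjusted, alpha = %g)\n",
              if (x$var_equal) "pooled" else "Welch", x$alpha))
  sel <- x$stats[x$stats$selected, ]
  cnt <- table(factor(sel$type, levels = x$types))
  cat(sprintf("  %d probes; selected per type: %s\n", x$n_probes,
              paste(sprintf("%s %d", names(cnt), as.vector(cnt)),
                    collapse = ", ")))
  invisible(x)
}

#' Selected t-test marker calls in marker-table form
#'
#' @param object a `ttest_markers` fit.
#' @return data.frame with columns `probe_id`, `marker_type`, `score` (the
#'   BH-adjusted p-value), suitable for [rollup_genes()].
#' @export
ttest_selected <- function(object) {
  stopifnot(inherits(object, "ttest_markers"))
  sel <- object$stats[object$stats$selected, , drop = FALSE]
  data.frame(probe_id = sel$probe_id, marker_type = sel$type,
             score = sel$p_adjusted, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with `m` p-values sorted
#' ascending, the adjusted value at rank `i` is `min over j >= i of
#' m * p_(j) / j`, capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Overlap structure of several marker gene sets
#'
#' Counts every region of the Venn partition of the given sets (each
#' element of the union is assigned to the unique region of the sets it
#' belongs to) and the pairwise Jaccard similarities.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `regions` (named integer vector; region names join
#'   member set names with `&`), `jaccard` (symmetric matrix) and
#'   `n_union`.
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    stop("'sets' must be a named list of at least 2 sets", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) member <- matrix(member, nrow = 1L,
                                        dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  # every non-empty subset of sets, in a stable order, zero-filled
  m <- length(sets)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  regions <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  jac <- matrix(1, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- jac[j, i] <- if (uni) inter / uni else 1
  }
  list(regions = regions, jaccard = jac, n_union = length(u))
}
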