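#' Detect tissue marker probe sets in a normalized expression matrix
#'
#' The central fitting function. For every probe the per-sample intensities
#' are sorted in decreasing order and the profile's cut-points — positions
#' where the samples above form complete replicate groups of whole sample
#' types — are located. A probe is called a positive marker for type `t`
#' when its first cut-point isolates exactly `t`'s replicates at the top of
#' the profile. The call's specificity score is the ratio of the mean of
#' the group following the first cut-point to the mean of the group
#' preceding it (the top group), so scores lie in (0, 1] and smaller means
#' more specific.
#'
#' Expression values are used exactly as supplied and are expected to be
#' normalized log2-scale intensities (e.g. RMA output); normalization is a
#' prerequisite, not something this function performs. Replicates are
#' required for every sample type, though not the same number per type.
#'
#' @param x numeric matrix of normalized intensities, probes in rows
#'   (rownames = probe ids), samples in columns (colnames = sample ids).
#'   All values must be finite and strictly positive.
#' @param groups sample-to-type assignment: named character/factor vector
#'   or two-column data.frame (sample_id, type), covering exactly the
#'   matrix columns.
#' @param score_mode how the group following the first cut-point is taken:
#'   `"segment"` (default) uses the segment up to the second cut-point (or
#'   the profile end), i.e. the second entry of the group-mean vector;
#'   `"rest"` pools all samples below the first cut-point. Provided for
#'   comparison; see the package vignette.
#' @param negative also report negative markers: a call for type `t` when
#'   the group below the last cut-point is exactly `t`'s replicates (one
#'   type at uniquely low expression). Off by default; the standard
#'   selection considers positive markers only.
#' @param min_replicates minimum replicate count per type (default 2; set
#'   3 for a stricter design).
#' @return an object of class `marker_detection`; see
#'   [marker_table()], [filter_markers()], and the `print`, `summary`,
#'   `coef` and `plot` methods.
#' @examples
#' fx <- fixture_profiles()$five_tissue
#' fit <- detect_markers(fx$expr, fx$groups)
#' fit
#' marker_table(fit)
#' @seealso [filter_markers()] to apply a score cutoff, [rollup_genes()]
#'   for gene-level marker sets, [ttest_markers()] for the one-vs-rest
#'   t-test baseline.
#' @export
detect_markers <- function(x, groups, score_mode = c("segment", "rest"),
                           negative = FALSE, min_replicates = 2L) {
  score_mode <- match.arg(score_mode)
  check_expression(x)
  g <- as_grouping(groups, min_replicates = min_replicates)
  check_consistent(x, g)
  gl <- as.character(g[colnames(x)])

  rows <- vector("list", nrow(x))
  for (p in seq_len(nrow(x))) {
    v <- x[p, ]
    # an all-equal profile carries no segregation information: no
    # cut-point, silently not a marker (ties elsewhere are fine — group
    # membership is decided by rank completeness, not value gaps)
    if (max(v) == min(v)) next
    ord <- order(v, decreasing = TRUE, method = "radix")
    ty <- gl[ord]
    cuts <- cut_positions_from_types(ty)
    if (!length(cuts)) next
    vs <- v[ord]
    means <- group_means(vs, cuts)
    calls <- list()

    k1 <- cuts[1L]
    if (all(ty[seq_len(k1)] == ty[1L])) {
      num <- if (score_mode == "segment") means[2L]
             else mean(vs[(k1 + 1L):length(vs)])
      calls[[length(calls) + 1L]] <- data.frame(
        probe_id = rownames(x)[p], marker_type = ty[1L],
        direction = "positive", score = num / means[1L],
        mean_group1 = means[1L], mean_group2 = num,
        n_cut_points = length(cuts), stringsAsFactors = FALSE)
    }

    if (negative) {
      kL <- cuts[length(cuts)]
      n <- length(ty)
      if (all(ty[(kL + 1L):n] == ty[n])) {
        m <- length(means)
        den <- if (score_mode == "segment") means[m - 1L]
               else mean(vs[seq_len(kL)])
        calls[[length(calls) + 1L]] <- data.frame(
          probe_id = rownames(x)[p], marker_type = ty[n],
          direction = "negative", score = means[m] / den,
          mean_group1 = den, mean_group2 = means[m],
          n_cut_points = length(cuts), stringsAsFactors = FALSE)
      }
    }
    if (length(calls)) rows[[p]] <- do.call(rbind, calls)
  }

  markers <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(markers))
    markers <- data.frame(probe_id = character(0), marker_type = character(0),
                          direction = character(0), score = numeric(0),
                          mean_group1 = numeric(0), mean_group2 = numeric(0),
                          n_cut_points = integer(0), stringsAsFactors = FALSE)
  markers <- sort_marker_table(markers, levels(g))
  structure(list(markers = markers,
                 n_probes = nrow(x), n_samples = ncol(x),
                 types = levels(g), replicates = as.vector(table(g)[levels(g)]),
                 score_mode = score_mode, negative = negative,
                 cutoff = 1, call = match.call()),
            class = "marker_detection")
}

# Deterministic table order: (type in grouping order, ascending score,
# probe id). Ascending score puts the most specific markers first.
sort_marker_table <- function(markers, type_levels) {
  if (!nrow(markers)) {
    rownames(markers) <- NULL
    return(markers)
  }
  o <- order(match(markers$marker_type, type_levels), markers$score,
             markers$probe_id, method = "radix")
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  markers
}

#' Apply a specificity-score cutoff to a marker detection
#'
#' Retains calls with `score <= cutoff` (inclusive: cutoff 1 keeps every
#' call). Within each type, calls stay ranked by ascending score, most
#' specific first, with ties broken by probe id.
#'
#' @param object a `marker_detection` from [detect_markers()].
#' @param cutoff score threshold in (0, 1].
#' @return a `marker_detection` restricted to the retained calls, with the
#'   cutoff recorded.
#' @export
filter_markers <- function(object, cutoff) {
  stopifnot(inherits(object, "marker_detection"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stop("'cutoff' must be a single value in (0, 1]", call. = FALSE)
  object$markers <- object$markers[object$markers$score <= cutoff, , drop = FALSE]
  rownames(object$markers) <- NULL
  object$cutoff <- cutoff
  object
}

#' Extract the marker call table
#'
#' @param object a `marker_detection`.
#' @return data.frame with columns `probe_id`, `marker_type`, `direction`,
#'   `score`, `mean_group1`, `mean_group2`, `n_cut_points`, sorted by
#'   (type, score, probe id).
#' @export
marker_table <- function(object) {
  stopifnot(inherits(object, "marker_detection"))
  object$markers
}

#' @export
print.marker_detection <- function(x, ...) {
  cat("Marker detection by sorted-profile cut-points\n")
  cat(sprintf("  %d probes, %d samples, %d sample types (%s)\n",
              x$n_probes, x$n_samples, length(x$types),
              paste(sprintf("%s: %d", x$types, x$replicates), collapse = ", ")))
  cat(sprintf("  score cutoff: %g; scoring: %s%s\n", x$cutoff, x$score_mode,
              if (x$negative) "; negative markers included" else ""))
  tab <- x$markers
  if (!nrow(tab)) {
    cat("  no marker calls\n")
  } else {
    cnt <- table(factor(tab$marker_type, levels = x$types))
    cat(sprintf("  %d marker call(s): %s\n", nrow(tab),
                paste(sprintf("%s %d", names(cnt), as.vector(cnt)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.marker_detection <- function(object, ...) {
  tab <- object$markers
  per_type <- do.call(rbind, lapply(object$types, function(t) {
    s <- tab$score[tab$marker_type == t]
    data.frame(type = t, n_markers = length(s),
               min_score = if (length(s)) min(s) else NA_real_,
               median_score = if (length(s)) stats::median(s) else NA_real_,
               max_score = if (length(s)) max(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_type = per_type, n_probes = object$n_probes,
                 cutoff = object$cutoff,
                 fraction_called = nrow(tab) / object$n_probes),
            class = "summary.marker_detection")
}

#' @export
print.summary.marker_detection <- function(x, ...) {
  cat(sprintf("Marker calls per type (cutoff %g; %.1f%% of %d probes called)\n",
              x$cutoff, 100 * x$fraction_called, x$n_probes))
  print(x$per_type, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
#' @describeIn detect_markers specificity scores as a named vector
#'   (names are probe ids; negative-marker calls, if present, are suffixed
#'   with `/neg`).
coef.marker_detection <- function(object, ...) {
  tab <- object$markers
  nm <- ifelse(tab$direction == "negative",
               paste0(tab$probe_id, "/neg"), tab$probe_id)
  stats::setNames(tab$score, nm)
}

#' Marker counts as a function of the score cutoff
#'
#' Plots, for a sweep of cutoffs, how many probes remain marker calls at
#' `score <= cutoff` — the standard diagnostic for choosing a cutoff
#' (counts are non-decreasing in the cutoff; less specific cutoffs admit
#' more markers).
#'
#' @param x a `marker_detection`.
#' @param cutoffs cutoff sweep, values in (0, 1].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data.frame of (cutoff, n_markers).
#' @export
plot.marker_detection <- function(x, cutoffs = seq(0.05, 1, by = 0.05), ...) {
  counts <- vapply(cutoffs, function(ct) sum(x$markers$score <= ct), integer(1))
  graphics::plot(cutoffs, counts, type = "s", xlab = "score cutoff",
                 ylab = "marker probe sets retained", ...)
  invisible(data.frame(cutoff = cutoffs, n_markers = counts))
}
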