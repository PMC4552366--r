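#' Sort one probe's expression profile in decreasing order
#'
#' Builds the sorted profile that the cut-point analysis operates on: the
#' probe's per-sample intensities ordered from highest to lowest, carrying
#' each sample's type label. Ties are broken by input sample order (stable
#' sort), so the result is deterministic across runs and platforms.
#'
#' @param values named numeric vector of normalized intensities for one
#'   probe; names are sample ids. All values must be finite and strictly
#'   positive.
#' @param groups sample-to-type assignment: a named character/factor vector
#'   or a two-column data.frame (sample_id, type).
#' @param probe_id optional probe identifier used in error messages and
#'   attached to the result.
#' @return a data.frame of class `sorted_profile` with columns `sample_id`,
#'   `type`, `value`, rows sorted by `value` decreasing.
#' @examples
#' sort_profile(c(A1 = 5, A2 = 4, B1 = 1, B2 = 2),
#'              c(A1 = "a", A2 = "a", B1 = "b", B2 = "b"))
#' @export
sort_profile <- function(values, groups, probe_id = NA_character_) {
  if (!is.numeric(values) || is.null(names(values)))
    stop("'values' must be a named numeric vector (one probe row)", call. = FALSE)
  g <- as_grouping(groups)
  bad <- names(values)[!is.finite(values) | values <= 0]
  if (length(bad))
    stop(sprintf("probe '%s': non-finite or non-positive value for sample(s) %s",
                 probe_id, paste(bad, collapse = ", ")), call. = FALSE)
  unl <- setdiff(names(values), names(g))
  if (length(unl))
    stop("unlabeled sample(s): ", paste(unl, collapse = ", "), call. = FALSE)
  ord <- order(values, decreasing = TRUE, method = "radix")
  out <- data.frame(sample_id = names(values)[ord],
                    type = as.character(g[names(values)])[ord],
                    value = unname(values[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "probe_id") <- probe_id
  class(out) <- c("sorted_profile", "data.frame")
  out
}

# Cut-point positions from the vector of type labels along a sorted profile.
# Rank k (1 <= k < n) is a cut-point iff the samples at ranks 1..k are
# exactly the union of the complete replicate sets of the types seen there.
# Equivalently: the summed replicate totals of the types first seen by rank
# k equal k.
cut_positions_from_types <- function(types) {
  n <- length(types)
  if (n < 2L) return(integer(0))
  f <- factor(types, levels = unique(types))
  tot <- tabulate(f)
  first <- !duplicated(f)
  expected <- cumsum(ifelse(first, tot[as.integer(f)], 0L))
  k <- seq_len(n - 1L)
  k[expected[k] == k]
}

#' Find the cut-points of a sorted expression profile
#'
#' A cut-point is a position in the descending-sorted profile where the
#' samples above it form complete replicate groups of one or more sample
#' types — it segregates whole types at high expression from the rest. A
#' profile can have several cut-points or none (types interleaved).
#'
#' Ties spanning a boundary do not invalidate a cut-point: membership is
#' decided by rank completeness, and a zero gap simply scores near 1. A
#' fully constant profile, however, carries no segregation information
#' and yields no cut-points.
#'
#' @param profile a `sorted_profile` from [sort_profile()], or a character
#'   vector of type labels already in sorted-profile order (the constant
#'   check requires the value column, so it applies to profiles only).
#' @return integer vector of cut-point positions, strictly increasing,
#'   possibly empty. Position `k` means k samples lie above the boundary.
#' @examples
#' p <- sort_profile(c(L1 = 9, L2 = 8.5, L3 = 8, B1 = 2, B2 = 1.9, B3 = 1.7),
#'                   c(L1 = "liver", L2 = "liver", L3 = "liver",
#'                     B1 = "brain", B2 = "brain", B3 = "brain"))
#' find_cut_points(p)  # 3: liver segregated on top (and brain below)
#' @export
find_cut_points <- function(profile) {
  types <- if (is.data.frame(profile)) {
    if (!"type" %in% names(profile))
      stop("'profile' must have a 'type' column", call. = FALSE)
    if ("value" %in% names(profile)) {
      if (is.unsorted(-profile$value))
        stop("'profile' is not sorted in decreasing order", call. = FALSE)
      if (nrow(profile) >= 2L &&
          profile$value[1L] == profile$value[nrow(profile)])
        return(integer(0))
    }
    as.character(profile$type)
  } else as.character(profile)
  if (length(types) < 2L)
    stop("a profile needs at least 2 samples", call. = FALSE)
  cut_positions_from_types(types)
}

#' Mean expression per segregated group
#'
#' `n` cut-points split a sorted profile into `n + 1` groups; each group is
#' summarized by the arithmetic mean of its expression values. Because the
#' profile is sorted decreasing, the mean vector is non-increasing.
#'
#' @param profile a `sorted_profile`, or a numeric vector of values already
#'   sorted in decreasing order.
#' @param cut_positions integer cut-point positions, strictly increasing,
#'   each in `1..n-1`. Empty yields the single overall mean.
#' @return numeric vector of group means, length `length(cut_positions) + 1`.
#' @examples
#' group_means(c(10, 10, 10, 5, 5, 5), 3)   # 10 5
#' group_means(c(12, 10, 6, 4), 2)          # 11 5
#' @export
group_means <- function(profile, cut_positions = integer(0)) {
  v <- if (is.data.frame(profile)) profile$value else as.numeric(profile)
  n <- length(v)
  cut_positions <- as.integer(cut_positions)
  if (length(cut_positions)) {
    if (is.unsorted(cut_positions, strictly = TRUE) ||
        any(cut_positions < 1L) || any(cut_positions > n - 1L))
      stop("cut positions must be strictly increasing and within 1..n-1",
           call. = FALSE)
  }
  bounds <- c(0L, cut_positions, n)
  vapply(seq_len(length(bounds) - 1L),
         function(i) mean(v[(bounds[i] + 1L):bounds[i + 1L]]),
         numeric(1))
}

#' Specificity score of one cut-point
#'
#' Cut-point `i` scores as the mean expression of the group following it
#' divided by the mean of the group preceding it. With values sorted
#' decreasing the ratio lies in (0, 1]: values near 0 indicate a wide gap
#' (high specificity), values near 1 a negligible one.
#'
#' @param means numeric vector of group means, as from [group_means()].
#' @param i cut-point index, `1 <= i <= length(means) - 1`.
#' @return the score `means[i + 1] / means[i]`.
#' @examples
#' score_cut_point(c(10, 5), 1)       # 0.5
#' score_cut_point(c(10, 8, 2), 2)    # 0.25
#' @export
score_cut_point <- function(means, i) {
  i <- as.integer(i)
  if (length(i) != 1L || i < 1L || i > length(means) - 1L)
    stop("cut-point index out of range", call. = FALSE)
  if (any(means <= 0))
    stop("group means must be positive", call. = FALSE)
  means[i + 1L] / means[i]
}
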