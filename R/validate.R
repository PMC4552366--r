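# Internal input validation shared by the user-facing entry points.
# The detector consumes normalized (log2-scale) intensities; ratio scores
# are only meaningful on strictly positive values, so positivity is a hard
# contract, not a warning.

check_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (probes x samples)",
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite expression value for probe '%s', sample '%s'",
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]),
         call. = FALSE)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(paste0("non-positive expression value for probe '%s', sample '%s'; ",
                        "normalized intensities must be strictly positive for ",
                        "ratio scores to lie in (0, 1]"),
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]),
         call. = FALSE)
  invisible(x)
}

# Coerce a sample-to-type assignment to a named factor. Accepts a named
# character/factor vector or a two-column data.frame (sample_id, type).
# Types keep first-appearance order.
as_grouping <- function(groups, min_replicates = 2L) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L)
      stop("grouping data.frame needs two columns: sample_id, type", call. = FALSE)
    g <- as.character(groups[[2L]])
    names(g) <- as.character(groups[[1L]])
    groups <- g
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("grouping must be named by sample id", call. = FALSE)
  if (anyDuplicated(names(groups)))
    stop("sample(s) assigned more than once: ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "),
         call. = FALSE)
  lab <- as.character(groups)
  if (anyNA(lab) || any(!nzchar(lab)))
    stop("every sample needs a non-empty type label", call. = FALSE)
  g <- factor(lab, levels = unique(lab))
  names(g) <- names(groups)
  if (nlevels(g) < 2L)
    stop("at least 2 distinct sample types are required", call. = FALSE)
  cnt <- table(g)
  small <- names(cnt)[cnt < min_replicates]
  if (length(small))
    stop("replicates are required for each sample type (>= ", min_replicates,
         "); too few samples for: ", paste(small, collapse = ", "), call. = FALSE)
  g
}

# Matrix columns and grouping must describe the same sample set.
check_consistent <- function(x, groups) {
  miss <- setdiff(colnames(x), names(groups))
  extra <- setdiff(names(groups), colnames(x))
  if (length(miss) || length(extra))
    stop("expression matrix and grouping disagree on samples",
         if (length(miss)) paste0("; unlabeled in grouping: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; absent from matrix: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}
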