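# Readers and writers for the tab-delimited interchange formats. All
# writers produce deterministic, byte-stable output for identical input.

#' Read a normalized expression matrix
#'
#' Tab-delimited text: first column probe identifiers, header row of
#' sample identifiers, numeric body. A gzipped file is accepted. The
#' matrix must satisfy the detector's contract: unique probe and sample
#' ids, all values finite and strictly positive.
#'
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @return numeric matrix, probes x samples.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file needs a probe-id column plus at least one sample column",
         call. = FALSE)
  probes <- as.character(raw[[1L]])
  samples <- colnames(raw)[-1L]
  body <- raw[-1L]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric expression value at data row %d, sample '%s': '%s'",
                     bad[1L], samples[j], col[bad[1L]]), call. = FALSE)
      body[[j]] <- num
    }
  }
  x <- as.matrix(as.data.frame(body, check.names = FALSE))
  dimnames(x) <- list(probes, samples)
  check_expression(x)
  x
}

#' Read a sample-to-type annotation
#'
#' Two tab-delimited columns, `sample_id` then `type`, with a header row
#' by default. Replicates are required: every sample type must have at
#' least `min_replicates` member samples, because the cut-point rule needs
#' complete replicate groups (the detector expects replicates for each
#' sample type, though not the same number for all types).
#'
#' @param path file path.
#' @param header does the file carry a header row (default TRUE).
#' @param min_replicates minimum replicates per type (default 2).
#' @return named factor, names = sample ids, levels = types in order of
#'   first appearance.
#' @export
read_grouping <- function(path, header = TRUE, min_replicates = 2L) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("sample annotation needs two tab-delimited columns: sample_id, type",
         call. = FALSE)
  as_grouping(stats::setNames(raw[[2L]], raw[[1L]]),
              min_replicates = min_replicates)
}

#' Read a curated known-marker list
#'
#' Tab-delimited, one row per (type, gene) pair: `type`, `gene_id` and an
#' optional `gene_symbol` column.
#'
#' @param path file path.
#' @param header does the file carry a header row (default TRUE).
#' @return named list, type -> character vector of gene ids.
#' @export
read_known_markers <- function(path, header = TRUE) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("known-marker file needs at least two columns: type, gene_id",
         call. = FALSE)
  as_known(raw[1:2])
}

fmt_num <- function(x) trimws(formatC(x, digits = 6, format = "g"))

#' Write a marker call table
#'
#' Tab-delimited with columns `probe_id`, `marker_type`, `score`,
#' `mean_group1`, `mean_group2`, `n_cut_points` (plus `direction` when
#' negative markers were requested), sorted by (type, score, probe id),
#' floating point rendered with 6 significant digits. An empty table
#' yields a header-only file.
#'
#' @param x a `marker_detection` or a compatible data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(x, path) {
  keep_dir <- inherits(x, "marker_detection") && x$negative
  tab <- if (inherits(x, "marker_detection")) x$markers else x
  cols <- c("probe_id", "marker_type",
            if (keep_dir || length(unique(tab$direction)) > 1L) "direction",
            "score", "mean_group1", "mean_group2", "n_cut_points")
  cols <- intersect(cols, names(tab))
  out <- tab[cols]
  for (cc in intersect(c("score", "mean_group1", "mean_group2"), cols))
    out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a gene-level marker table
#'
#' Columns `type`, `gene_id`, `gene_symbol`, `best_score`, `n_probes`.
#'
#' @param genes output of [rollup_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_markers <- function(genes, path) {
  out <- genes[c("type", "gene_id", "gene_symbol", "best_score", "n_probes")]
  out$best_score <- fmt_num(out$best_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a precision/recall table
#'
#' Columns `strategy`, `cutoff`, `n_predicted`, `n_identified`,
#' `precision`, `recall`.
#'
#' @param pr output of [precision_recall()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pr <- function(pr, path) {
  out <- pr
  out$precision <- fmt_num(out$precision)
  out$recall <- fmt_num(out$recall)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: probe-id first column, sample header.
#'
#' @param x numeric matrix, probes x samples.
#' @param path output path.
#' @param digits significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 6) {
  body <- apply(x, 2, function(col)
    trimws(formatC(col, digits = digits, format = "g")))
  out <- data.frame(probe_id = rownames(x), body,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a simulated data set to interchange files
#'
#' Writes `<prefix>_expr.tsv`, `<prefix>_pheno.tsv`,
#' `<prefix>_annotation.tsv` (NetAffx-style, genes joined by `" /// "`)
#' and `<prefix>_truth.tsv`, in the formats the readers consume.
#'
#' @param sim a `marker_sim` from [simulate_markers()].
#' @param prefix output path prefix.
#' @return character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "marker_sim"))
  paths <- paste0(prefix, c("_expr.tsv", "_pheno.tsv",
                            "_annotation.tsv", "_truth.tsv"))
  write_expression(sim$expr, paths[1L])
  utils::write.table(data.frame(sample_id = names(sim$groups),
                                type = as.character(sim$groups)),
                     paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  ann <- sim$annotation
  probes <- attr(ann, "probe_ids")
  gid <- vapply(probes, function(p) {
    g <- ann$gene_id[ann$probe_id == p]
    if (length(g)) paste(g, collapse = " /// ") else "---"
  }, character(1))
  sym <- vapply(probes, function(p) {
    s <- ann$gene_symbol[ann$probe_id == p]
    if (length(s)) paste(s, collapse = " /// ") else "---"
  }, character(1))
  utils::write.table(data.frame(probe_id = probes, gene_id = gid,
                                gene_symbol = sym),
                     paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  tr <- sim$truth
  tr$expected_score <- fmt_num(tr$expected_score)
  utils::write.table(tr, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(paths)
}
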