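# Probe-to-gene annotation handling (NetAffx-style exports) and gene-level
# rollup of marker tables.

#' Construct a probe annotation
#'
#' Long-form probe-to-gene map: one row per (probe, gene) pair. Probes with
#' no annotation are listed in the probe universe but have no rows. A probe
#' with several rows is ambiguous.
#'
#' @param probe_id,gene_id,gene_symbol parallel character vectors, one
#'   element per (probe, gene) pair.
#' @param all_probes character vector of every probe on the platform
#'   (defaults to the probes appearing in `probe_id`).
#' @param release free-text annotation release label.
#' @return a data.frame of class `probe_annotation` with attributes
#'   `probe_ids` (the platform probe universe) and `release`.
#' @export
probe_annotation <- function(probe_id, gene_id, gene_symbol = gene_id,
                             all_probes = unique(probe_id), release = NA_character_) {
  map <- data.frame(probe_id = as.character(probe_id),
                    gene_id = as.character(gene_id),
                    gene_symbol = as.character(gene_symbol),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map[c("probe_id", "gene_id")]))
    stop("duplicated (probe, gene) annotation pair", call. = FALSE)
  miss <- setdiff(map$probe_id, all_probes)
  if (length(miss))
    stop("annotated probe(s) missing from the probe universe: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  structure(map, probe_ids = unique(as.character(all_probes)),
            release = release,
            class = c("probe_annotation", "data.frame"))
}

#' Read a NetAffx-style probe annotation table
#'
#' Tab-delimited, three columns: probe id, gene id(s), gene symbol(s).
#' Multiple genes of an ambiguous probe are separated by `" /// "`; `"---"`
#' or an empty field means the probe is unannotated. A gzipped file is
#' accepted.
#'
#' @param path file path.
#' @param header does the file carry a header row (default TRUE).
#' @param release annotation release label to record.
#' @return a [probe_annotation()].
#' @export
read_annotation <- function(path, header = TRUE, release = NA_character_) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 3L)
    stop("annotation file needs 3 tab-delimited columns: probe_id, gene_id(s), gene_symbol(s)",
         call. = FALSE)
  probes <- raw[[1L]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicated annotation row(s) for probe(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  split_field <- function(s) {
    parts <- trimws(strsplit(s, "///", fixed = TRUE)[[1L]])
    parts[nzchar(parts) & parts != "---"]
  }
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ids <- split_field(raw[[2L]][i])
    sym <- split_field(raw[[3L]][i])
    if (!length(ids)) next
    if (length(sym) != length(ids)) {
      if (length(sym) <= 1L) sym <- rep(if (length(sym)) sym else NA_character_,
                                        length(ids))
      else stop(sprintf("malformed annotation at data line %d (probe '%s'): %d gene ids but %d symbols",
                        i, probes[i], length(ids), length(sym)), call. = FALSE)
    }
    rows[[i]] <- data.frame(probe_id = probes[i], gene_id = ids,
                            gene_symbol = sym, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(map))
    map <- data.frame(probe_id = character(0), gene_id = character(0),
                      gene_symbol = character(0), stringsAsFactors = FALSE)
  probe_annotation(map$probe_id, map$gene_id, map$gene_symbol,
                   all_probes = probes, release = release)
}

#' Roll marker probe calls up to gene-level marker sets
#'
#' Maps called probes to genes and deduplicates: a gene predicted by
#' several probes is kept once per type with the best (minimum) score. By
#' default only probes mapping unambiguously to exactly one gene
#' contribute — the identification rule used throughout the evaluation;
#' with `unambiguous_only = FALSE` every mapped gene of an ambiguous probe
#' contributes (more permissive, for exploration). Unannotated probes
#' never contribute; their count is reported as an attribute.
#'
#' @param x a `marker_detection` (positive calls are used) or a data.frame
#'   with columns `probe_id`, `marker_type`, `score`.
#' @param annotation a [probe_annotation()].
#' @param unambiguous_only require a one-gene mapping (default TRUE).
#' @return data.frame with columns `type`, `gene_id`, `gene_symbol`,
#'   `best_score`, `n_probes`, sorted by (type, best_score, gene_id), with
#'   attributes `universe` (all gene ids in the annotation),
#'   `n_unmapped` (calls dropped for missing annotation) and `n_ambiguous`
#'   (calls dropped for ambiguity, when `unambiguous_only`).
#' @export
rollup_genes <- function(x, annotation, unambiguous_only = TRUE) {
  stopifnot(inherits(annotation, "probe_annotation"))
  tab <- if (inherits(x, "marker_detection")) {
    m <- x$markers
    m[m$direction == "positive", c("probe_id", "marker_type", "score")]
  } else {
    stopifnot(all(c("probe_id", "marker_type", "score") %in% names(x)))
    x[c("probe_id", "marker_type", "score")]
  }
  universe <- unique(annotation$gene_id)
  ngenes <- table(annotation$probe_id)
  n_per_probe <- as.vector(ngenes[tab$probe_id])
  n_per_probe[is.na(n_per_probe)] <- 0L
  n_unmapped <- sum(n_per_probe == 0L)
  if (unambiguous_only) {
    n_ambiguous <- sum(n_per_probe > 1L)
    tab <- tab[n_per_probe == 1L, , drop = FALSE]
  } else {
    n_ambiguous <- 0L
    tab <- tab[n_per_probe >= 1L, , drop = FALSE]
  }
  merged <- merge(tab, annotation, by = "probe_id")
  if (nrow(merged)) {
    key <- paste(merged$marker_type, merged$gene_id, sep = "\r")
    best <- tapply(merged$score, key, min)
    nprb <- tapply(merged$probe_id, key, function(p) length(unique(p)))
    first <- merged[!duplicated(key), , drop = FALSE]
    fkey <- paste(first$marker_type, first$gene_id, sep = "\r")
    out <- data.frame(type = first$marker_type, gene_id = first$gene_id,
                      gene_symbol = first$gene_symbol,
                      best_score = as.vector(best[fkey]),
                      n_probes = as.integer(nprb[fkey]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$type, out$best_score, out$gene_id, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(type = character(0), gene_id = character(0),
                      gene_symbol = character(0), best_score = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE)
  }
  attr(out, "universe") <- universe
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}
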