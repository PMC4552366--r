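gene_preds <- function(ids, types = "liver", scores = 0.5) {
  g <- data.frame(type = rep_len(types, length(ids)), gene_id = ids,
                  gene_symbol = ids, best_score = rep_len(scores, length(ids)),
                  n_probes = 1L, stringsAsFactors = FALSE)
  attr(g, "universe") <- NULL
  g
}

test_that("precision/recall follows the set arithmetic", {
  known <- list(liver = paste0("g", 1:10))
  pred <- gene_preds(c(paste0("g", 1:4), paste0("x", 1:4)))
  pr <- precision_recall(pred, known, cutoffs = 1, universe = NULL)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.4)
  expect_equal(pr$n_predicted, 8L)
  expect_equal(pr$n_identified, 4L)

  same <- precision_recall(gene_preds(paste0("g", 1:10)), known,
                           cutoffs = c(0.5, 1), universe = NULL)
  expect_true(all(same$precision == 1 & same$recall == 1))

  disj <- precision_recall(gene_preds(paste0("x", 1:5)), known,
                           cutoffs = 1, universe = NULL)
  expect_true(all(disj$precision == 0 & disj$recall == 0))
})

test_that("known markers are restricted to the platform universe", {
  known <- list(liver = c("g1", "g2", "off_platform"))
  pred <- gene_preds(c("g1", "g2"))
  pr <- precision_recall(pred, known, cutoffs = 1,
                         universe = c("g1", "g2", "g3"))
  expect_equal(pr$recall, 1)
  expect_error(precision_recall(pred, list(liver = "off_platform"),
                                cutoffs = 1, universe = c("g1", "g2")),
               "no known markers")
})

test_that("per-tissue and combined strategies agree with disjoint known sets", {
  pred <- data.frame(type = c("liver", "liver", "brain"),
                     gene_id = c("g1", "g2", "h1"), gene_symbol = "",
                     best_score = c(0.2, 0.8, 0.3), n_probes = 1L)
  known <- list(liver = c("g1", "g9"), brain = c("h1", "h2"))
  per <- precision_recall(pred, known, cutoffs = 1, strategy = "per_tissue",
                          universe = NULL)
  comb <- precision_recall(pred, known, cutoffs = 1, universe = NULL)
  expect_equal(sum(per$n_identified), comb$n_identified)
  expect_setequal(per$strategy, c("per_tissue:liver", "per_tissue:brain"))

  # recall and identified counts are non-decreasing in cutoff
  sweep <- precision_recall(pred, known, cutoffs = c(0.1, 0.25, 0.5, 1),
                            universe = NULL, zero_precision = "one")
  expect_false(is.unsorted(sweep$recall))
  expect_false(is.unsorted(sweep$n_identified))
})

test_that("zero-prediction points are omitted by default or pinned to 1", {
  pred <- gene_preds("g1", scores = 0.9)
  known <- list(liver = "g1")
  omit <- precision_recall(pred, known, cutoffs = c(0.1, 1), universe = NULL)
  expect_equal(omit$cutoff, 1)
  one <- precision_recall(pred, known, cutoffs = c(0.1, 1), universe = NULL,
                          zero_precision = "one")
  expect_equal(one$precision[one$cutoff == 0.1], 1)
  expect_equal(one$recall[one$cutoff == 0.1], 0)
})

test_that("random baseline matches the hypergeometric expectation", {
  rb <- random_baseline(100, 10, c(50, 100))
  expect_equal(rb$precision, c(0.1, 0.1))
  expect_equal(rb$recall, c(0.5, 1))
  expect_error(random_baseline(100, 10, 150), "sizes")
  expect_error(random_baseline(10, 20, 5), "exceed")

  mc <- random_baseline(200, 20, 50, n_draws = 10000, seed = 99)
  se_p <- sqrt(0.1 * 0.9 / 50) / sqrt(10000)  # binomial bound on the SE
  expect_lt(abs(mc$mc_precision - mc$precision), 3 * se_p)
  expect_lt(abs(mc$mc_recall - mc$recall), 3 * se_p * 50 / 20)
})

test_that("one-vs-rest t-test matches base t.test and selects by adjusted p and direction", {
  set.seed(13)
  d <- rand_matrix(3, c(3, 4, 5), n_probes = 25)
  tt <- ttest_markers(d$expr, d$groups, alpha = 0.05)
  g <- as.character(d$groups[colnames(d$expr)])
  for (i in sample(nrow(d$expr), 5)) {
    for (t in unique(g)) {
      ref <- t.test(d$expr[i, g == t], d$expr[i, g != t])
      row <- tt$stats[tt$stats$probe_id == rownames(d$expr)[i] &
                        tt$stats$type == t, ]
      expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(row$df, unname(ref$parameter), tolerance = 1e-12)
    }
  }
  expect_true(all(tt$stats$p_adjusted >= tt$stats$p_value - 1e-15))
  expect_true(all(tt$stats$p_adjusted <= 1))
  sel <- tt$stats[tt$stats$selected, ]
  expect_true(all(sel$mean_type > sel$mean_rest))

  pooled <- ttest_markers(d$expr, d$groups, var_equal = TRUE)
  i <- 1; t <- unique(g)[1]
  ref <- t.test(d$expr[i, g == t], d$expr[i, g != t], var.equal = TRUE)
  row <- pooled$stats[pooled$stats$probe_id == rownames(d$expr)[i] &
                        pooled$stats$type == t, ]
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("t-test handles flat and degenerate probes without error", {
  g <- factor(rep(c("a", "b"), each = 3))
  names(g) <- paste0("s", 1:6)
  x <- rbind(flat = rep(4, 6), gap = c(8, 8, 8, 2, 2, 2))
  colnames(x) <- names(g)
  tt <- ttest_markers(x, g)
  flat <- tt$stats[tt$stats$probe_id == "flat", ]
  expect_true(all(flat$p_value == 1))
  expect_false(any(flat$selected))
  gap <- tt$stats[tt$stats$probe_id == "gap" & tt$stats$type == "a", ]
  expect_equal(gap$p_value, 0)
  expect_true(gap$degenerate)
  expect_true(gap$selected)
})

test_that("strongly planted markers are detected by the t-test route", {
  sim <- simulate_markers(n_background = 15, n_markers_per_type = 1,
                          delta = 2, noise_sd = 0.25, seed = 17)
  tt <- ttest_markers(sim$expr, sim$groups, alpha = 0.05)

  # independent route: base t.test + p.adjust per one-vs-rest comparison
  g <- as.character(sim$groups[colnames(sim$expr)])
  oracle_sel <- character(0)
  for (t in levels(sim$groups)) {
    p <- apply(sim$expr, 1, function(v)
      t.test(v[g == t], v[g != t])$p.value)
    up <- rowMeans(sim$expr[, g == t, drop = FALSE]) >
      rowMeans(sim$expr[, g != t, drop = FALSE])
    hit <- which(p.adjust(p, "BH") <= 0.05 & up)
    if (length(hit))
      oracle_sel <- c(oracle_sel, paste(rownames(sim$expr)[hit], t))
  }
  sel <- ttest_selected(tt)
  expect_setequal(paste(sel$probe_id, sel$marker_type), oracle_sel)

  # every planted probe is strongly differential (raw p) for its tissue,
  # and the cut-point detector recovers all of them
  tk <- paste(sim$truth$probe_id, sim$truth$type)
  raw <- tt$stats[paste(tt$stats$probe_id, tt$stats$type) %in% tk, ]
  expect_true(all(raw$p_value < 0.05))
  det <- marker_table(detect_markers(sim$expr, sim$groups))
  expect_true(all(tk %in% paste(det$probe_id, det$marker_type)))
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.04, 0.04)), c(0.04, 0.04))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("overlap counts partition the union", {
  ov <- overlap_counts(list(s1 = c("a", "b"), s2 = c("b", "c")))
  expect_equal(ov$regions[["s1"]], 1L)
  expect_equal(ov$regions[["s2"]], 1L)
  expect_equal(ov$regions[["s1&s2"]], 1L)
  expect_equal(ov$jaccard["s1", "s2"], 1 / 3)

  same <- overlap_counts(list(x = letters[1:4], y = letters[1:4]))
  expect_equal(same$regions[["x&y"]], 4L)
  expect_equal(sum(same$regions), 4L)

  set.seed(6)
  sets <- list(a = sample(letters, 10), b = sample(letters, 8),
               c = sample(letters, 12))
  ov3 <- overlap_counts(sets)
  expect_equal(sum(ov3$regions), length(unique(unlist(sets))))
  expect_equal(ov3$n_union, length(unique(unlist(sets))))
  expect_error(overlap_counts(list(a = "x")), "at least 2")
})
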