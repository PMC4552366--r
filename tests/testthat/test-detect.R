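test_that("the five-tissue fixture yields a liver positive marker only", {
  fx <- fixture_profiles()$five_tissue
  fit <- detect_markers(fx$expr, fx$groups)
  tab <- marker_table(fit)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$marker_type, "liver")
  expect_equal(tab$direction, "positive")
  expect_equal(tab$n_cut_points, 2L)
  # score = mean(middle nine) / mean(liver triplicate)
  v <- sort(fx$expr[1, ], decreasing = TRUE)
  expect_equal(tab$score, mean(v[4:12]) / mean(v[1:3]))

  # brain sits uniquely at the bottom: a negative marker when requested
  fitn <- detect_markers(fx$expr, fx$groups, negative = TRUE)
  tabn <- marker_table(fitn)
  expect_equal(nrow(tabn), 2L)
  neg <- tabn[tabn$direction == "negative", ]
  expect_equal(neg$marker_type, "brain")
  expect_equal(neg$score, mean(v[13:15]) / mean(v[4:12]))
})

test_that("constant and interleaved profiles yield no calls", {
  fx <- fixture_profiles()
  expect_equal(nrow(marker_table(
    detect_markers(fx$all_ties$expr, fx$all_ties$groups))), 0L)
  expect_equal(nrow(marker_table(
    detect_markers(fx$interleaved$expr, fx$interleaved$groups))), 0L)
})

test_that("unequal replicate designs are supported; duplicate type cut at 2", {
  fx <- fixture_profiles()$unequal_replicates
  fit <- detect_markers(fx$expr, fx$groups)
  tab <- marker_table(fit)
  expect_equal(tab$marker_type, "heart")
  p <- sort_profile(fx$expr[1, ], fx$groups)
  expect_equal(find_cut_points(p)[1], 2L)
  # strict triplicate mode rejects the duplicate design
  expect_error(detect_markers(fx$expr, fx$groups, min_replicates = 3),
               "replicates")
})

test_that("detection equals the brute-force oracle on random matrices", {
  set.seed(101)
  for (i in 1:40) {
    n_types <- sample(2:6, 1)
    reps <- sample(2:4, n_types, replace = TRUE)
    d <- rand_matrix(n_types, reps, n_probes = sample(5:30, 1))
    got <- marker_table(detect_markers(d$expr, d$groups))
    want <- oracle_markers(d$expr, d$groups)
    got <- got[order(got$probe_id), c("probe_id", "marker_type", "score")]
    want <- want[order(want$probe_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("planted markers are recovered exactly when the shift dwarfs the noise", {
  sim <- simulate_markers(n_background = 300, n_markers_per_type = 10,
                          delta = 3, noise_sd = 0.25, seed = 5)
  # background probes can top a complete replicate group by chance, but
  # only with scores near 1; the 0.9 cutoff separates planted structure
  tab <- marker_table(filter_markers(detect_markers(sim$expr, sim$groups),
                                     0.9))
  got <- tab[c("probe_id", "marker_type")]
  want <- sim$truth[c("probe_id", "type")]
  expect_setequal(paste(got$probe_id, got$marker_type),
                  paste(want$probe_id, want$type))
})

test_that("scores are in (0, 1] and invariant to column permutation and scaling", {
  set.seed(77)
  d <- rand_matrix(4, c(3, 3, 2, 4), n_probes = 40)
  fit <- detect_markers(d$expr, d$groups)
  tab <- marker_table(fit)
  expect_true(all(tab$score > 0 & tab$score <= 1))

  perm <- sample(ncol(d$expr))
  tab2 <- marker_table(detect_markers(d$expr[, perm], d$groups[perm]))
  expect_setequal(paste(tab$probe_id, tab$marker_type, signif(tab$score, 12)),
                  paste(tab2$probe_id, tab2$marker_type, signif(tab2$score, 12)))

  x3 <- d$expr
  x3["p005", ] <- x3["p005", ] * 3.7
  tab3 <- marker_table(detect_markers(x3, d$groups))
  expect_equal(tab3[tab3$probe_id == "p005", c("score", "n_cut_points")],
               tab[tab$probe_id == "p005", c("score", "n_cut_points")],
               ignore_attr = TRUE)
})

test_that("filter_markers applies an inclusive cutoff and keeps rank order", {
  set.seed(8)
  d <- rand_matrix(3, 3, n_probes = 60, plant_frac = 0.6)
  fit <- detect_markers(d$expr, d$groups)
  tab <- marker_table(fit)
  expect_identical(marker_table(filter_markers(fit, 1)), tab)
  expect_equal(nrow(marker_table(filter_markers(fit, min(tab$score) / 2))), 0L)
  at_min <- marker_table(filter_markers(fit, min(tab$score)))
  expect_true(nrow(at_min) >= 1L)
  expect_true(all(at_min$score == min(tab$score)))
  for (t in unique(tab$marker_type))
    expect_false(is.unsorted(tab$score[tab$marker_type == t]))
  expect_error(filter_markers(fit, 0), "cutoff")
  expect_error(filter_markers(fit, 1.2), "cutoff")
})

test_that("the pooled-rest scoring variant uses all samples below the first cut", {
  fx <- fixture_profiles()$five_tissue
  tab <- marker_table(detect_markers(fx$expr, fx$groups, score_mode = "rest"))
  v <- sort(fx$expr[1, ], decreasing = TRUE)
  expect_equal(tab$score, mean(v[4:15]) / mean(v[1:3]))
})

test_that("inconsistent matrix/grouping sample sets are rejected with the discrepancy", {
  fx <- fixture_profiles()$five_tissue
  g <- fx$groups[-1]
  expect_error(detect_markers(fx$expr, g), "liver_1")
  expect_error(detect_markers(fx$expr[, -1, drop = FALSE], fx$groups),
               "liver_1")
})

test_that("accessor methods summarise the fit", {
  sim <- simulate_markers(n_background = 100, n_markers_per_type = 5, seed = 2)
  fit <- detect_markers(sim$expr, sim$groups)
  sc <- coef(fit)
  expect_type(sc, "double")
  expect_true(all(names(sc) %in% rownames(sim$expr)))
  s <- summary(fit)
  expect_equal(sum(s$per_type$n_markers), nrow(marker_table(fit)))
  expect_output(print(fit), "marker call")
  expect_output(print(s), "Marker calls per type")
  pdf(NULL)
  sweep <- plot(fit, cutoffs = c(0.5, 0.9, 1))
  dev.off()
  expect_false(is.unsorted(sweep$n_markers))
})
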