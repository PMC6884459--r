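test_that("class_tally reproduces the published percentages from the printed counts", {
  t <- class_tally(n_annotated = 17661, n_detected = 13518, n_tested = 8471,
                   n_up = 1397, n_down = 740)
  expect_identical(t$n_significant, 2137)
  expect_equal(t$pct_up_of_significant, 65.4)
  expect_equal(t$pct_down_of_significant, 34.6)
  expect_equal(t$pct_significant_of_tested, 25.2)
  expect_equal(t$pct_significant_of_annotated, 12.1)
  expect_equal(t$pct_up_of_significant + t$pct_down_of_significant, 100,
               tolerance = 0.1)
  expect_false(t$empty)
})

test_that("class_tally flags the degenerate zero-significant case and rejects non-nested counts", {
  t0 <- class_tally(100, 80, 50, 0, 0)
  expect_true(t0$empty)
  expect_equal(t0$pct_up_of_significant, 0)
  expect_equal(t0$pct_significant_of_tested, 0)
  expect_error(class_tally(100, 80, 90, 1, 0), class = "devdelay_value_error")
  expect_error(class_tally(100, 80, 50, 40, 20), class = "devdelay_value_error")
})

test_that("tally_expression_classes counts a DE table exactly as a record-by-record scan", {
  set.seed(60)
  status <- sample(c("not_detected", "detected_untested", "tested"), 50,
                   replace = TRUE, prob = c(0.2, 0.3, 0.5))
  direction <- ifelse(status == "tested",
                      sample(c("up", "down", "none"), 50, replace = TRUE),
                      "none")
  de <- de_records(sprintf("g%02d", 1:50), direction = direction,
                   status = status)
  t <- tally_expression_classes(de, n_annotated = 80)
  scan <- c(det = 0, tes = 0, up = 0, dn = 0)
  for (i in 1:50) {
    if (de$status[i] != "not_detected") scan["det"] <- scan["det"] + 1
    if (de$status[i] == "tested") scan["tes"] <- scan["tes"] + 1
    if (de$direction[i] == "up") scan["up"] <- scan["up"] + 1
    if (de$direction[i] == "down") scan["dn"] <- scan["dn"] + 1
  }
  expect_identical(c(t$n_detected, t$n_tested, t$n_up, t$n_down),
                   unname(as.integer(scan)))
  expect_error(tally_expression_classes(de, n_annotated = 10),
               class = "devdelay_value_error")
})

test_that("derepression_check intersects up-regulation with the reference silent set", {
  ref <- reference_12(rbind(matrix(0, 3, 12), matrix(1:9, 3, 12)),
                      ids = c("s1", "s2", "s3", "a1", "a2", "a3"))
  expect_identical(ref$silent_set, c("s1", "s2", "s3"))

  none_up <- de_records(c("a1", "s1"), direction = c("down", "none"))
  expect_identical(derepression_check(none_up, ref)$n_silent_upregulated, 0L)

  disjoint <- de_records(c("a1", "a2"), direction = "up")
  expect_identical(derepression_check(disjoint, ref)$n_silent_upregulated, 0L)

  overlap <- de_records(c("s1", "s2", "s3", "a1", "ghost"), direction = "up")
  res <- derepression_check(overlap, ref)
  expect_identical(res$n_silent_upregulated, 3L)
  expect_setequal(res$offending_gene_ids, c("s1", "s2", "s3"))
  expect_identical(res$no_reference_gene_ids, "ghost")
})

test_that("low_expression_dysregulated reproduces the published 21/2137 = 0.98%", {
  mean_control <- c(rep(1, 21), rep(50, 2137 - 21), rep(0.5, 10))
  direction <- c(rep("up", 2137), rep("none", 10))
  de <- de_records(sprintf("g%04d", seq_along(direction)),
                   direction = direction, mean_control = mean_control)
  res <- low_expression_dysregulated(de, fpkm_threshold = 3)
  expect_identical(res$count, 21L)
  expect_identical(res$n_significant, 2137L)
  expect_equal(res$pct_of_significant, 0.98)
  # threshold 0: nothing is below zero
  expect_identical(low_expression_dysregulated(de, 0)$count, 0L)
})

test_that("low-expression counts equal an independent filtered scan on random tables", {
  set.seed(61)
  de <- de_records(sprintf("g%03d", 1:200),
                   direction = sample(c("up", "down", "none"), 200, TRUE),
                   mean_control = rexp(200, 1 / 5))
  res <- low_expression_dysregulated(de, 3)
  manual <- sum(de$direction %in% c("up", "down") & de$mean_control < 3)
  expect_identical(res$count, as.integer(manual))
})

test_that("profile_summary medians equal the order-statistic definition", {
  ref <- tiny_reference()
  one <- profile_summary("early", ref)
  expect_equal(one$median_expression, unname(ref$values["early", ]))
  expect_identical(one$max_bin, "0-2")
  expect_identical(one$min_bin, "4-6")

  ordered <- reference_12(rbind(1:12, (1:12) + 5, (1:12) + 9),
                          ids = c("lo", "mid", "hi"))
  expect_equal(profile_summary(c("lo", "mid", "hi"), ordered)$median_expression,
               unname(ordered$values["mid", ]))

  set.seed(62)
  big <- reference_12(matrix(rexp(100 * 12), 100, 12))
  sel <- sample(big$gene_ids, 40)
  ps <- profile_summary(sel, big)
  manual <- vapply(1:12, function(j) {
    v <- sort(big$values[sel, j])
    (v[20] + v[21]) / 2
  }, 1)
  expect_equal(ps$median_expression, manual)

  expect_error(profile_summary(character(0), ref), class = "devdelay_value_error")
  expect_error(profile_summary(c("early", "nope"), ref), "nope",
               class = "devdelay_value_error")
})

test_that("the window rule classifies up/down genes with ties counting as unexplained", {
  vals <- rbind(c(rep(10, 3), rep(4, 3), rep(1, 6)),   # early high
                c(rep(4, 3), rep(4, 3), rep(1, 6)),    # tie
                c(rep(2, 3), rep(9, 3), rep(1, 6)))    # late high
  ref <- reference_12(vals, ids = c("hi_early", "tie", "hi_late"))
  de <- de_records(c("hi_early", "tie", "hi_late"), direction = "up")
  cl <- classify_delay_explainability(de, ref)
  expect_identical(cl$explained_by_delay, c(TRUE, FALSE, FALSE))
  expect_identical(attr(cl, "n_up_unexplained"), 2L)

  de_dn <- de_records(c("hi_early", "tie", "hi_late"), direction = "down")
  cl_dn <- classify_delay_explainability(de_dn, ref)
  expect_identical(cl_dn$explained_by_delay, c(FALSE, FALSE, TRUE))
  expect_identical(attr(cl_dn, "n_down_unexplained"), 2L)
})

test_that("window alignment and aggregate arguments are validated", {
  ref <- reference_12(matrix(1:24, 2, 12))
  de <- de_records(c("g1", "g2"), direction = "up")
  expect_error(classify_delay_explainability(de, ref, early_window = c(0, 5)),
               "aligned", class = "devdelay_value_error")
  expect_error(classify_delay_explainability(de, ref, aggregate = "median"))
  # max aggregation is available
  cl <- classify_delay_explainability(de, ref, aggregate = "max")
  expect_equal(cl$window_early_mean, unname(apply(ref$values[, 1:3], 1, max)))
})

test_that("classification partitions dysregulated genes once and is order-invariant", {
  cfg <- simulation_config(n_genes = 800, delay_hours = 2,
                           frac_direct_up = 0.03, frac_direct_down = 0.03,
                           seed = 63)
  sim <- simulate_embryo_experiment(cfg)
  de <- differential_expression(sim$control, sim$mutant)
  cl <- classify_delay_explainability(de, sim$reference)

  dys <- de$gene_id[de$direction != "none"]
  expect_setequal(cl$gene_id, intersect(dys, sim$reference$gene_ids))
  expect_identical(anyDuplicated(cl$gene_id), 0L)
  expect_lte(attr(cl, "n_up_unexplained"), sum(cl$direction == "up"))
  expect_lte(attr(cl, "n_down_unexplained"), sum(cl$direction == "down"))

  # independent gene-by-gene reapplication of the quoted rule
  for (i in seq_len(nrow(cl))) {
    g <- cl$gene_id[i]
    early <- mean(sim$reference$values[g, 1:3])
    late <- mean(sim$reference$values[g, 4:6])
    want <- if (cl$direction[i] == "up") early > late else early < late
    expect_identical(cl$explained_by_delay[i], want)
  }

  # invariance to DE record order and reference column order
  de_shuf <- de[sample(nrow(de)), ]
  perm <- sample(12)
  ref_shuf <- time_course(sim$reference$values[, perm],
                          gene_ids = sim$reference$gene_ids,
                          bin_starts = sim$reference$bins$start[perm],
                          bin_ends = sim$reference$bins$end[perm])
  cl2 <- classify_delay_explainability(de_shuf, ref_shuf)
  cl2 <- cl2[match(cl$gene_id, cl2$gene_id), ]
  expect_equal(cl$explained_by_delay, cl2$explained_by_delay)
  expect_equal(cl$window_early_mean, cl2$window_early_mean)
})

test_that("direct-effect genes under zero delay are flagged as not delay-explainable", {
  cfg <- simulation_config(n_genes = 1000, delay_hours = 0,
                           frac_direct_up = 0.025, frac_direct_down = 0.025,
                           seed = 64)
  sim <- simulate_embryo_experiment(cfg)
  de <- differential_expression(sim$control, sim$mutant)
  cl <- classify_delay_explainability(de, sim$reference)
  direct <- c(sim$truth$direct_up_genes, sim$truth$direct_down_genes)
  dsig <- cl[cl$gene_id %in% direct, ]
  expect_gt(nrow(dsig), 5)
  expect_gte(mean(!dsig$explained_by_delay), 0.8)
})

test_that("stage_assignment recovers a reference bin from its own column and rejects degenerate input", {
  set.seed(65)
  ref <- reference_12(matrix(rexp(50 * 12, 1 / 10), 50, 12))
  k <- 7L
  s <- stage_assignment(stats::setNames(ref$values[, k], ref$gene_ids), ref)
  expect_identical(s$best_bin, k)
  expect_identical(s$best_bin_label, ref$bins$label[k])
  expect_equal(unname(s$correlation_profile[k]), 1)

  expect_error(stage_assignment(stats::setNames(rep(1, 50), ref$gene_ids), ref),
               "degenerate", class = "devdelay_degenerate_error")
  expect_error(stage_assignment(stats::setNames(1:5, ref$gene_ids[1:5]), ref),
               class = "devdelay_value_error")
})

test_that("a 2 h delayed mutant stage-assigns one bin earlier than its control", {
  earlier <- 0
  for (seed in 1:10) {
    sim <- simulate_embryo_experiment(
      simulation_config(n_genes = 500, delay_hours = 2, seed = seed))
    de <- differential_expression(sim$control, sim$mutant)
    sc <- stage_assignment(stats::setNames(de$mean_control, de$gene_id),
                           sim$reference)
    sm <- stage_assignment(stats::setNames(de$mean_mutant, de$gene_id),
                           sim$reference)
    earlier <- earlier + (sc$best_bin - sm$best_bin == 1)
  }
  expect_gte(earlier, 9)
})
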