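# Cohort analyses: size bins, group summaries, overlaps, correlation and
# feature association.

test_that("default size bins are contiguous, 23 groups, anchored at 26 bp", {
  bins <- default_size_bins()
  expect_equal(nrow(bins), 23L)
  expect_equal(bins$lower[1], 26L)
  expect_equal(bins$upper[1], 32L)
  # first five groups cover 26-72 bp
  expect_equal(bins$upper[5], 72L)
  # one edge at 332 and a final open group beyond 1 kb
  expect_true(332L %in% bins$upper)
  expect_true(is.na(bins$upper[23]))
  expect_gt(bins$lower[23], 1000L)
  expect_true(all(bins$upper[-23] == bins$lower[-1] - 1L))
})

test_that("size-group assignment matches the printed anchors", {
  expect_equal(assign_size_group(28), 1L)
  expect_equal(assign_size_group(55), 4L)
  expect_equal(assign_size_group(1500), 23L)
  expect_equal(assign_size_group(c(26, 32, 33, 72, 73)),
               c(1L, 1L, 2L, 5L, 6L))
  expect_error(assign_size_group(20), "smallest bin edge")

  bad <- data.frame(lower = c(26L, 40L), upper = c(30L, 50L))
  expect_error(assign_size_group(28, bad), "contiguous")
})

make_records <- function(ids, rs, significant = rep(FALSE, length(ids))) {
  data.frame(ies_id = ids, rs = rs, significant = significant,
             stringsAsFactors = FALSE)
}

test_that("group summaries: quartiles, adjacent tests and stars", {
  set.seed(20)
  n <- 3000
  lengths <- data.frame(
    ies_id = sprintf("i%04d", 1:n),
    length = sample_ies_length(default_ies_length_distribution(), n))

  # null: every group from one distribution -> essentially no stars
  rs_null <- runif(n)
  s_null <- group_summaries(make_records(lengths$ies_id, rs_null), lengths)
  expect_equal(sum(s_null$n), n)
  expect_true(all(s_null$q1 <= s_null$median & s_null$median <= s_null$q3,
                  na.rm = TRUE))
  expect_lt(sum(s_null$stars != ""), 3)
  expect_true(all(s_null$stars != "**" & s_null$stars != "***"))

  # retention increasing with size: monotone medians over the first 5 groups
  r_len <- pmin(1, 0.1 + 0.002 * lengths$length)
  rs_size <- rbinom(n, 200, r_len) / 200
  s_size <- group_summaries(make_records(lengths$ies_id, rs_size), lengths)
  med5 <- s_size$median[1:5]
  expect_true(all(diff(med5) >= 0))
  expect_gt(med5[5], med5[1])
  expect_true(any(s_size$stars[2:5] != ""))

  # single populated group: no adjacent test anywhere
  one <- lengths[1:50, ]; one$length <- 28L
  s_one <- group_summaries(make_records(one$ies_id, runif(50)), one)
  expect_true(all(s_one$stars == ""))
  expect_equal(s_one$n[1], 50L)
  expect_true(all(s_one$n[-1] == 0L))
})

test_that("proportion significant per group is the plain ratio", {
  lengths <- data.frame(ies_id = c("a", "b", "c", "d"),
                        length = c(28L, 30L, 40L, 80L))
  rec_all <- make_records(lengths$ies_id, rep(0.5, 4), rep(TRUE, 4))
  p_all <- proportion_significant_by_group(rec_all, lengths)
  expect_true(all(p_all$proportion[p_all$n > 0] == 1))

  rec_none <- make_records(lengths$ies_id, rep(0.5, 4), rep(FALSE, 4))
  p_none <- proportion_significant_by_group(rec_none, lengths)
  expect_true(all(p_none$proportion[p_none$n > 0] == 0))

  rec_half <- make_records(lengths$ies_id, rep(0.5, 4),
                           c(TRUE, FALSE, TRUE, TRUE))
  p_half <- proportion_significant_by_group(rec_half, lengths)
  expect_equal(p_half$proportion[1], 0.5)  # a, b in group 1
})

test_that("overlap cells partition the union", {
  a_in_b <- overlap_sets(list(A = c("x", "y"), B = c("x", "y", "z")))
  cells <- a_in_b$cells
  expect_equal(cells$count[cells$cell == "A"], 0L)
  expect_equal(cells$count[cells$cell == "A&B"], 2L)
  expect_true(a_in_b$subsets$is_subset[a_in_b$subsets$a == "A"])

  disjoint <- overlap_sets(list(A = c("1", "2"), B = c("3", "4")))
  expect_equal(disjoint$cells$count[disjoint$cells$cell == "A&B"], 0L)
  expect_equal(sum(disjoint$cells$count), 4L)

  set.seed(21)
  universe <- sprintf("id%04d", 1:1000)
  sets <- list(P = sample(universe, 400), Q = sample(universe, 300),
               R = sample(universe, 500))
  ov <- overlap_sets(sets)
  expect_equal(sum(ov$cells$count),
               length(unique(unlist(sets))))
  expect_equal(nrow(ov$cells), 7L)
})

test_that("rank correlation handles ties and recovers replicates", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, rev(x))$rho, -1)
  expect_error(rank_correlation(1:2, 2:1), "at least 3")

  set.seed(22)
  a <- runif(200); b <- a + rnorm(200, sd = 0.3)
  ours <- rank_correlation(a, b)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_lt(ours$p, 1e-10)

  # two independent read samples of one truth table correlate strongly
  sim <- small_sim(seed = 81, n_ies = 40, contig_length = 30000L, depth = 25)
  set.seed(23)
  truth <- simulation_truth(sim$annotations,
                            retention = runif(nrow(sim$annotations)))
  rd1 <- simulate_reads(sim, truth, tempfile(), emit_sequences = FALSE,
                        seed = 101)
  rd2 <- simulate_reads(sim, truth, tempfile(), emit_sequences = FALSE,
                        seed = 202)
  c1 <- count_boundaries(rd1$paths$mac_sam, rd1$paths$mac_plus_ies_sam,
                         sim$annotations, sim$map)
  c2 <- count_boundaries(rd2$paths$mac_sam, rd2$paths$mac_plus_ies_sam,
                         sim$annotations, sim$map)
  rep_cor <- rank_correlation(retention_score(c1$ies_plus, c1$ies_minus),
                              retention_score(c2$ies_plus, c2$ies_minus))
  expect_gt(rep_cor$rho, 0.9)
})

test_that("feature comparison detects shifts and associations", {
  set.seed(24)
  null_cmp <- compare_feature(runif(300), runif(300), "continuous")
  expect_gt(null_cmp$p, 0.001)

  shifted <- compare_feature(runif(500) + 0.05, runif(500), "continuous")
  expect_lt(shifted$p, 0.01)
  expect_identical(shifted$direction, "higher")

  # 2x2 association: 90/10 vs 50/50, chi-square with closed-form oracle
  sig <- rep(c(TRUE, FALSE), c(90, 10))
  nsig <- rep(c(TRUE, FALSE), c(50, 50))
  res <- compare_feature(sig, nsig, "binary")
  tab <- rbind(c(90, 10), c(50, 50))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  expect_equal(res$p, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  expect_identical(res$direction, "higher")

  expect_error(compare_feature(numeric(0), runif(5)), "non-empty")
})

test_that("GC shift detection has power across seeds", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    res <- compare_feature(rnorm(500, 0.33, 0.05), rnorm(500, 0.28, 0.05),
                           "continuous")
    hits <- hits + (res$p < 0.01 && res$direction == "higher")
  }
  expect_gte(hits, 9L)
})
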