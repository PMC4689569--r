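test_that("group statistics reproduce the worked-example arithmetic", {
  # 148-member group, 54 down, 10 up
  calls <- make_calls(148, 54, 10)
  gs <- group_stats(calls$gene_id, calls)
  expect_equal(round(gs$percent_down, 1), 36.5)
  expect_equal(gs$du, 5.4)
  # 196-member group, 45 down, 10 up
  calls2 <- make_calls(196, 45, 10)
  gs2 <- group_stats(calls2$gene_id, calls2)
  expect_equal(gs2$du, 4.5)
  expect_equal(round(gs2$percent_down, 1), 23.0)
  # whole-proteome totals: 231 down, 95 up of 2408
  calls3 <- make_calls(2408, 231, 95)
  gs3 <- group_stats(calls3$gene_id, calls3)
  expect_equal(round(gs3$percent_down, 1), 9.6)
  expect_equal(round(gs3$du, 1), 2.4)
  # no regulated proteins at all: D/U flagged undefined
  calls4 <- make_calls(10, 0, 0)
  gs4 <- group_stats(calls4$gene_id, calls4)
  expect_equal(gs4$percent_down, 0)
  expect_false(gs4$du_defined)
  expect_true(is.na(gs4$du))
  expect_error(group_stats("missing", calls4), "DE call")
})

test_that("codon_group selects over-called genes in the quantified set", {
  usage <- data.frame(gene_id = c("a", "b", "c", "d"),
                      codon = "AGA",
                      call = c("over", "over", "none", "under"))
  expect_equal(codon_group(usage, "AGA"), c("a", "b"))
  expect_equal(codon_group(usage, "AGA", quantified = c("b", "c")), "b")
})

test_that("resampling null hits the degenerate limits", {
  # every pool protein down: all draws tie the observed 100%
  calls <- make_calls(30, 30, 0)
  members <- calls$gene_id[1:5]
  pool <- calls$gene_id[6:30]
  rs <- resample_null(members, pool, calls, "percent_down",
                      n_samplings = 200, seed = 1)
  expect_equal(rs$empirical_p, 1)
  # no down proteins in the pool, observed strictly positive
  calls2 <- rbind(make_calls(5, 5, 0, prefix = "m"),
                  make_calls(25, 0, 5, prefix = "q"))
  rs2 <- resample_null(calls2$gene_id[1:5], calls2$gene_id[6:30], calls2,
                       "percent_down", n_samplings = 200, seed = 1)
  expect_equal(rs2$empirical_p, 0)
  expect_error(resample_null(calls$gene_id[1:5], calls$gene_id[3:30],
                             calls, n_samplings = 10),
               "disjoint")
  expect_error(resample_null(calls$gene_id[1:10], calls$gene_id[11:15],
                             calls, n_samplings = 10),
               "smaller than group")
})

test_that("small-pool empirical p matches exhaustive subset enumeration", {
  calls <- rbind(make_calls(5, 4, 1, prefix = "m"),
                 make_calls(10, 3, 2, prefix = "q"))
  members <- calls$gene_id[1:5]
  pool <- calls$gene_id[6:15]
  obs <- group_stats(members, calls)$percent_down
  # brute force over all C(10,5) subsets of the pool
  down <- calls$call[match(pool, calls$gene_id)] == "down"
  subsets <- utils::combn(10, 5)
  exact_p <- mean(apply(subsets, 2, function(ix) {
    100 * sum(down[ix]) / 5 >= obs
  }))
  rs <- resample_null(members, pool, calls, "percent_down",
                      n_samplings = 4000, seed = 3)
  mc_se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(rs$empirical_p - exact_p), 3 * mc_se + 1e-9)
})

test_that("empirical p converges across sampling depths", {
  set.seed(9)
  calls <- make_calls(400, 60, 25)
  calls <- calls[sample.int(400), ]
  members <- calls$gene_id[1:60]
  pool <- setdiff(calls$gene_id, members)
  small <- resample_null(members, pool, calls, "percent_down",
                         n_samplings = 500, seed = 11)
  big <- resample_null(members, pool, calls, "percent_down",
                       n_samplings = 5000, seed = 12)
  p <- big$empirical_p
  se <- sqrt(p * (1 - p) / 500)
  expect_lt(abs(small$empirical_p - p), 3 * se + 1e-9)
  # reproducible given the seed
  again <- resample_null(members, pool, calls, "percent_down",
                         n_samplings = 500, seed = 11)
  expect_identical(small$empirical_p, again$empirical_p)
})

test_that("undefined D/U draws count as at least as extreme", {
  # pool with no up-regulated proteins: every draw has undefined D/U,
  # so the D/U empirical p is 1 whatever the observed group shows
  calls <- rbind(make_calls(4, 2, 2, prefix = "m"),
                 make_calls(20, 10, 0, prefix = "q"))
  rs <- resample_null(calls$gene_id[1:4], calls$gene_id[5:24], calls,
                      "du", n_samplings = 300, seed = 2)
  expect_true(all(is.infinite(rs$null_du)))
  expect_equal(rs$empirical_p_du, 1)
})

test_that("exclusion analysis recounts by hand on a 6-gene example", {
  calls <- data.frame(gene_id = paste0("g", 1:6),
                      call = c("down", "down", "up", "down",
                               "unchanged", "down"))
  groups <- list(AGA = c("g1", "g2", "g3", "g4"),
                 GAA = c("g3", "g4", "g5"))
  ex <- exclusion_analysis("AGA", "GAA", groups, calls)
  # AGA minus GAA leaves g1, g2: both down
  expect_equal(sort(ex$focal_minus_other$members), c("g1", "g2"))
  expect_equal(ex$focal_minus_other$stats$n_down, 2)
  expect_equal(ex$focal_minus_other$stats$percent_down, 100)
  # GAA minus AGA leaves g5 only: unchanged
  expect_equal(ex$other_minus_focal$members, "g5")
  expect_equal(ex$other_minus_focal$stats$n_down, 0)
  # disjoint groups: stats identical to the unfiltered group
  groups2 <- list(AGA = c("g1", "g2"), GAA = c("g5", "g6"))
  ex2 <- exclusion_analysis("AGA", "GAA", groups2, calls)
  expect_equal(ex2$focal_minus_other$stats,
               group_stats(groups2$AGA, calls))
  # complete overlap empties the focal side
  groups3 <- list(AGA = c("g1", "g2"), GAA = c("g1", "g2", "g3"))
  ex3 <- exclusion_analysis("AGA", "GAA", groups3, calls)
  expect_true(ex3$focal_minus_other$emptied)
  expect_null(ex3$focal_minus_other$stats)
  expect_error(exclusion_analysis("AGA", "AGA", groups, calls), "differ")
})

test_that("abundance matching degenerates to plain resampling when flat", {
  set.seed(15)
  calls <- make_calls(200, 40, 15)
  calls <- calls[sample.int(200), ]
  members <- calls$gene_id[1:30]
  pool <- setdiff(calls$gene_id, members)
  flat <- stats::setNames(rep(1, 200), calls$gene_id)
  # equal abundance: matched sampling draws from what is effectively one
  # pool, so the two nulls agree within Monte-Carlo error
  plain <- resample_null(members, pool, calls, "percent_down",
                         n_samplings = 3000, seed = 21)
  matched <- abundance_matched_null(members, pool, flat, calls,
                                    "percent_down", n_bins = 10,
                                    n_samplings = 3000, seed = 22)
  p <- plain$empirical_p
  se <- sqrt(max(p * (1 - p), 1e-4) / 3000)
  expect_lt(abs(matched$empirical_p - p), 4 * se + 0.02)
})

test_that("abundance matching preserves the bin histogram by construction", {
  # pool bins sized exactly like the group's: every draw is forced to the
  # same per-bin membership, so the null statistic is constant
  calls <- rbind(make_calls(4, 2, 1, prefix = "m"),
                 make_calls(4, 1, 2, prefix = "q"))
  members <- calls$gene_id[1:4]
  pool <- calls$gene_id[5:8]
  ab <- stats::setNames(c(1, 2, 3, 4, 1.1, 2.1, 3.1, 4.1), calls$gene_id)
  rs <- abundance_matched_null(members, pool, ab, calls, "percent_down",
                               n_bins = 4, n_samplings = 100, seed = 5)
  expect_equal(rs$bin_counts, rep(1L, 4))
  expect_length(unique(rs$null_percent_down), 1)
  # a bin the pool cannot fill is a named error
  ab2 <- stats::setNames(c(10, 11, 12, 13, 1, 1.1, 1.2, 1.3),
                         calls$gene_id)
  expect_error(abundance_matched_null(members, pool, ab2, calls,
                                      n_bins = 2, n_samplings = 10),
               "bin")
})

test_that("mRNA filter removes only same-direction significant changes", {
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      call = c("down", "down", "down", "unchanged"))
  mrna <- data.frame(gene_id = c("a", "b", "c", "d"),
                     log2fc = c(0.01, -1, 1, -1),
                     p = c(0.9, 0.001, 0.001, 0.001))
  mf <- mrna_filter(calls, mrna)
  expect_equal(mf$removed_ids, "b")        # down protein, down mRNA
  expect_true(all(c("a", "c", "d") %in% mf$calls$gene_id))
  expect_equal(mf$n_removed, 1)
  # genes missing from the mRNA table pass through
  mf2 <- mrna_filter(calls, mrna[mrna$gene_id == "b", ])
  expect_equal(mf2$n_removed, 1)
  expect_equal(nrow(mf2$calls), 3)
})

test_that("frequency bins are left-closed with an open last bin", {
  usage <- data.frame(gene_id = paste0("g", 1:5), codon = "AGA",
                      freq_per_1000 = c(9.99, 10, 15, 71, 200))
  calls <- data.frame(gene_id = paste0("g", 1:5),
                      call = c("down", "up", "down", "down", "up"))
  b <- bin_by_frequency(calls, usage, "AGA")
  expect_equal(b$n, c(1, 2, 0, 0, 0, 0, 2))
  expect_equal(b$bin[b$n > 0], c(1, 2, 7))  # 10.0 goes to the second bin
  expect_true(is.infinite(b$freq_hi[7]))
  # single populated bin when all frequencies are below one width
  usage2 <- data.frame(gene_id = paste0("g", 1:5), codon = "AGA",
                       freq_per_1000 = c(1, 2, 3, 4, 5))
  b2 <- bin_by_frequency(calls, usage2, "AGA")
  expect_equal(sum(b2$n > 0), 1)
})

test_that("a planted monotone effect shows up as a rising D/U trend", {
  set.seed(33)
  n <- 3000
  freq <- runif(n, 0, 70)
  p_down <- plogis(-2 + 0.06 * freq)
  u <- runif(n)
  call <- ifelse(u < p_down, "down", ifelse(u > 0.93, "up", "unchanged"))
  usage <- data.frame(gene_id = paste0("g", 1:n), codon = "AGA",
                      freq_per_1000 = freq)
  calls <- data.frame(gene_id = paste0("g", 1:n), call = call)
  b <- bin_by_frequency(calls, usage, "AGA")
  populated <- b[!is.na(b$du) & b$n >= 50, ]
  expect_gt(nrow(populated), 3)
  expect_gt(tail(populated$du, 1), head(populated$du, 1))
  expect_gt(cor(populated$bin, populated$du, method = "spearman"), 0.5)
})

test_that("rank correlation matches small-case oracles", {
  mono <- freq_change_correlation(c(1, 2, 3, 4), c(8, 6, 4, 2))
  expect_equal(mono$rho, -1)
  expect_equal(freq_change_correlation(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_error(freq_change_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(freq_change_correlation(c(1, 2), c(1, 2)), "at least 3")
  # independent vectors: negligible correlation at n = 1000
  set.seed(8)
  r <- freq_change_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(r$rho), 0.1)
})
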