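make_lib_with_peptides <- function(n_pass_per_protein, log2_pass = 3,
                                   log2_fail = 0) {
  # each protein gets the requested number of distinct passing peptides
  # plus one failing peptide
  set.seed(77)
  n <- length(n_pass_per_protein)
  lib <- proteome(sprintf("Q%02d", seq_len(n)),
                  vapply(rep(80, n), random_sequence, ""))
  rows <- list()
  for (i in seq_len(n)) {
    k <- n_pass_per_protein[i]
    starts <- seq(1, by = 8, length.out = k + 1)
    lr <- c(rep(log2_pass, k), log2_fail)
    rows[[i]] <- data.frame(
      sequence = substring(lib$sequence[i], starts, starts + 6),
      accession = lib$accession[i], start = starts,
      ratio_hl = 2^lr, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$end <- df$start + 6L
  df$log2_ratio <- log2(df$ratio_hl)
  seqs <- lib$sequence[match(df$accession, lib$accession)]
  df$preceding <- ifelse(df$start == 1, "-",
                         substring(seqs, df$start - 1, df$start - 1))
  df$following <- substring(seqs, df$end + 1, df$end + 1)
  list(lib = lib, table = quant_table(df))
}

test_that("fold changes convert to log2 ratios", {
  expect_equal(fold_to_log2(1), 0)
  expect_equal(fold_to_log2(5.85), log2(5.85))
  expect_gt(fold_to_log2(5.85), 1.8)   # PAK2 D148 peptide passes
  expect_gt(fold_to_log2(10.18), 1.8)  # BCAS2 peptide passes
  expect_error(fold_to_log2(0), "positive")
  expect_error(fold_to_log2(-2), "positive")
})

test_that("up-regulated fraction uses a strict cutoff", {
  lib <- proteome("P1", strrep("A", 40))
  tab <- toy_quant_table(lib, rep("AAAAAAA", 3), rep("P1", 3),
                         c(1L, 10L, 20L), 2^c(0.5, 1.5, 2.5))
  expect_equal(upregulated_fraction(tab, 1), 2 / 3)
  tab0 <- toy_quant_table(lib, "AAAAAAA", "P1", 1L, 1)
  expect_equal(upregulated_fraction(tab0, 1), 0)
  # boundary is strict: log2 exactly 1 does not count
  tab1 <- toy_quant_table(lib, "AAAAAAA", "P1", 1L, 2)
  expect_equal(upregulated_fraction(tab1, 1), 0)
  expect_error(upregulated_fraction(tab[0, ], 1), "empty")
})

test_that("dual-threshold calling counts distinct peptides and tiers calls", {
  fx <- make_lib_with_peptides(c(1, 2, 4, 5, 7))
  calls <- call_substrates(fx$table, log2_cutoff = 1.8, min_peptides = 2)
  expect_equal(calls$accession, c("Q02", "Q03", "Q04", "Q05"))
  expect_equal(calls$n_up_peptides, c(2L, 4L, 5L, 7L))
  expect_equal(calls$tier, c("warm", "warm", "hot", "hot"))
  expect_true(all(calls$n_up_peptides >= 2))
  # hot + warm partition all calls
  expect_equal(sum(calls$tier == "hot") + sum(calls$tier == "warm"),
               nrow(calls))
  # the ratio cutoff is inclusive
  fx18 <- make_lib_with_peptides(c(3, 3), log2_pass = 1.8)
  expect_equal(nrow(call_substrates(fx18$table)), 2L)
  # duplicate sequences collapse: same peptide at two ratios counts once
  lib <- proteome("P1", strrep("A", 40))
  dup <- toy_quant_table(lib, c("AAAAAAA", "AAAAAAA", "AAAAAAAA"),
                         rep("P1", 3), c(1L, 5L, 9L), c(8, 8, 8))
  expect_equal(call_substrates(dup)$n_up_peptides, 2L)
  expect_error(call_substrates(fx$table, min_peptides = 1), "at least 2")
})

test_that("known-substrate flags and supporting peptides are attached", {
  fx <- make_lib_with_peptides(c(2, 5, 3))
  calls <- call_substrates(fx$table, known = c("Q01", "Q02"))
  expect_equal(calls$is_known, c(TRUE, TRUE, FALSE))
  sup <- attr(calls, "peptides")
  expect_named(sup, calls$accession)
  expect_equal(vapply(sup, nrow, 1L), setNames(calls$n_up_peptides,
                                               calls$accession))
  expect_true(all(sup[["Q02"]]$log2_ratio >= 1.8))
})

test_that("raising either threshold never increases the number of calls", {
  set.seed(303)
  for (i in 1:20) {
    tab <- random_quant_table()
    n_prev <- Inf
    for (cut in c(0.5, 1, 1.8, 2.5, 3.5)) {
      n <- nrow(call_substrates(tab, log2_cutoff = cut))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    n_prev <- Inf
    for (m in 2:6) {
      n <- nrow(call_substrates(tab, min_peptides = m))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("known-percentage curves match hand counts and mark empty denominators", {
  fx <- make_lib_with_peptides(c(2, 2, 2, 2, 2))
  tab <- fx$table
  # 10 passing peptides; proteins Q01, Q02 known -> 4 of 10 peptides known
  curve <- known_percentage_by_ratio_cutoff(tab, c("Q01", "Q02"),
                                            cutoffs = c(1.8))
  expect_equal(curve$percent_known, 40)
  expect_equal(curve$n_denominator, 10L)
  expect_equal(attr(curve, "denominator_kind"), "peptides")

  all_known <- known_percentage_by_ratio_cutoff(tab, fx$lib$accession,
                                                cutoffs = c(0, 1, 1.8))
  expect_true(all(all_known$percent_known == 100))
  none_known <- known_percentage_by_ratio_cutoff(tab, character(),
                                                 cutoffs = c(0, 1.8))
  expect_true(all(none_known$percent_known == 0))
  expect_message(
    empty <- known_percentage_by_ratio_cutoff(tab, "Q01", cutoffs = 99),
    "empty denominator")
  expect_true(is.na(empty$percent_known))

  # protein-denominator curve: 4 proteins (2 known) at m = 2,
  # 2 proteins (1 known) at m = 5
  fx2 <- make_lib_with_peptides(c(2, 2, 5, 5))
  c2 <- known_percentage_by_count(fx2$table, c("Q01", "Q03"),
                                  count_minima = c(2, 5))
  expect_equal(c2$percent_known, c(50, 50))
  expect_equal(c2$n_denominator, c(4L, 2L))
  expect_equal(attr(c2, "denominator_kind"), "proteins")
  # m = 1 admits every protein with any passing peptide
  c1 <- known_percentage_by_count(fx2$table, character(), count_minima = 1)
  expect_equal(c1$n_denominator, 4L)
})

test_that("substrate recovery on the default simulation meets the design bar", {
  sim <- simulate_experiment(sim_params())
  calls <- call_substrates(sim$table, log2_cutoff = 1.8, min_peptides = 2)
  perf <- call_performance(calls, sim$truth)
  expect_gte(perf$precision, 0.9)
  expect_gte(perf$recall, 0.7)

  # halving the ratio noise cannot hurt either metric
  quiet <- simulate_experiment(sim_params(log2_bg_sd = 0.2,
                                          log2_sub_sd = 0.4))
  perf2 <- call_performance(call_substrates(quiet$table), quiet$truth)
  expect_gte(perf2$precision, perf$precision - 1e-9)
  expect_gte(perf2$recall, perf$recall - 1e-9)
})

test_that("upregulated fraction agrees with its closed-form mixture expectation", {
  sim <- simulate_experiment(sim_params())
  tab <- sim$table
  mu <- ifelse(tab$n_ctrl == 0, 3,
               ifelse(tab$n_trt == 0, -3, log2(tab$n_trt / tab$n_ctrl)))
  sd <- ifelse(tab$n_ctrl == 0 | tab$n_trt == 0, 0.8, 0.4)
  expected <- mean(stats::pnorm(1, mu, sd, lower.tail = FALSE))
  expect_lt(abs(upregulated_fraction(tab, 1) - expected), 0.05)
})
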