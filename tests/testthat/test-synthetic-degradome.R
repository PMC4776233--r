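test_that("proteome generation honours size, length distribution and seed", {
  expect_equal(nrow(generate_proteome(sim_params(n_proteins = 0))), 0L)

  p <- sim_params(n_proteins = 100, seed = 1)
  expect_identical(generate_proteome(p), generate_proteome(p))

  p <- sim_params(n_proteins = 500, length_mean = 400, length_sd = 120,
                  seed = 7)
  lens <- nchar(generate_proteome(p)$sequence)
  se <- 120 / sqrt(500)
  expect_lt(abs(mean(lens) - 400), 3 * se)
  expect_true(all(lens >= 50))
})

test_that("planted substrates carry the requested motifs at D positions", {
  lib <- generate_proteome(sim_params(n_proteins = 50, seed = 3))

  set.seed(11)
  none <- plant_substrates(lib, sim_params(substrate_fraction = 0))
  expect_length(none$truth$substrates, 0)
  expect_identical(none$proteome$sequence, lib$sequence)

  set.seed(12)
  all_devd <- plant_substrates(
    lib, sim_params(substrate_fraction = 1, motif_weights = c(DEVD = 1)))
  expect_setequal(all_devd$truth$substrates, lib$accession)
  sites <- all_devd$truth$sites
  seqs <- all_devd$proteome$sequence[match(sites$accession,
                                           all_devd$proteome$accession)]
  expect_true(all(substring(seqs, sites$position - 3, sites$position)
                  == "DEVD"))
  expect_true(all(substring(seqs, sites$position, sites$position) == "D"))
  expect_true(all(sites$position >= 1 &
                    sites$position <= nchar(seqs) - 1))
})

test_that("fragment release keeps exactly the attachment-free intervals", {
  # unattached protein, one cut: both halves released
  expect_equal(simulate_release(20, 10, integer()),
               data.frame(start = c(1L, 11L), end = c(10L, 20L)))
  # attachment at residue 1, no cuts: nothing released
  expect_equal(nrow(simulate_release(20, integer(), 1L)), 0L)
  # attachments {1, 30}, cuts {10, 20}: only the middle fragment escapes
  expect_equal(simulate_release(40, c(10, 20), c(1, 30)),
               data.frame(start = 11L, end = 20L))
})

test_that("release conservation holds on random cases", {
  set.seed(101)
  for (i in 1:100) {
    L <- sample(10:80, 1)
    cuts <- sample(seq_len(L - 1), sample(0:5, 1))
    att <- sample(seq_len(L), sample(0:4, 1))
    got <- simulate_release(L, cuts, att)
    # disjoint, inside [1, L], attachment-free
    if (nrow(got) > 1) expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    expect_true(all(got$start >= 1 & got$end <= L & got$start <= got$end))
    for (k in seq_len(nrow(got))) {
      expect_false(any(att >= got$start[k] & att <= got$end[k]))
    }
    # agrees with the brute-force partition oracle
    oracle <- brute_force_release(L, cuts, att)
    expect_equal(got$start, vapply(oracle, function(f) as.integer(f[1]), 1L))
    expect_equal(got$end, vapply(oracle, function(f) as.integer(f[2]), 1L))
  }
})

test_that("tryptic digestion follows the KR/P rule", {
  d0 <- digest_tryptic("AAKAA", max_missed = 0)
  expect_equal(d0$peptide, c("AAK", "AA"))
  expect_equal(d0$start_offset, c(1L, 4L))
  expect_equal(d0$nterm_edge, c(TRUE, FALSE))
  expect_equal(d0$cterm_edge, c(FALSE, TRUE))

  # proline blocks the cut
  expect_equal(digest_tryptic("AAKPAA", max_missed = 0)$peptide, "AAKPAA")

  d2 <- digest_tryptic("AKRAKA", max_missed = 2)
  expect_equal(sort(d2$peptide), brute_force_digest("AKRAKA", 2))
})

test_that("digestion equals brute-force enumeration on random sequences", {
  set.seed(202)
  for (i in 1:200) {
    seq <- random_sequence(sample(1:40, 1))
    mm <- sample(0:3, 1)
    got <- digest_tryptic(seq, mm)
    expect_equal(sort(got$peptide), brute_force_digest(seq, mm),
                 info = paste(seq, mm))
    # semi-tryptic consistency: every terminus is a fragment edge or a
    # KR-not-before-P boundary
    ch <- strsplit(seq, "")[[1]]
    ends <- got$start_offset + nchar(got$peptide) - 1L
    n_ok <- got$nterm_edge |
      (ch[pmax(got$start_offset - 1L, 1L)] %in% c("K", "R") &
         ch[got$start_offset] != "P")
    c_ok <- got$cterm_edge |
      (ch[ends] %in% c("K", "R") & ch[pmin(ends + 1L, nchar(seq))] != "P")
    expect_true(all(n_ok) && all(c_ok))
  }
})

test_that("the simulated experiment is seed-deterministic and degenerates correctly", {
  p <- sim_params(n_proteins = 40, seed = 9)
  a <- simulate_experiment(p)
  b <- simulate_experiment(p)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)

  # byte-identical on disk
  fa <- tempfile(); fb <- tempfile()
  write_quant_table(a$table, fa)
  write_quant_table(b$table, fb)
  expect_identical(readLines(fa), readLines(fb))

  empty <- simulate_experiment(sim_params(n_proteins = 20,
                                          substrate_fraction = 0,
                                          background_rate = 0,
                                          coupling_prob = 1,
                                          seed = 5))
  expect_equal(nrow(empty$table), 0L)
})

test_that("simulated peptides satisfy their invariants and ground-truth linkage", {
  sim <- simulate_experiment(sim_params(n_proteins = 60, seed = 4))
  tab <- sim$table
  seqs <- sim$proteome$sequence[match(tab$accession,
                                      sim$proteome$accession)]
  expect_true(all(substring(seqs, tab$start, tab$end) == tab$sequence))
  expect_true(all(nchar(tab$sequence) >= 7 & nchar(tab$sequence) <= 35))
  expect_true(all(abs(tab$log2_ratio - log2(tab$ratio_hl)) < 1e-9))
  expect_true(all(tab$log2_ratio <= 10 + 1e-12) &&
                all(tab$log2_ratio >= -10 - 1e-12))

  # every caspase-released peptide lies in a fragment bounded by a true cut:
  # its protein must be a planted substrate and a true site must fall in or
  # flank the peptide's parent fragment region
  flagged <- tab[tab$caspase_released, ]
  expect_true(all(flagged$accession %in% sim$truth$substrates))
  key <- paste(sim$truth$sites$accession, sim$truth$sites$position)
  # at minimum, each flagged peptide's protein has a true site
  expect_true(all(flagged$accession %in% sim$truth$sites$accession))
})

test_that("noiseless treated-only peptides take the substrate location exactly", {
  p <- sim_params(n_proteins = 30, cleavage_efficiency = 1,
                  log2_bg_sd = 0, log2_sub_sd = 0, log2_sub_mean = 3,
                  seed = 21)
  sim <- simulate_experiment(p)
  tab <- sim$table
  trt_only <- tab$n_ctrl == 0 & tab$n_trt > 0
  expect_gt(sum(trt_only), 0)
  expect_true(all(abs(tab$log2_ratio[trt_only] - 3) < 1e-12))
  both <- tab$n_ctrl > 0 & tab$n_trt > 0
  expect_true(all(abs(tab$log2_ratio[both] -
                        log2(tab$n_trt[both] / tab$n_ctrl[both])) < 1e-12))
})

test_that("ground truth survives a disk round trip", {
  sim <- simulate_experiment(sim_params(n_proteins = 30, seed = 2))
  dir <- tempfile()
  write_ground_truth(sim$truth, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$substrates, sim$truth$substrates)
  expect_equal(back$sites$accession, sim$truth$sites$accession)
  expect_equal(back$sites$position, sim$truth$sites$position)
})
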