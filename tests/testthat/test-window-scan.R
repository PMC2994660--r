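test_that("window enumeration arithmetic matches the sliding rule", {
  sim <- simulate_codon_alignment(sensu_stricto_tree(), 300, seed = 401)
  win <- enumerate_windows(sim$alignment)   # 900 nt, gap-free
  expect_equal(nrow(win), (900 - 102) / 3 + 1)  # 267
  expect_true(all(win$gap_free))
  expect_equal(win$end - win$start, rep(102, 267))
  expect_equal(attr(win, "n_excluded"), 0L)

  # alignment length equal to the window size: exactly one window
  sim34 <- simulate_codon_alignment(sensu_stricto_tree(), 34, seed = 402)
  expect_equal(nrow(enumerate_windows(sim34$alignment)), 1L)

  # window larger than the alignment: empty with a warning
  expect_warning(w0 <- enumerate_windows(sim34$alignment, window_size = 204),
                 "exceeds alignment length")
  expect_equal(nrow(w0), 0L)
  expect_error(enumerate_windows(sim34$alignment, window_size = 100),
               "divisible by 3")
})

test_that("a single gapped codon removes exactly the overlapping windows", {
  set.seed(403)
  aln <- random_alignment(5, 300)   # 900 nt
  # gap codon column at nucleotides [450, 453): codon column 151
  aln$codon[2, 151] <- "---"; aln$gap[2, 151] <- TRUE
  aln$idx[2, 151] <- NA_integer_
  win <- enumerate_windows(aln)
  excluded <- win$start[!win$gap_free]
  # windows [s, s+102) overlapping nucleotide interval [450, 453)
  expect_equal(excluded, seq(351, 450, by = 3))
  expect_equal(win$gap_free, oracle_gap_free(aln, 102, 3))
})

test_that("gap-exclusion agrees with the brute-force oracle on random data", {
  set.seed(404)
  for (i in 1:20) {
    aln <- random_alignment(4, sample(40:120, 1),
                            gap_codons = sample(0:6, 1))
    step <- sample(c(3, 6, 9), 1)
    win <- enumerate_windows(aln, window_size = 51, step = step)
    expect_equal(win$gap_free, oracle_gap_free(aln, 51, step))
    expect_equal(attr(win, "n_excluded"), sum(!win$gap_free))
  }
})

test_that("scan summary statistics are recomputable from the windows", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 60, omega = 0.4, seed = 405)
  scan <- scan_omega(sim$alignment, tr)
  om <- scan$windows$omega[!is.na(scan$windows$omega)]
  expect_equal(scan$summary$median_omega, median(om))
  expect_equal(scan$summary$frac_gt1, mean(om > 1))
  expect_equal(scan$summary$n_windows, length(om))

  rep <- summarize_scan(scan)
  expect_equal(rep$scan_median, median(om))
  expect_equal(nrow(rep$plot_table), length(om))
})

test_that("the empirical null is seeded, deterministic and order-statistic based", {
  tr <- sensu_stricto_tree()
  genes <- simulate_null_gene_set(3, 60, omega_background = 0.1, tr,
                                  seed = 406)
  n1 <- build_empirical_null(genes, tr, n_windows = 25, seed = 9)
  n2 <- build_empirical_null(genes, tr, n_windows = 25, seed = 9)
  expect_identical(n1$omega, n2$omega)
  expect_equal(n1$n, 25L)
  so <- sort(n1$omega)
  expect_equal(unname(n1$ci["lower"]), so[ceiling(0.025 * 25)])
  expect_equal(unname(n1$ci["upper"]), so[ceiling(0.975 * 25)])
  expect_equal(n1$median, median(n1$omega))
  expect_false(is.unsorted(n1$ci))

  # asking for the whole pool is the identity sample
  pool_size <- sum(vapply(genes, function(g)
    sum(enumerate_windows(g)$gap_free), numeric(1)))
  expect_warning(nall <- build_empirical_null(genes, tr,
                                              n_windows = pool_size + 50,
                                              seed = 1),
                 "using all")
  expect_equal(nall$n, pool_size)
})

test_that("scan plus null plus posteriors summarize into one report", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 60, omega = 0.4, seed = 407)
  scan <- scan_omega(sim$alignment, tr)
  genes <- simulate_null_gene_set(2, 50, 0.1, tr, seed = 408)
  null <- build_empirical_null(genes, tr, n_windows = 20, seed = 2)
  beb_like <- data.frame(site = 1:60,
                         pp_positive = c(rep(0.1, 58), 0.8, 0.9),
                         post_mean_omega = 0.5,
                         flagged = c(rep(FALSE, 58), TRUE, TRUE))
  rep <- summarize_scan(scan, null, beb_like)
  expect_equal(rep$null_median, null$median)
  expect_equal(rep$flagged_codons$codon, c(59, 60))
  expect_equal(rep$flagged_codons$nuc_midpoint, c(175.5, 178.5))
  expect_true(rep$frac_above_null_upper >= 0 &&
                rep$frac_above_null_upper <= 1)
})
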