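test_that("fragment coverage counts membership per base", {
  tracks <- coverage_from_fragments(
    data.frame(contig = "c1", start = 2, end = 5), c(c1 = 8))
  expect_equal(tracks$c1$counts, c(0, 0, 1, 1, 1, 0, 0, 0))
  # additivity of identical fragments
  t2 <- coverage_from_fragments(
    data.frame(contig = "c1", start = c(2, 2), end = c(5, 5)), c(c1 = 8))
  expect_equal(t2$c1$counts, 2 * tracks$c1$counts)
  expect_error(coverage_from_fragments(
    data.frame(contig = "c1", start = 5, end = 12), c(c1 = 8)),
    "out-of-bounds")
})

test_that("fragment coverage matches brute force and conserves mass", {
  set.seed(601)
  len <- 400
  fr <- data.frame(contig = "c1",
                   start = sample(0:(len - 30), 100, replace = TRUE))
  fr$end <- fr$start + sample(10:30, 100, replace = TRUE)
  cov <- coverage_from_fragments(fr, c(c1 = len))$c1$counts
  oracle <- vapply(0:(len - 1), function(b)
    sum(fr$start <= b & b < fr$end), numeric(1))
  expect_equal(cov, oracle)
  expect_equal(sum(cov), sum(fr$end - fr$start))
})

test_that("window medians follow the fixed grid and the even-count rule", {
  const <- coverage_track("c1", rep(7, 240))
  wm <- window_medians(const)
  expect_equal(wm$median, rep(7, nrow(wm)))
  # length 250: starts 0, 50, 100, 150 (end 250 fits exactly)
  wm250 <- window_medians(coverage_track("c1", rep(1, 250)))
  expect_equal(wm250$start, c(0, 50, 100, 150))
  expect_equal(wm250$end, c(100, 150, 200, 250))
  # shorter than one window: empty track with a warning
  expect_warning(w0 <- window_medians(coverage_track("c1", rep(1, 50))),
                 "shorter than window")
  expect_equal(nrow(w0), 0L)
  # random track against a sort-and-pick oracle
  set.seed(602)
  tr <- coverage_track("c1", rpois(530, 9))
  wm2 <- window_medians(tr)
  for (i in seq_len(nrow(wm2))) {
    v <- sort(tr$counts[(wm2$start[i] + 1):wm2$end[i]])
    expect_equal(wm2$median[i], (v[50] + v[51]) / 2)
  }
  # monotone in the counts, invariant to add-then-subtract
  tr_up <- coverage_track("c1", tr$counts + 3)
  expect_equal(window_medians(tr_up)$median, wm2$median + 3)
  expect_true(all(window_medians(tr_up)$median >= wm2$median))
})

test_that("per-base ratios mask zero-input bases", {
  ip <- coverage_track("c1", rep(20, 10))
  input <- coverage_track("c1", c(rep(10, 9), 0))
  r <- per_base_ratio(ip, input)
  expect_equal(unname(r[1:9]), rep(2, 9))
  expect_true(is.na(r[10]))
  expect_equal(attr(r, "masked_fraction"), 0.1)
  expect_error(per_base_ratio(ip, coverage_track("c2", rep(1, 10))),
               "different contigs")
  expect_error(per_base_ratio(ip, coverage_track("c1", rep(1, 5))),
               "length mismatch")
})

test_that("uniform tracks give depth-ratio means and unit normalization", {
  ip <- coverage_track("c1", rep(12, 3000))
  input <- coverage_track("c1", rep(30, 3000))
  wi <- window_medians(ip); wn <- window_medians(input)
  regions <- data.frame(contig = "c1",
                        start = c(300, 1500), end = c(900, 2100),
                        label = c("query", "ctrl"))
  enr <- region_enrichment(wi, wn, regions, control = "ctrl")
  expect_equal(enr$mean_ratio, rep(12 / 30, 2))
  expect_equal(enr$normalized, rep(1, 2))
  expect_true(enr$is_control[2])
  # control against itself is exactly 1 whatever the data
  set.seed(603)
  ip2 <- coverage_track("c1", rpois(3000, 8))
  wi2 <- window_medians(ip2)
  enr2 <- region_enrichment(wi2, wn, regions, control = "ctrl")
  expect_equal(enr2$normalized[enr2$is_control], 1)
})

test_that("normalized enrichment is invariant to global depth rescaling", {
  set.seed(604)
  sim <- simulate_chip_experiment(
    c(chr = 6000),
    regions = data.frame(contig = "chr", start = 1000, end = 1600,
                         fold = 8),
    input_depth = 30, ip_depth = 10, seed = 11)
  regions <- data.frame(contig = "chr",
                        start = c(1000, 4000), end = c(1600, 4600),
                        label = c("silencer", "ctrl"))
  wi <- window_medians(sim$ip$chr); wn <- window_medians(sim$input$chr)
  enr <- region_enrichment(wi, wn, regions, control = "ctrl")
  scaled_ip <- coverage_track("chr", sim$ip$chr$counts * 3)
  scaled_in <- coverage_track("chr", sim$input$chr$counts * 3)
  enr2 <- region_enrichment(window_medians(scaled_ip),
                            window_medians(scaled_in),
                            regions, control = "ctrl")
  expect_equal(enr2$normalized, enr$normalized, tolerance = 1e-12)
})

test_that("window correlations behave at the exact and degenerate limits", {
  set.seed(605)
  tr <- coverage_track("c1", rpois(2000, 20))
  wm <- window_medians(tr)
  expect_equal(window_correlation(wm, wm), 1)
  neg <- wm; neg$median <- 2 * mean(wm$median) - wm$median
  attr(neg, "contig") <- "c1"
  expect_equal(window_correlation(wm, neg), -1)
  flat <- window_medians(coverage_track("c1", rep(5, 2000)))
  expect_error(window_correlation(wm, flat), "zero variance")
})

test_that("replicate experiments at depth correlate strongly", {
  reg <- data.frame(contig = "chr", start = 2000, end = 2600, fold = 10)
  a <- simulate_chip_experiment(c(chr = 20000), reg, input_depth = 25,
                                ip_depth = 10, seed = 21)
  b <- simulate_chip_experiment(c(chr = 20000), reg, input_depth = 25,
                                ip_depth = 10, seed = 22)
  r_in <- window_correlation(window_medians(a$input$chr),
                             window_medians(b$input$chr))
  r_ip <- window_correlation(window_medians(a$ip$chr),
                             window_medians(b$ip$chr))
  # input replicates share no structure beyond noise around a flat mean,
  # IP replicates share the planted region
  expect_gt(r_ip, 0.5)
  expect_true(abs(r_in) < 0.2)
})

test_that("bedGraph round-trip and hybrid genome concatenation", {
  tr <- list(c1 = coverage_track("c1", c(0, 0, 3, 3, 1, 0)),
             c2 = coverage_track("c2", c(5, 5, 5, 2)))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, c(c1 = 6, c2 = 4))
  expect_equal(back$c1$counts, tr$c1$counts)
  expect_equal(back$c2$counts, tr$c2$counts)

  fa_a <- withr::local_tempfile(fileext = ".fasta")
  fa_b <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chrI", "ACGTACGT", ">chrII", "GGCC"), fa_a)
  writeLines(c(">contig1", "TTTT", ">chrI", "AAAA", ">x", "CC"), fa_b)
  out <- withr::local_tempfile(fileext = ".fasta")
  manifest <- concat_hybrid_genome(fa_a, fa_b, "Sc_", "Sb_", out)
  hyb <- Biostrings::readBStringSet(out)
  expect_equal(length(hyb), 5L)
  expect_equal(names(hyb)[1:2], c("Sc_chrI", "Sc_chrII"))
  expect_equal(manifest$source, c("A", "A", "B", "B", "B"))
  expect_setequal(manifest$contig[manifest$source == "B"],
                  c("Sb_contig1", "Sb_chrI", "Sb_x"))
  # empty second genome: output identical to prefixed genome A
  fa_e <- withr::local_tempfile(fileext = ".fasta")
  file.create(fa_e)
  out2 <- withr::local_tempfile(fileext = ".fasta")
  m2 <- concat_hybrid_genome(fa_a, fa_e, "Sc_", "Sb_", out2)
  expect_equal(nrow(m2), 2L)
  expect_equal(as.character(Biostrings::readBStringSet(out2)),
               as.character(hyb[1:2]), ignore_attr = TRUE)
})
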