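test_that("simulators are deterministic under a fixed seed", {
  tr <- sensu_stricto_tree()
  a <- simulate_codon_alignment(tr, 50, seed = 701)
  b <- simulate_codon_alignment(tr, 50, seed = 701)
  c <- simulate_codon_alignment(tr, 50, seed = 702)
  expect_identical(a$alignment$codon, b$alignment$codon)
  expect_false(identical(a$alignment$codon, c$alignment$codon))
  expect_identical(a$truth, b$truth)

  x <- simulate_chip_experiment(c(c1 = 500), seed = 703)
  y <- simulate_chip_experiment(c(c1 = 500), seed = 703)
  expect_identical(x$ip$c1$counts, y$ip$c1$counts)
  expect_identical(x$input$c1$counts, y$input$c1$counts)

  g1 <- simulate_null_gene_set(2, 40, 0.1, tr, seed = 704)
  g2 <- simulate_null_gene_set(2, 40, 0.1, tr, seed = 704)
  expect_identical(g1$gene001$codon, g2$gene001$codon)
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_codon_alignment(tr, 5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("zero branch lengths copy the root sequence to every tip", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0,(d:0,e:0):0);")
  sim <- simulate_codon_alignment(tr, 30, seed = 705)
  for (i in 2:5)
    expect_identical(sim$alignment$codon[i, ], sim$alignment$codon[1, ])
})

test_that("omega zero forbids nonsynonymous change", {
  sim <- simulate_codon_alignment(sensu_stricto_tree(), 200, omega = 0,
                                  seed = 706)
  aa <- apply(sim$alignment$codon, 2, function(cc)
    length(unique(translate_codons(cc))))
  expect_true(all(aa == 1))
})

test_that("long simulations converge to the equilibrium frequencies", {
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  sim <- simulate_codon_alignment(tr, 50000, omega = 0.5, seed = 707)
  emp <- tabulate(sim$alignment$idx, 61) / (2 * 50000)
  tv <- 0.5 * sum(abs(emp - rep(1 / 61, 61)))
  expect_lt(tv, 0.02)
})

test_that("pairwise divergence grows linearly at small distances", {
  diffs <- vapply(c(0.02, 0.05, 0.08), function(t) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    sim <- simulate_codon_alignment(tr, 20000, omega = 0.5,
                                    seed = 708 + round(1000 * t))
    mean(sim$alignment$codon[1, ] != sim$alignment$codon[2, ])
  }, numeric(1))
  slope <- coef(lm(diffs ~ 0 + c(0.02, 0.05, 0.08)))[[1]]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("mixture truth tables record the generating class per site", {
  sim <- simulate_codon_alignment(sensu_stricto_tree(), 500, model = "M8",
                                  p0 = 0.9, omega_s = 5, seed = 709)
  expect_equal(nrow(sim$truth), 500)
  sel <- sim$truth$class == "selected"
  expect_true(all(sim$truth$omega[sel] == 5))
  expect_true(all(sim$truth$omega[!sel] <= 1))
  expect_gt(mean(sel), 0.05); expect_lt(mean(sel), 0.16)
  # selected sites evolve faster under common mixture scaling
  ndiff <- apply(sim$alignment$codon, 2, function(cc)
    length(unique(cc)))
  expect_gt(mean(ndiff[sel]), mean(ndiff[!sel]))
})

test_that("planted ChIP folds shape the IP mean but not the input", {
  reg <- data.frame(contig = "c1", start = 100, end = 700, fold = 14)
  sim <- simulate_chip_experiment(c(c1 = 5000), reg, input_depth = 30,
                                  ip_depth = 10, noise = "poisson",
                                  seed = 710)
  inside <- 101:700
  expect_gt(mean(sim$ip$c1$counts[inside]), 10 * 14 * 0.9)
  expect_lt(abs(mean(sim$ip$c1$counts[-inside]) - 10), 1)
  expect_lt(abs(mean(sim$input$c1$counts) - 30), 1)
  # per-base ratio recovers fold x depth ratio within 10%
  r <- per_base_ratio(sim$ip$c1, sim$input$c1)
  expect_lt(abs(mean(r[inside], na.rm = TRUE) - 14 * (10 / 30)) /
              (14 * (10 / 30)), 0.1)
})
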