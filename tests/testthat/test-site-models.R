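test_that("beta discretization matches numerical quadrature", {
  for (pq in list(c(0.5, 2), c(1, 1), c(2, 5), c(0.2, 0.3))) {
    p <- pq[1]; q <- pq[2]; K <- 10
    m <- discretize_beta(p, q, K)
    br <- qbeta(seq(0, 1, length.out = K + 1), p, q)
    oracle <- vapply(seq_len(K), function(k)
      stats::integrate(function(x) x * dbeta(x, p, q), br[k], br[k + 1],
                       rel.tol = 1e-10)$value * K, numeric(1))
    expect_equal(m, oracle, tolerance = 1e-6)
    expect_true(all(m >= 0 & m <= 1))
    expect_false(is.unsorted(m))
  }
  # K = 1 is the full beta mean
  expect_equal(discretize_beta(0.5, 2, 1), 0.2, tolerance = 1e-9)
})

test_that("M7 with one class degenerates to the single-ratio model", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 150, omega = 0.25, seed = 201)
  f7 <- fit_m7(sim$alignment, tr, K = 1, engine = "exact")
  m <- f7$mixture$p / (f7$mixture$p + f7$mixture$q)
  expect_equal(codon_loglik(sim$alignment, tr, f7$kappa, m),
               f7$lnL, tolerance = 1e-5)
})

test_that("model nesting orders the maximized likelihoods", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 300, model = "M7", p = 0.5, q = 2,
                                  seed = 202)
  aln <- sim$alignment
  m0 <- fit_m0(aln, tr, optimize_branch_lengths = FALSE,
               starts = list(c(2, 0.4)))
  g <- site_loglik_grid(aln, tr, kappa = m0$kappa)
  f7 <- fit_m7(aln, tr, engine = "grid", grid = g)
  f8 <- fit_m8(aln, tr, engine = "grid", grid = g, m7_fit = f7)
  expect_gte(f8$lnL, f7$lnL - 0.05)

  # a beta can concentrate near the M0 estimate, so M7 cannot do much
  # worse than M0 when the single ratio is below 1 (exact engine)
  f7e <- fit_m7(aln, tr, engine = "exact")
  expect_gte(f7e$lnL, m0$lnL - 0.5)
})

test_that("the M7-vs-M8 test has the stated closed form", {
  fake <- function(model, lnL) structure(
    list(model = model, lnL = lnL, n_sites = 100L, taxa = c("a", "b")),
    class = "codon_fit")
  eq <- lrt_m7_m8(fake("M7", -500), fake("M8", -500))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # chi-squared with 2 df: p = exp(-x / 2)
  lr <- lrt_m7_m8(fake("M7", -500), fake("M8", -500 + 15.2 / 2))
  expect_equal(lr$statistic, 15.2)
  expect_equal(lr$p_value, exp(-15.2 / 2), tolerance = 1e-12)
  expect_equal(lr$p_value, 5.0e-4, tolerance = 0.01)
  # nesting means a negative difference is clipped to zero
  neg <- lrt_m7_m8(fake("M7", -500), fake("M8", -500.2))
  expect_equal(neg$statistic, 0)
  expect_error(lrt_m7_m8(fake("M7", -1),
                         structure(list(model = "M8", lnL = -1,
                                        n_sites = 50L, taxa = c("a", "b")),
                                   class = "codon_fit")),
               "different alignments")
})

test_that("M8 recovers a planted selected class", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 1500, model = "M8", p = 0.5, q = 2,
                                  p0 = 0.9, omega_s = 3, seed = 203)
  aln <- sim$alignment
  m0 <- fit_m0(aln, tr, optimize_branch_lengths = FALSE,
               starts = list(c(2, 0.4)))
  g <- site_loglik_grid(aln, tr, kappa = m0$kappa)
  f7 <- fit_m7(aln, tr, engine = "grid", grid = g)
  f8 <- fit_m8(aln, tr, engine = "grid", grid = g, m7_fit = f7)
  expect_gt(f8$mixture$omega_s, 2)
  expect_lt(f8$mixture$omega_s, 4.5)
  expect_gt(f8$mixture$p0, 0.85)
  expect_lt(f8$mixture$p0, 0.95)
})

test_that("M7 fits recover beta shape parameters", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 1500, model = "M7", p = 0.5, q = 2,
                                  seed = 204)
  aln <- sim$alignment
  f7 <- fit_m7(aln, tr, engine = "grid")
  expect_lt(abs(f7$mixture$p - 0.5) / 0.5, 0.3)
  expect_lt(abs(f7$mixture$q - 2) / 2, 0.3)
})

test_that("BEB posteriors are probabilities and stay low without signal", {
  tr <- sensu_stricto_tree()
  aln <- codon_alignment(setNames(rep(strrep("ATGGCTAAATTTCCG", 4), 5),
                                  tr$tip.label))
  g <- site_loglik_grid(aln, tr, kappa = 2)
  f8 <- fit_m8(aln, tr, engine = "grid", grid = g)
  beb <- beb_site_posteriors(aln, tr, f8)
  expect_true(all(beb$pp_positive >= 0 & beb$pp_positive <= 1))
  expect_true(all(beb$pp_positive < 0.75))
  expect_false(any(beb$flagged))
  expect_equal(nrow(beb), aln$n_sites)
})

test_that("BEB maps flagged codons to reference coordinates", {
  tr <- sensu_stricto_tree()
  sim <- simulate_codon_alignment(tr, 120, model = "M8", p0 = 0.9,
                                  omega_s = 5, seed = 205)
  aln <- sim$alignment
  # give the reference taxon a gap at codon 2
  ri <- match("Scer", aln$taxa)
  aln$codon[ri, 2] <- "---"
  aln$gap[ri, 2] <- TRUE
  aln$idx[ri, 2] <- NA_integer_
  g <- site_loglik_grid(aln, tr, kappa = 2)
  f8 <- fit_m8(aln, tr, engine = "grid", grid = g)
  beb <- beb_site_posteriors(aln, tr, f8, reference = "Scer")
  expect_true(is.na(beb$ref_pos[2]))
  expect_equal(beb$ref_pos[1], 1)
  expect_equal(beb$ref_pos[3], 2)
  expect_equal(beb$ref_pos[120], 119)
})
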