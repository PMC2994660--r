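# Site-mixture models M7 (beta) and M8 (beta & omega_s), their LRT, and
# Bayes Empirical Bayes per-codon posteriors.

#' Equal-probability discretization of a beta distribution
#'
#' Splits Beta(p, q) into `K` classes of equal probability 1/K and returns
#' the mean of each quantile slice (the class representative used by the
#' discrete site-mixture likelihood).
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of classes.
#' @return Numeric vector of `K` class means in `[0, 1]`.
#' @export
discretize_beta <- function(p, q, K) {
  stopifnot(p > 0, q > 0, K >= 1)
  # qbeta warns about reduced accuracy for very extreme shapes explored
  # during optimization; the clamped class means remain usable there
  br <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = K + 1), p, q))
  # mean over a slice: K * p/(p+q) * [I_b(p+1,q) - I_a(p+1,q)]
  cdf1 <- stats::pbeta(br, p + 1, q)
  m <- K * (p / (p + q)) * diff(cdf1)
  pmin(pmax(m, 0), 1)
}

# mixture log-likelihood given npat x K category likelihood matrix
.mix_loglik <- function(Lmat, weights, w_pat) {
  mix <- as.vector(Lmat %*% weights)
  sum(w_pat * log(pmax(mix, 1e-300)))
}

# exact npat x K site-likelihood matrix for a set of omega categories under
# common mixture scaling: category k multiplies branch lengths by u[k]
.cat_lik_exact <- function(pd, pt, el, kappa, omegas, pi,
                           u = rep(1, length(omegas))) {
  out <- matrix(NA_real_, ncol(pd$pat), length(omegas))
  for (k in seq_along(omegas)) {
    eig <- .codon_eig(kappa, omegas[k], pi)
    Plist <- lapply(el * u[k], .pmat, eig = eig)
    out[, k] <- .site_lik(pd$pat, pt, Plist, pi)
  }
  out
}

.prepare_site_fit <- function(aln, tree, pi) {
  .check_tree(tree, aln$taxa)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  list(pt = .prep_tree(tree), pd = .pattern_data(aln, tree),
       pi = pi / sum(pi))
}

#' Fit the M7 (beta) site-mixture codon model
#'
#' Site dN/dS follows a Beta(p, q) on (0, 1), discretized into `K`
#' equal-probability classes. With `engine = "exact"` the class conditional
#' likelihoods are recomputed by pruning at every optimizer step and kappa
#' is co-estimated. With `engine = "grid"` the fit interpolates class
#' likelihoods off a precomputed [site_loglik_grid()] (kappa and branch
#' lengths fixed at the grid's values) - orders of magnitude faster, meant
#' for replicated simulation studies.
#'
#' @inheritParams fit_m0
#' @param K Number of beta classes (10, the conventional default).
#' @param engine `"exact"` or `"grid"`.
#' @param grid A `site_lik_grid` (required for `engine = "grid"`; if
#'   missing, one is built using `kappa`).
#' @param kappa Fixed kappa for the grid engine; defaults to a quick M0
#'   estimate with branch lengths held at the tree's values.
#' @param optimize_branch_lengths Exact engine only: co-estimate branch
#'   lengths (slow; default `FALSE`, which keeps the supplied tree's
#'   lengths - conventionally those of a whole-gene M0 fit).
#' @return A `codon_fit` with `model = "M7"` and a `mixture` element
#'   holding `p`, `q`, `K` and the class means.
#' @export
fit_m7 <- function(aln, tree, K = 10, engine = c("exact", "grid"),
                   grid = NULL, kappa = NULL, pi = NULL,
                   optimize_branch_lengths = FALSE, control = list()) {
  engine <- match.arg(engine)
  stopifnot(inherits(aln, "codon_alignment"))
  wK <- rep(1 / K, K)
  out_tree <- tree
  if (engine == "grid") {
    grid <- .ensure_grid(grid, aln, tree, kappa, pi)
    co <- .counted(function(theta) {
      m <- discretize_beta(exp(theta[1]), exp(theta[2]), K)
      -.mix_loglik(.interp_sitelik(grid, m, .mixture_u(grid$nu, m, wK)),
                   wK, grid$w)
    })
    starts <- list(log(c(0.5, 2)), log(c(1, 1)))
    best <- .run_starts(co$fn, starts, rep(log(0.005), 2), rep(log(99), 2),
                        control = control)
    p <- exp(best$par[1]); q <- exp(best$par[2]); kap <- grid$kappa
  } else {
    prep <- .prepare_site_fit(aln, tree, pi)
    nb <- if (optimize_branch_lengths) length(prep$pt$el) else 0L
    el0 <- pmax(prep$pt$el, 1e-4)
    co <- .counted(function(theta) {
      kap_t <- exp(theta[1])
      m <- discretize_beta(exp(theta[2]), exp(theta[3]), K)
      u <- .mixture_u(.nu_parts(kap_t, prep$pi), m, wK)
      el <- if (nb) exp(theta[4:(3 + nb)]) else prep$pt$el
      L <- .cat_lik_exact(prep$pd, prep$pt, el, kap_t, m, prep$pi, u)
      -.mix_loglik(L, wK, prep$pd$w)
    })
    starts <- lapply(list(log(c(2, 0.5, 2)), log(c(2, 1, 1))),
                     function(s) c(s, if (nb) log(el0)))
    best <- .run_starts(co$fn, starts,
                        c(log(0.01), rep(log(0.005), 2), rep(log(1e-6), nb)),
                        c(log(100), rep(log(99), 2), rep(log(50), nb)),
                        control = control)
    kap <- exp(best$par[1]); p <- exp(best$par[2]); q <- exp(best$par[3])
    if (nb) out_tree <- .set_edge_lengths(tree, prep$pt,
                                          exp(best$par[4:(3 + nb)]))
  }
  structure(list(model = "M7", lnL = -best$value, kappa = kap,
                 mixture = list(p = p, q = q, K = K,
                                means = discretize_beta(p, q, K)),
                 pi = if (engine == "grid") grid$pi else prep$pi,
                 tree = out_tree, engine = engine,
                 converged = best$any_converged,
                 n_evaluations = co$env$n,
                 n_sites = aln$n_sites, taxa = sort(aln$taxa)),
            class = "codon_fit")
}

#' Fit the M8 (beta & omega_s) site-mixture codon model
#'
#' A fraction `p0` of sites follows the discretized Beta(p, q) of M7; the
#' remaining `1 - p0` sit at a single dN/dS `omega_s` constrained to be at
#' least 1, making the M7-vs-M8 comparison a one-sided test for positively
#' selected sites. A boundary fit with `p0` near 1 is a legitimate result,
#' not an error.
#'
#' @inheritParams fit_m7
#' @param omega_s_max Upper bound for the selected-class dN/dS (the grid
#'   engine additionally caps it at the grid's largest dN/dS value).
#' @param m7_fit Optional matching [fit_m7()] result; supplies warm starts
#'   (including the M7 optimum on the `p0 -> 1` boundary, which guarantees
#'   the nesting inequality up to optimizer tolerance).
#' @return A `codon_fit` with `model = "M8"` and `mixture` holding
#'   `p0`, `p`, `q`, `omega_s`, `K`.
#' @export
fit_m8 <- function(aln, tree, K = 10, engine = c("exact", "grid"),
                   grid = NULL, kappa = NULL, pi = NULL, omega_s_max = 99,
                   m7_fit = NULL, optimize_branch_lengths = FALSE,
                   control = list()) {
  engine <- match.arg(engine)
  stopifnot(inherits(aln, "codon_alignment"))
  unpack <- function(theta) {
    list(p0 = stats::plogis(theta[1]), p = exp(theta[2]), q = exp(theta[3]),
         ws = 1 + exp(theta[4]))
  }
  mk_weights <- function(p0, K) c(rep(p0 / K, K), 1 - p0)
  lower <- c(-12, log(0.005), log(0.005), log(1e-6))
  upper <- c(12, log(99), log(99), log(omega_s_max - 1))
  if (!is.null(m7_fit) && m7_fit$model == "M7") {
    # warm starts: the M7 optimum on the boundary (nesting), a
    # selection-enriched perturbation, and a diffuse low-omega_s point
    # (the optimum null data tend to favor)
    starts <- list(c(12, log(m7_fit$mixture$p),
                     log(m7_fit$mixture$q), log(1e-6)),
                   c(stats::qlogis(0.9), log(m7_fit$mixture$p),
                     log(m7_fit$mixture$q), log(2)),
                   c(stats::qlogis(0.6), log(m7_fit$mixture$p),
                     log(m7_fit$mixture$q), log(0.3)))
  } else {
    starts <- list(c(stats::qlogis(0.9), log(0.5), log(2), log(1)),
                   c(stats::qlogis(0.7), log(1), log(1), log(3)))
  }
  out_tree <- tree

  if (engine == "grid") {
    grid <- .ensure_grid(grid, aln, tree, kappa, pi)
    # keep the selected class inside the omega grid
    upper[4] <- min(upper[4], log(max(grid$omega) - 1))
    starts <- lapply(starts, function(s) c(s[1:3], min(s[4], upper[4])))
    co <- .counted(function(theta) {
      th <- unpack(theta)
      m <- c(discretize_beta(th$p, th$q, K), th$ws)
      wts <- mk_weights(th$p0, K)
      -.mix_loglik(.interp_sitelik(grid, m, .mixture_u(grid$nu, m, wts)),
                   wts, grid$w)
    })
    best <- .run_starts(co$fn, starts, lower, upper, control = control)
    kap <- grid$kappa
  } else {
    prep <- .prepare_site_fit(aln, tree, pi)
    if (is.null(kappa)) kappa <- 2
    nb <- if (optimize_branch_lengths) length(prep$pt$el) else 0L
    el0 <- pmax(prep$pt$el, 1e-4)
    starts <- lapply(starts, function(s)
      c(log(kappa), s, if (nb) log(el0)))
    co <- .counted(function(theta) {
      kap_t <- exp(theta[1])
      th <- unpack(theta[2:5])
      m <- c(discretize_beta(th$p, th$q, K), th$ws)
      wts <- mk_weights(th$p0, K)
      uu <- .mixture_u(.nu_parts(kap_t, prep$pi), m, wts)
      el <- if (nb) exp(theta[6:(5 + nb)]) else prep$pt$el
      L <- .cat_lik_exact(prep$pd, prep$pt, el, kap_t, m, prep$pi, uu)
      -.mix_loglik(L, wts, prep$pd$w)
    })
    best <- .run_starts(co$fn, starts,
                        c(log(0.01), lower, rep(log(1e-6), nb)),
                        c(log(100), upper, rep(log(50), nb)),
                        control = control)
    kap <- exp(best$par[1])
    if (nb) out_tree <- .set_edge_lengths(tree, prep$pt,
                                          exp(best$par[6:(5 + nb)]))
    best$par <- best$par[2:5]
  }
  u <- unpack(best$par)
  structure(list(model = "M8", lnL = -best$value, kappa = kap,
                 mixture = list(p0 = u$p0, p = u$p, q = u$q,
                                omega_s = u$ws, K = K,
                                means = discretize_beta(u$p, u$q, K)),
                 pi = if (engine == "grid") grid$pi else prep$pi,
                 tree = out_tree, engine = engine,
                 grid = if (engine == "grid") grid else NULL,
                 converged = best$any_converged,
                 n_evaluations = co$env$n,
                 n_sites = aln$n_sites, taxa = sort(aln$taxa)),
            class = "codon_fit")
}

.ensure_grid <- function(grid, aln, tree, kappa, pi) {
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "site_lik_grid"))
    if (!identical(grid$n_sites, aln$n_sites) ||
        !identical(grid$taxa, sort(aln$taxa)))
      stop("site-likelihood grid was built from different data")
    return(grid)
  }
  if (is.null(kappa)) {
    m0 <- fit_m0(aln, tree, optimize_branch_lengths = FALSE, pi = pi)
    kappa <- if (is.na(m0$kappa)) 2 else m0$kappa
  }
  site_loglik_grid(aln, tree, kappa, pi = pi)
}

#' Likelihood-ratio test of M8 against M7
#'
#' The test statistic is `2 * (lnL_M8 - lnL_M7)`, clipped at zero (the
#' models are nested), referred to a chi-squared distribution with two
#' degrees of freedom.
#'
#' @param fit7,fit8 `codon_fit` objects from [fit_m7()] and [fit_m8()] on
#'   the same alignment and tree.
#' @return An object of class `codon_lrt` with `statistic`, `df` and
#'   `p_value`.
#' @export
lrt_m7_m8 <- function(fit7, fit8) {
  stopifnot(fit7$model == "M7", fit8$model == "M8")
  if (!.same_data(fit7, fit8))
    stop("fits describe different alignments")
  stat <- max(0, 2 * (fit8$lnL - fit7$lnL))
  structure(list(statistic = stat, df = 2,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 lnL7 = fit7$lnL, lnL8 = fit8$lnL),
            class = "codon_lrt")
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: 2*dlnL = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Bayes Empirical Bayes per-codon posteriors of positive selection
#'
#' For each codon column, the posterior probability that its dN/dS exceeds
#' 1 under the M8 mixture, integrating out the mixture parameters over a
#' uniform grid prior: `grid_points` values in each of `p0` (midpoints of
#' `[0, 1]`), `p` and `q` (midpoints of `(0, 2]`) and `omega_s` (midpoints
#' of `[1, 11]`). Grid cells are weighted by their data likelihood. Class
#' conditional likelihoods are interpolated from a [site_loglik_grid()]
#' built at the M8 kappa estimate.
#'
#' @inheritParams fit_m7
#' @param fit8 A converged M8 `codon_fit`.
#' @param grid_points Grid resolution per parameter dimension.
#' @param threshold Posterior-probability threshold used to flag sites.
#' @param reference Optional taxon name; when given, each codon column is
#'   also assigned the amino-acid position in that taxon's ungapped
#'   sequence (`NA` where the reference has a gap).
#' @return A data frame of class `site_posteriors` with one row per codon
#'   column: `site`, `pp_positive`, `post_mean_omega`, `flagged`, and
#'   `ref_pos` when a reference is given. The grid ranges are attached as
#'   attributes.
#' @export
beb_site_posteriors <- function(aln, tree, fit8, grid_points = 10,
                                threshold = 0.75, reference = NULL,
                                grid = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), fit8$model == "M8")
  if (!isTRUE(fit8$converged)) stop("M8 fit did not converge")
  if (is.null(grid)) grid <- fit8$grid
  grid <- .ensure_grid(grid, aln, tree, fit8$kappa, fit8$pi)
  K <- fit8$mixture$K
  g <- grid_points
  mid <- function(lo, hi) lo + (seq_len(g) - 0.5) * (hi - lo) / g
  p0_g <- mid(0, 1); p_g <- mid(0, 2); q_g <- mid(0, 2); ws_g <- mid(1, 11)

  # overall rate scale fixed at the M8 estimate (branch lengths and kappa
  # likewise): only the mixture weights and positions vary over the grid
  mx <- fit8$mixture
  m8 <- c(mx$means, mx$omega_s)
  w8 <- c(rep(mx$p0 / K, K), 1 - mx$p0)
  nubar <- sum(w8 * (grid$nu$s + m8 * grid$nu$n))
  u_of <- function(om) (grid$nu$s + om * grid$nu$n) / nubar

  npat <- dim(grid$logL)[1]
  w <- grid$w
  # per-(p,q) cell: mean class likelihood and mean class likelihood * omega
  B <- matrix(NA_real_, npat, g * g)
  Cm <- matrix(NA_real_, npat, g * g)
  for (ip in seq_len(g)) for (iq in seq_len(g)) {
    m <- discretize_beta(p_g[ip], q_g[iq], K)
    Lk <- .interp_sitelik(grid, m, u_of(m))
    j <- (ip - 1L) * g + iq
    B[, j] <- rowMeans(Lk)
    Cm[, j] <- as.vector(Lk %*% m) / K
  }
  S <- .interp_sitelik(grid, ws_g, u_of(ws_g))

  # pass 1: cell log-likelihoods
  cell_ll <- array(NA_real_, c(g, g * g, g))   # p0 x (p,q) x ws
  for (i0 in seq_len(g)) {
    p0 <- p0_g[i0]
    for (is in seq_len(g)) {
      mix <- p0 * B + (1 - p0) * S[, is]       # npat x g^2
      cell_ll[i0, , is] <- colSums(w * log(pmax(mix, 1e-300)))
    }
  }
  wcell <- exp(cell_ll - max(cell_ll))
  wcell <- wcell / sum(wcell)

  # pass 2: accumulate site posteriors
  pp_sel <- numeric(npat)
  mean_om <- numeric(npat)
  for (i0 in seq_len(g)) {
    p0 <- p0_g[i0]
    for (is in seq_len(g)) {
      mix <- pmax(p0 * B + (1 - p0) * S[, is], 1e-300)
      post_sel <- (1 - p0) * S[, is] / mix     # npat x g^2
      eom <- (p0 * Cm + (1 - p0) * S[, is] * ws_g[is]) / mix
      wc <- wcell[i0, , is]
      pp_sel <- pp_sel + as.vector(post_sel %*% wc)
      mean_om <- mean_om + as.vector(eom %*% wc)
    }
  }
  pp_site <- pp_sel[grid$pat_id]
  om_site <- mean_om[grid$pat_id]
  out <- data.frame(site = seq_len(grid$n_sites),
                    pp_positive = pmin(pmax(pp_site, 0), 1),
                    post_mean_omega = om_site)
  out$flagged <- out$pp_positive >= threshold
  if (!is.null(reference)) {
    ri <- match(reference, aln$taxa)
    if (is.na(ri)) stop("reference taxon '", reference, "' not in alignment")
    nogap <- !aln$gap[ri, ]
    ref_pos <- rep(NA_integer_, aln$n_sites)
    ref_pos[nogap] <- cumsum(nogap)[nogap]
    out$ref_pos <- ref_pos
  }
  attr(out, "threshold") <- threshold
  attr(out, "beb_grid") <- list(p0 = range(p0_g), p = range(p_g),
                                q = range(q_g), omega_s = range(ws_g),
                                grid_points = g)
  class(out) <- c("site_posteriors", "data.frame")
  out
}
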