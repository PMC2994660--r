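# Single-ratio (M0) maximum-likelihood fit.

.OMEGA_MIN <- 1e-4

# counted objective wrapper; returns closure + counter environment
.counted <- function(fn) {
  env <- new.env()
  env$n <- 0L
  f <- function(theta) {
    env$n <- env$n + 1L
    v <- fn(theta)
    if (!is.finite(v)) 1e10 else v
  }
  list(fn = f, env = env)
}

.run_starts <- function(obj, starts, lower, upper, method = "L-BFGS-B",
                        control = list()) {
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = method, lower = lower, upper = upper,
                   control = utils::modifyList(list(factr = 1e7), control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("optimization failed from every start")
  best$any_converged <- conv
  best
}

#' Fit the single-ratio (M0) codon model
#'
#' Maximum-likelihood estimation of a single dN/dS ratio (and kappa, and
#' optionally branch lengths) under the Goldman-Yang model with F3x4
#' frequencies. Optimization is box-constrained quasi-Newton on
#' log-transformed parameters, run from several fixed starting points.
#'
#' @inheritParams codon_loglik
#' @param optimize_branch_lengths If `TRUE` (default) branch lengths are
#'   co-estimated; otherwise they are fixed at the values in `tree`.
#' @param omega_cap Upper bound for the dN/dS estimate. Fits hitting the cap
#'   (e.g. zero synonymous divergence) are returned with `capped = TRUE`
#'   rather than reporting an infinite ratio.
#' @param starts List of `c(kappa, omega)` starting points.
#' @param control Passed to [stats::optim()] control (merged over defaults).
#' @return An object of class `codon_fit` with elements `model = "M0"`,
#'   `lnL`, `kappa`, `omega`, `pi`, `tree` (with estimated branch lengths
#'   when applicable), `converged`, `capped`, `zero_divergence` and
#'   `n_evaluations`. On a zero-divergence alignment `omega` is `NA` and
#'   `zero_divergence` is `TRUE`.
#' @export
fit_m0 <- function(aln, tree, optimize_branch_lengths = TRUE, pi = NULL,
                   omega_cap = 99,
                   starts = list(c(2, 0.4), c(1, 0.1), c(4, 1.5)),
                   control = list()) {
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree, aln$taxa)
  if (length(aln$taxa) < 2L) stop("need at least 2 taxa")
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- pi / sum(pi)
  pt <- .prep_tree(tree)
  pd <- .pattern_data(aln, tree)

  if (.zero_divergence(pd$pat)) {
    return(structure(list(model = "M0", lnL = NA_real_, kappa = NA_real_,
                          omega = NA_real_, pi = pi, tree = tree,
                          converged = FALSE, capped = FALSE,
                          zero_divergence = TRUE, n_evaluations = 0L,
                          n_sites = aln$n_sites, taxa = sort(aln$taxa)),
                     class = "codon_fit"))
  }

  nb <- length(pt$el)
  if (optimize_branch_lengths) {
    obj_raw <- function(theta)
      -.loglik_single(pd, pt, exp(theta[3:(2 + nb)]),
                      exp(theta[1]), exp(theta[2]), pi)
    el0 <- pmax(pt$el, 1e-4)
    st <- lapply(starts, function(s) c(log(s[1]), log(s[2]), log(el0)))
    lower <- c(log(0.01), log(.OMEGA_MIN), rep(log(1e-6), nb))
    upper <- c(log(100), log(omega_cap), rep(log(50), nb))
  } else {
    obj_raw <- function(theta)
      -.loglik_single(pd, pt, pt$el, exp(theta[1]), exp(theta[2]), pi)
    st <- lapply(starts, function(s) log(s))
    lower <- c(log(0.01), log(.OMEGA_MIN))
    upper <- c(log(100), log(omega_cap))
  }
  co <- .counted(obj_raw)
  best <- .run_starts(co$fn, st, lower, upper, control = control)

  kappa <- exp(best$par[1]); omega <- exp(best$par[2])
  out_tree <- tree
  if (optimize_branch_lengths) {
    el_hat <- exp(best$par[3:(2 + nb)])
    out_tree <- .set_edge_lengths(tree, pt, el_hat)
  }
  structure(list(model = "M0", lnL = -best$value, kappa = kappa,
                 omega = min(omega, omega_cap), pi = pi, tree = out_tree,
                 converged = best$any_converged,
                 capped = omega >= omega_cap * 0.999,
                 zero_divergence = FALSE,
                 n_evaluations = co$env$n,
                 n_sites = aln$n_sites, taxa = sort(aln$taxa)),
            class = "codon_fit")
}

# write postorder edge lengths back onto the original tree's edge order
.set_edge_lengths <- function(tree, pt, el) {
  key_orig <- paste(tree$edge[, 1], tree$edge[, 2])
  key_post <- paste(pt$edge[, 1], pt$edge[, 2])
  tree$edge.length <- el[match(key_orig, key_post)]
  tree
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit:", x$model, "\n")
  if (isTRUE(x$zero_divergence)) {
    cat("  zero-divergence alignment: omega undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  lnL = %.4f  kappa = %.4f\n", x$lnL, x$kappa))
  if (!is.null(x$omega) && !is.na(x$omega))
    cat(sprintf("  omega = %.4f%s\n", x$omega,
                if (isTRUE(x$capped)) " (capped)" else ""))
  if (!is.null(x$mixture)) {
    m <- x$mixture
    if (x$model == "M7")
      cat(sprintf("  beta(p = %.4f, q = %.4f), K = %d\n", m$p, m$q, m$K))
    if (x$model == "M8")
      cat(sprintf("  p0 = %.4f  beta(p = %.4f, q = %.4f)  omega_s = %.4f, K = %d\n",
                  m$p0, m$p, m$q, m$omega_s, m$K))
  }
  if (!is.null(x$branch_omega)) {
    cat("  per-branch omega:\n")
    print(round(x$branch_omega, 4))
  }
  cat("  converged:", x$converged, " evaluations:", x$n_evaluations, "\n")
  invisible(x)
}

# shared check that two fits describe the same data
.same_data <- function(a, b) {
  identical(a$n_sites, b$n_sites) && identical(a$taxa, b$taxa)
}
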