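# Free-ratio branch model: an independent dN/dS on every branch.

#' Fit the free-ratio branch model
#'
#' Estimates one dN/dS per branch with a shared kappa and F3x4 frequencies;
#' branch lengths are co-estimated by default. Branches are keyed by their
#' child node: the tip label for terminal branches, `"node<k>"` for
#' internal ones. Branch estimates hitting the cap (e.g. no synonymous
#' change on the branch) are flagged.
#'
#' @inheritParams fit_m0
#' @return A `codon_fit` with `model = "free_ratio"`, a named
#'   `branch_omega` vector, `capped_branches` flags, shared `kappa`, `lnL`
#'   and the tree with estimated branch lengths.
#' @export
fit_free_ratio <- function(aln, tree, optimize_branch_lengths = TRUE,
                           pi = NULL, omega_cap = 99, control = list()) {
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree, aln$taxa)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- pi / sum(pi)
  pt <- .prep_tree(tree)
  pd <- .pattern_data(aln, tree)
  if (.zero_divergence(pd$pat))
    stop("zero-divergence alignment: branch-specific omega undefined")
  nb <- length(pt$el)
  keys <- .edge_keys(pt)

  # warm start from the single-ratio fit
  m0 <- fit_m0(aln, tree, optimize_branch_lengths = optimize_branch_lengths,
               pi = pi)
  el0 <- pmax(.prep_tree(m0$tree)$el, 1e-4)
  om0 <- max(m0$omega, .OMEGA_MIN, na.rm = TRUE)

  if (optimize_branch_lengths) {
    obj_raw <- function(theta)
      -.loglik_branch(pd, pt, exp(theta[(nb + 2):(2 * nb + 1)]),
                      exp(theta[1]), exp(theta[2:(nb + 1)]), pi)
    st <- list(c(log(max(m0$kappa, 0.1)), rep(log(om0), nb), log(el0)),
               c(log(2), rep(log(0.3), nb), log(el0)))
    lower <- c(log(0.01), rep(log(.OMEGA_MIN), nb), rep(log(1e-6), nb))
    upper <- c(log(100), rep(log(omega_cap), nb), rep(log(50), nb))
  } else {
    obj_raw <- function(theta)
      -.loglik_branch(pd, pt, pt$el, exp(theta[1]),
                      exp(theta[2:(nb + 1)]), pi)
    st <- list(c(log(max(m0$kappa, 0.1)), rep(log(om0), nb)),
               c(log(2), rep(log(0.3), nb)))
    lower <- c(log(0.01), rep(log(.OMEGA_MIN), nb))
    upper <- c(log(100), rep(log(omega_cap), nb))
  }
  co <- .counted(obj_raw)
  best <- .run_starts(co$fn, st, lower, upper, control = control)

  omega_hat <- pmin(exp(best$par[2:(nb + 1)]), omega_cap)
  names(omega_hat) <- keys
  out_tree <- tree
  if (optimize_branch_lengths)
    out_tree <- .set_edge_lengths(tree, pt,
                                  exp(best$par[(nb + 2):(2 * nb + 1)]))
  structure(list(model = "free_ratio", lnL = -best$value,
                 kappa = exp(best$par[1]),
                 branch_omega = omega_hat,
                 capped_branches = omega_hat >= omega_cap * 0.999,
                 pi = pi, tree = out_tree,
                 converged = best$any_converged,
                 n_evaluations = co$env$n,
                 n_sites = aln$n_sites, taxa = sort(aln$taxa),
                 m0 = m0),
            class = "codon_fit")
}

#' Compare the free-ratio model to a single shared ratio
#'
#' Likelihood-ratio test of the free-ratio model against M0 (all branch
#' ratios equal), with degrees of freedom equal to the number of branches
#' minus one. This is the package's operationalization of branch-level
#' support: a non-significant result means no branch-specific shift in
#' selective pressure is statistically supported.
#'
#' @inheritParams fit_m0
#' @param free A `codon_fit` from [fit_free_ratio()].
#' @param m0 Optional matching M0 fit; refit if missing (the free-ratio
#'   fit's warm-start M0 is reused when available).
#' @return A `codon_lrt` with `statistic`, `df` and `p_value`.
#' @export
constrain_equal_and_compare <- function(aln, tree, free, m0 = NULL) {
  stopifnot(free$model == "free_ratio")
  if (is.null(m0)) m0 <- free$m0
  if (is.null(m0)) m0 <- fit_m0(aln, tree)
  if (!.same_data(free, m0)) stop("fits describe different alignments")
  stat <- max(0, 2 * (free$lnL - m0$lnL))
  df <- length(free$branch_omega) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 lnL_free = free$lnL, lnL_m0 = m0$lnL),
            class = "codon_lrt")
}

#' Annotate a tree with per-branch dN/dS estimates
#'
#' @param free A `codon_fit` from [fit_free_ratio()].
#' @return The fitted tree with a `node.label`-independent edge annotation:
#'   a data frame (`branch_table`) of child key, branch length and omega,
#'   plus the tree whose edge order matches the table.
#' @export
branch_omega_table <- function(free) {
  stopifnot(free$model == "free_ratio")
  pt <- .prep_tree(free$tree)
  data.frame(branch = .edge_keys(pt),
             length = pt$el,
             omega = unname(free$branch_omega[.edge_keys(pt)]),
             capped = unname(free$capped_branches[.edge_keys(pt)]))
}
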