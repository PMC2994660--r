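# Felsenstein pruning likelihood over codon sites.

# --- tree preprocessing -----------------------------------------------------

.check_tree <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths (substitutions per codon)")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!is.null(taxa) && !setequal(tree$tip.label, taxa))
    stop("tree tip labels do not match alignment taxa")
  invisible(tree)
}

# postorder edge table; root recovered as the node that is never a child
.prep_tree <- function(tree) {
  pt <- ape::reorder.phylo(tree, "postorder")
  edge <- pt$edge
  list(edge = edge, el = pt$edge.length,
       ntip = length(pt$tip.label), nnode = pt$Nnode,
       tip.label = pt$tip.label,
       root = setdiff(edge[, 1], edge[, 2])[1])
}

# site-pattern compression; tip rows ordered as tree tip labels
.pattern_data <- function(aln, tree) {
  ord <- match(tree$tip.label, aln$taxa)
  idx <- aln$idx[ord, , drop = FALSE]
  key <- apply(idx, 2, paste, collapse = ",")
  keep <- !duplicated(key)
  pat_id <- match(key, key[keep])
  list(pat = idx[, keep, drop = FALSE],
       w = as.numeric(tabulate(pat_id, sum(keep))),
       pat_id = pat_id)
}

# degenerate data: every pattern has at most one distinct observed state
.zero_divergence <- function(pat) {
  all(apply(pat, 2, function(col) length(unique(col[!is.na(col)])) <= 1L))
}

# --- pruning ---------------------------------------------------------------

# per-pattern site likelihood (not log), given per-edge P matrices in the
# postorder edge order of `pt`
.site_lik <- function(pat, pt, Plist, pi) {
  npat <- ncol(pat)
  ntip <- pt$ntip
  partial <- vector("list", ntip + pt$nnode)
  edge <- pt$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    P <- Plist[[k]]
    if (ch <= ntip) {
      st <- pat[ch, ]
      M <- matrix(1, 61, npat)
      ok <- which(!is.na(st))
      if (length(ok)) M[, ok] <- P[, st[ok]]
    } else {
      M <- P %*% partial[[ch]]
    }
    partial[[par]] <- if (is.null(partial[[par]])) M else partial[[par]] * M
  }
  lik <- as.vector(pi %*% partial[[pt$root]])
  pmax(lik, 1e-300)
}

.loglik_single <- function(pd, pt, el, kappa, omega, pi) {
  eig <- .codon_eig(kappa, omega, pi)
  Plist <- lapply(el, .pmat, eig = eig)
  sum(pd$w * log(.site_lik(pd$pat, pt, Plist, pi)))
}

# branch-specific omega: `omega_edge` is a vector over postorder edges
.loglik_branch <- function(pd, pt, el, kappa, omega_edge, pi) {
  uo <- unique(omega_edge)
  eigs <- lapply(uo, function(o) .codon_eig(kappa, o, pi))
  names(eigs) <- as.character(uo)
  Plist <- lapply(seq_along(el), function(k)
    .pmat(eigs[[as.character(omega_edge[k])]], el[k]))
  sum(pd$w * log(.site_lik(pd$pat, pt, Plist, pi)))
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over codon sites under the Goldman-Yang model. Gap
#' and ambiguous codons are treated as missing data (partial likelihood
#' vectors of ones). The root is weighted by the equilibrium frequencies;
#' by reversibility the result does not depend on root placement.
#'
#' @param aln A `codon_alignment`.
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per codon; tip labels must match the alignment taxa.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Either a single dN/dS ratio applied to all branches, or a
#'   named vector keyed by child node (tip label or internal node number)
#'   giving one dN/dS per branch.
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @return The log-likelihood (sum over codon sites).
#' @export
codon_loglik <- function(aln, tree, kappa, omega, pi = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree, aln$taxa)
  if (aln$n_sites == 0L) stop("empty alignment")
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- pi / sum(pi)
  pt <- .prep_tree(tree)
  pd <- .pattern_data(aln, tree)
  if (length(omega) == 1L && is.null(names(omega)))
    return(.loglik_single(pd, pt, pt$el, kappa, omega, pi))
  omega_edge <- .omega_by_edge(pt, omega)
  .loglik_branch(pd, pt, pt$el, kappa, omega_edge, pi)
}

# map a child-node-keyed omega vector onto postorder edges
.omega_by_edge <- function(pt, omega) {
  keys <- .edge_keys(pt)
  if (!setequal(names(omega), keys))
    stop("branch omega map must have one entry per branch, keyed by child ",
         "node (tip label or internal node number)")
  unname(omega[keys])
}

# branch identity: child tip label, or "node<k>" for internal children
.edge_keys <- function(pt) {
  ch <- pt$edge[, 2]
  ifelse(ch <= pt$ntip, pt$tip.label[ch], paste0("node", ch))
}

# --- site-likelihood grids (mixture engines) -------------------------------

#' Per-site codon log-likelihoods on a (dN/dS, branch-scale) grid
#'
#' Computes, for each alignment site pattern, the conditional log-likelihood
#' under a single-omega model at every combination of `omega_grid` and
#' `scale_grid`, where the scale multiplies all branch lengths; `kappa` and
#' the frequencies are held fixed. This grid is the work-horse behind the
#' fast site-mixture engine and the Bayes Empirical Bayes integration: a
#' mixture category with dN/dS `w` under common mixture scaling has
#' branch-length multiplier `nu(w)/nubar`, and its conditional likelihood is
#' read off the grid by bilinear interpolation in (omega, log scale).
#'
#' @inheritParams codon_loglik
#' @param omega_grid Increasing vector of dN/dS values; the default spans
#'   `[1e-4, 15]` densely below 1 and log-spaced above.
#' @param scale_grid Increasing vector of branch-length multipliers; the
#'   default is log-spaced over `[0.2, 32]`.
#' @return An object of class `site_lik_grid`.
#' @export
site_loglik_grid <- function(aln, tree, kappa, omega_grid = NULL,
                             scale_grid = NULL, pi = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree, aln$taxa)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  pi <- pi / sum(pi)
  om_eps <- 0.01  # omega axis is uniform (and interpolated) in log(omega + om_eps)
  if (is.null(omega_grid))
    omega_grid <- exp(seq(log(1e-4 + om_eps), log(15 + om_eps),
                          length.out = 40)) - om_eps
  if (is.null(scale_grid))
    scale_grid <- exp(seq(log(0.2), log(32), length.out = 19))
  stopifnot(!is.unsorted(omega_grid), all(omega_grid >= 0),
            !is.unsorted(scale_grid), all(scale_grid > 0))
  pt <- .prep_tree(tree)
  pd <- .pattern_data(aln, tree)
  logL <- array(NA_real_,
                c(ncol(pd$pat), length(omega_grid), length(scale_grid)))
  for (g in seq_along(omega_grid)) {
    eig <- .codon_eig(kappa, omega_grid[g], pi)
    for (s in seq_along(scale_grid)) {
      Plist <- lapply(pt$el * scale_grid[s], .pmat, eig = eig)
      logL[, g, s] <- log(.site_lik(pd$pat, pt, Plist, pi))
    }
  }
  structure(list(omega = omega_grid, scale = scale_grid, logL = logL,
                 om_eps = om_eps, w = pd$w, pat_id = pd$pat_id,
                 n_sites = aln$n_sites, kappa = kappa, pi = pi,
                 nu = .nu_parts(kappa, pi),
                 taxa = sort(aln$taxa)),
            class = "site_lik_grid")
}

# npat x length(omegas) site likelihoods by bilinear interpolation of the
# per-site log-likelihood in (omega, log scale); arguments clamped to the
# grid ranges. `u` gives the branch-scale per requested omega (default 1).
.interp_sitelik <- function(grid, omegas, u = rep(1, length(omegas)),
                            log = FALSE) {
  og <- log(grid$omega + grid$om_eps)
  sg <- log(grid$scale)
  x <- pmin(pmax(log(omegas + grid$om_eps), og[1]), og[length(og)])
  lu <- pmin(pmax(log(u), sg[1]), sg[length(sg)])
  i <- findInterval(x, og, all.inside = TRUE)
  fo <- (x - og[i]) / (og[i + 1] - og[i])
  j <- findInterval(lu, sg, all.inside = TRUE)
  fu <- (lu - sg[j]) / (sg[j + 1] - sg[j])
  out <- matrix(NA_real_, dim(grid$logL)[1], length(omegas))
  for (k in seq_along(omegas)) {
    out[, k] <-
      (1 - fo[k]) * ((1 - fu[k]) * grid$logL[, i[k], j[k]] +
                     fu[k] * grid$logL[, i[k], j[k] + 1]) +
      fo[k] * ((1 - fu[k]) * grid$logL[, i[k] + 1, j[k]] +
               fu[k] * grid$logL[, i[k] + 1, j[k] + 1])
  }
  if (log) out else exp(out)
}
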