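# Goldman-Yang codon rate matrix and transition probabilities.

#' Goldman-Yang codon instantaneous rate matrix
#'
#' Builds the 61x61 GY94-type rate matrix: for codon pairs differing at one
#' nucleotide, the rate to codon j is proportional to `pi[j]`, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous exchanges; pairs
#' differing at two or more positions have rate 0. The matrix is scaled so
#' that the expected number of substitutions per codon per unit time,
#' `-sum(pi * diag(Q))`, equals 1, so branch lengths are in expected
#' substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Codon frequency vector over the 61 sense codons (sums to 1).
#'   Defaults to uniform.
#' @return A 61x61 rate matrix with rows summing to 0.
#' @export
#' @examples
#' Q <- codon_rate_matrix(kappa = 2, omega = 0.5)
#' max(abs(rowSums(Q)))
codon_rate_matrix <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(omega), length(omega) == 1L, omega >= 0,
            length(pi) == 61L, all(pi > 0))
  pi <- pi / sum(pi)
  tab <- .codon_tables
  r <- ifelse(tab$pair_ti, kappa, 1) * ifelse(tab$pair_ns, omega, 1)
  Q <- matrix(0, 61, 61, dimnames = list(.CODONS, .CODONS))
  Q[cbind(tab$pair_i, tab$pair_j)] <- r * pi[tab$pair_j]
  Q[cbind(tab$pair_j, tab$pair_i)] <- r * pi[tab$pair_i]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / mu
}

# Unscaled substitution rate nu(omega) = nu_s + omega * nu_n: the expected
# unscaled flux through synonymous and nonsynonymous single-nucleotide
# exchanges. Site-mixture models scale all categories by the common factor
# 1 / nubar (mixture-average nu), so branch lengths stay in expected
# substitutions per codon under the whole mixture and high-omega sites
# evolve faster than low-omega sites.
.nu_parts <- function(kappa, pi) {
  tab <- .codon_tables
  f <- 2 * pi[tab$pair_i] * pi[tab$pair_j] * ifelse(tab$pair_ti, kappa, 1)
  list(s = sum(f[!tab$pair_ns]), n = sum(f[tab$pair_ns]))
}

# per-category branch-length multipliers under common mixture scaling
.mixture_u <- function(nu, omegas, weights) {
  nuk <- nu$s + omegas * nu$n
  nuk / sum(weights * nuk)
}

# Eigendecomposition of the reversible Q via its symmetrization
# S = D^{1/2} Q D^{-1/2}.  P(t) = A exp(val t) B with A = D^{-1/2} U,
# B = U' D^{1/2}.
.codon_eig <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  sp <- sqrt(pi / sum(pi))
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sp, B = t(e$vectors * sp), val = e$values)
}

.pmat <- function(eig, t) {
  P <- eig$A %*% (exp(eig$val * t) * eig$B)
  P[P < 0] <- 0
  P
}

#' Codon transition probability matrix
#'
#' Matrix exponential `P(t) = exp(Qt)` of the scaled reversible codon rate
#' matrix, computed by eigendecomposition.
#'
#' @inheritParams codon_rate_matrix
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @return Row-stochastic 61x61 matrix; the identity at `t = 0`.
#' @export
transition_probabilities <- function(kappa, omega, t,
                                     pi = rep(1 / 61, 61)) {
  if (t < 0) stop("branch length t must be non-negative")
  pi <- pi / sum(pi)
  P <- .pmat(.codon_eig(kappa, omega, pi), t)
  P / rowSums(P)
}
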