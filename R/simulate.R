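# Seeded simulators: codon alignments evolved under the implemented models,
# and ChIP coverage tracks with planted fold enrichment.

# run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses the current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' A five-taxon sensu stricto style yeast tree
#'
#' The default study tree for simulations: the sensu stricto topology
#' ((Scer,Spar),Smik,(Skud,Sbay)) with branch lengths in expected
#' substitutions per codon, scaled to a rapidly evolving gene (total tree
#' length 1.12).
#'
#' @return An unrooted `ape::phylo` tree.
#' @export
sensu_stricto_tree <- function() {
  ape::read.tree(text = paste0(
    "((Scer:0.09,Spar:0.11):0.13,Smik:0.22,(Skud:0.20,Sbay:0.25):0.12);"))
}

# theoretical mixture of omega values (weights sum to 1) for a model spec
.theoretical_mixture <- function(model, omega, p, q, p0, omega_s,
                                 sim_categories) {
  switch(model,
    M0 = list(omegas = omega, weights = 1),
    M7 = list(omegas = discretize_beta(p, q, sim_categories),
              weights = rep(1 / sim_categories, sim_categories)),
    M8 = list(omegas = c(discretize_beta(p, q, sim_categories), omega_s),
              weights = c(rep(p0 / sim_categories, sim_categories), 1 - p0)),
    stop("unknown model '", model, "'"))
}

# draw per-site omega values and classes for a model spec
.draw_site_omegas <- function(n_codons, model, omega, p, q, p0, omega_s,
                              sim_categories) {
  switch(model,
    M0 = list(omega = rep(omega, n_codons),
              class = rep("single", n_codons)),
    M7 = {
      cats <- discretize_beta(p, q, sim_categories)
      k <- sample.int(sim_categories, n_codons, replace = TRUE)
      list(omega = cats[k], class = rep("beta", n_codons))
    },
    M8 = {
      cats <- discretize_beta(p, q, sim_categories)
      sel <- stats::runif(n_codons) > p0
      om <- numeric(n_codons)
      om[!sel] <- cats[sample.int(sim_categories, sum(!sel), replace = TRUE)]
      om[sel] <- omega_s
      list(omega = om, class = ifelse(sel, "selected", "beta"))
    },
    branch = list(omega = rep(NA_real_, n_codons),
                  class = rep("branch", n_codons)),
    stop("unknown model '", model, "'"))
}

#' Simulate a codon alignment on a tree
#'
#' Evolves codon sites along `tree` under the Goldman-Yang model. The root
#' state of each site is drawn from the equilibrium frequencies; each branch
#' then applies the transition probabilities of the scaled rate matrix.
#' Site dN/dS is drawn once per site from the model's mixture (M7/M8 draws
#' are taken from a fine equal-probability discretization of the beta) and
#' does not switch along the tree. Mixture categories share a common rate
#' scaling, so branch lengths are expected substitutions per codon averaged
#' over sites and high-dN/dS sites evolve faster than conserved ones.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions per codon.
#' @param n_codons Number of codon sites.
#' @param model `"M0"`, `"M7"`, `"M8"` or `"branch"`.
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS for `model = "M0"`.
#' @param p,q Beta shape parameters (M7, M8).
#' @param p0 Proportion of beta-class sites (M8).
#' @param omega_s Selected-class dN/dS (M8).
#' @param branch_omega Named per-branch dN/dS map keyed by child node
#'   (`model = "branch"`).
#' @param pi `"uniform"` or a 61-vector of codon frequencies.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param sim_categories Number of discretization classes used to draw
#'   beta-distributed site dN/dS values.
#' @return A list with `alignment` (a `codon_alignment`) and `truth` (data
#'   frame of per-site generating class and dN/dS).
#' @export
simulate_codon_alignment <- function(tree, n_codons, model = "M0",
                                     kappa = 2, omega = 0.4,
                                     p = 0.5, q = 2, p0 = 0.95, omega_s = 5,
                                     branch_omega = NULL, pi = "uniform",
                                     seed = NULL, sim_categories = 50) {
  .check_tree(tree)
  stopifnot(n_codons >= 1)
  if (identical(pi, "uniform")) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61L)
  pi <- pi / sum(pi)
  .with_seed(seed, {
    truth <- .draw_site_omegas(n_codons, model, omega, p, q, p0, omega_s,
                               sim_categories)
    pt <- .prep_tree(tree)
    ntip <- pt$ntip
    nnode_tot <- ntip + pt$nnode
    states <- matrix(NA_integer_, nnode_tot, n_codons)
    states[pt$root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)

    if (model == "branch") {
      omega_edge <- .omega_by_edge(pt, branch_omega)
      eig_for_edge <- lapply(omega_edge, .codon_eig, kappa = kappa, pi = pi)
      site_cat <- rep(1L, n_codons)
    } else {
      uo <- unique(truth$omega)
      site_cat <- match(truth$omega, uo)
      eig_cat <- lapply(uo, .codon_eig, kappa = kappa, pi = pi)
      # common mixture scaling: high-omega categories evolve faster; the
      # scale is taken over the model's theoretical mixture
      nu <- .nu_parts(kappa, pi)
      mix <- .theoretical_mixture(model, omega, p, q, p0, omega_s,
                                  sim_categories)
      nubar <- sum(mix$weights * (nu$s + mix$omegas * nu$n))
      u_cat <- (nu$s + uo * nu$n) / nubar
    }

    for (k in rev(seq_len(nrow(pt$edge)))) {      # preorder
      par <- pt$edge[k, 1]; ch <- pt$edge[k, 2]; t <- pt$el[k]
      if (model == "branch") {
        Pk <- list(.pmat(eig_for_edge[[k]], t))
        cat_of_site <- rep(1L, n_codons)
      } else {
        Pk <- lapply(seq_along(eig_cat), function(cc)
          .pmat(eig_cat[[cc]], t * u_cat[cc]))
        cat_of_site <- site_cat
      }
      Pk <- lapply(Pk, function(P) P / rowSums(P))
      child <- integer(n_codons)
      for (cc in unique(cat_of_site)) {
        in_cat <- which(cat_of_site == cc)
        pstates <- states[par, in_cat]
        for (s in unique(pstates)) {
          i <- in_cat[pstates == s]
          child[i] <- sample.int(61, length(i), replace = TRUE,
                                 prob = Pk[[cc]][s, ])
        }
      }
      states[ch, ] <- child
    }

    tipseq <- vapply(seq_len(ntip), function(i)
      paste0(.CODONS[states[i, ]], collapse = ""), "")
    names(tipseq) <- pt$tip.label
    aln <- codon_alignment(tipseq)
    truth_df <- data.frame(site = seq_len(n_codons),
                           class = truth$class, omega = truth$omega)
    list(alignment = aln, truth = truth_df)
  })
}

#' Simulate a set of homogeneous background genes
#'
#' Generates `n_genes` alignments evolved under M0 at a shared background
#' dN/dS, the raw material for [build_empirical_null()].
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in codons.
#' @param omega_background Shared dN/dS.
#' @inheritParams simulate_codon_alignment
#' @return Named list of `codon_alignment` objects.
#' @export
simulate_null_gene_set <- function(n_genes, gene_length, omega_background,
                                   tree, kappa = 2, pi = "uniform",
                                   seed = NULL) {
  .with_seed(seed, {
    out <- lapply(seq_len(n_genes), function(i)
      simulate_codon_alignment(tree, gene_length, model = "M0",
                               kappa = kappa, omega = omega_background,
                               pi = pi, seed = NULL)$alignment)
    names(out) <- sprintf("gene%03d", seq_len(n_genes))
    out
  })
}

#' Simulate a ChIP-Seq IP/Input coverage experiment
#'
#' Draws per-base read counts for an input (whole chromatin) and an IP
#' fraction over one or more contigs. Input counts have mean `input_depth`
#' everywhere; IP counts have mean `ip_depth * fold(b)`, where the fold is
#' the planted enrichment inside each region and 1 elsewhere. Noise is
#' negative binomial by default (ChIP coverage is overdispersed); Poisson
#' is available for oracle checks. Counts are independent across bases
#' (coverage-level simulation; fragment-length correlation is not
#' modelled).
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param regions Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and `fold`; may be empty.
#' @param input_depth Mean input coverage per base.
#' @param ip_depth Mean IP coverage per base at unenriched positions.
#' @param noise `"nb"` or `"poisson"`.
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return List with `ip` and `input` (named lists of `coverage_track`)
#'   and `truth` (the regions with planted folds and depths).
#' @export
simulate_chip_experiment <- function(contig_lengths,
                                     regions = NULL,
                                     input_depth = 30, ip_depth = 10,
                                     noise = c("nb", "poisson"),
                                     dispersion = 0.1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(!is.null(names(contig_lengths)))
  if (is.null(regions))
    regions <- data.frame(contig = character(), start = integer(),
                          end = integer(), fold = numeric())
  stopifnot(all(regions$fold >= 0))
  rdraw <- function(mu) {
    if (noise == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  .with_seed(seed, {
    ip <- list(); input <- list()
    for (ctg in names(contig_lengths)) {
      len <- contig_lengths[[ctg]]
      fold <- rep(1, len)
      rr <- regions[regions$contig == ctg, , drop = FALSE]
      for (j in seq_len(nrow(rr))) {
        stopifnot(rr$start[j] >= 0, rr$end[j] <= len)
        fold[(rr$start[j] + 1):rr$end[j]] <- rr$fold[j]
      }
      input[[ctg]] <- coverage_track(ctg, rdraw(rep(input_depth, len)))
      ip[[ctg]] <- coverage_track(ctg, rdraw(ip_depth * fold))
    }
    list(ip = ip, input = input,
         truth = list(regions = regions, input_depth = input_depth,
                      ip_depth = ip_depth, noise = noise,
                      dispersion = dispersion))
  })
}
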