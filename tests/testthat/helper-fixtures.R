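# Shared fixtures and independent oracles, built in code at test time.

tree2 <- function() ape::read.tree(text = "(a:0.15,b:0.25);")
tree3 <- function() ape::read.tree(text = "(a:0.1,b:0.2,c:0.3);")
tree4u <- function() ape::read.tree(
  text = "(a:0.1,b:0.2,(c:0.15,d:0.25):0.12);")
tree4r <- function() ape::read.tree(
  text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.25):0.07);")

# random gap-free codon alignment (uniform codons, no evolutionary signal;
# for structural tests only)
random_alignment <- function(ntaxa, n_sites, gap_codons = 0) {
  cods <- sense_codons()
  seqs <- vapply(seq_len(ntaxa), function(i)
    paste0(sample(cods, n_sites, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("t", seq_len(ntaxa))
  aln <- codon_alignment(seqs)
  if (gap_codons > 0) {
    pos <- sample(n_sites, gap_codons)
    for (s in pos) {
      i <- sample(ntaxa, 1)
      aln$codon[i, s] <- "---"
      aln$gap[i, s] <- TRUE
      aln$idx[i, s] <- NA_integer_
    }
  }
  aln
}

# Brute-force likelihood oracle: exhaustive sum over all internal-node
# state assignments, using only the exported transition probabilities.
brute_force_loglik <- function(aln, tree, kappa, omega, pi) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  internals <- sort(unique(edge[edge > ntip]))
  root <- setdiff(edge[, 1], edge[, 2])
  P <- lapply(seq_len(nrow(edge)), function(k)
    transition_probabilities(kappa, omega, tr$edge.length[k], pi))
  tipstate <- aln$idx[match(tr$tip.label, aln$taxa), , drop = FALSE]

  combos <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  total <- 0
  for (s in seq_len(aln$n_sites)) {
    lik <- pi[combos[, match(root, internals)]]
    for (k in seq_len(nrow(edge))) {
      pstate <- combos[, match(edge[k, 1], internals)]
      ch <- edge[k, 2]
      if (ch <= ntip) {
        st <- tipstate[ch, s]
        if (is.na(st)) next  # missing tip: sums to 1
        lik <- lik * P[[k]][cbind(pstate, st)]
      } else {
        lik <- lik * P[[k]][cbind(pstate, combos[, match(ch, internals)])]
      }
    }
    total <- total + log(sum(lik))
  }
  total
}

# two-taxon closed form: sum over the 61 root states per site
two_taxon_loglik <- function(aln, tree, kappa, omega, pi) {
  tr <- ape::reorder.phylo(tree, "postorder")
  P <- lapply(seq_len(2), function(k)
    transition_probabilities(kappa, omega, tr$edge.length[k], pi))
  tipstate <- aln$idx[match(tr$tip.label, aln$taxa), , drop = FALSE]
  ch <- tr$edge[, 2]
  total <- 0
  for (s in seq_len(aln$n_sites)) {
    v1 <- if (is.na(tipstate[ch[1], s])) rep(1, 61) else P[[1]][, tipstate[ch[1], s]]
    v2 <- if (is.na(tipstate[ch[2], s])) rep(1, 61) else P[[2]][, tipstate[ch[2], s]]
    total <- total + log(sum(pi * v1 * v2))
  }
  total
}

# brute-force window gap rule: test every start against the gap matrix
oracle_gap_free <- function(aln, window_size, step) {
  starts <- seq.int(0L, aln$nuc_length - window_size, by = step)
  vapply(starts, function(s) {
    cols <- (s %/% 3 + 1):((s + window_size) %/% 3)
    !any(aln$gap[, cols])
  }, logical(1))
}
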