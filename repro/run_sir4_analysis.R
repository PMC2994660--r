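#!/usr/bin/env Rscript

# Full selection-scan workflow on user-supplied SIR4 data (see README.md).

suppressPackageStartupMessages(library(coevoscan))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = "results/sir4")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[gsub("-", "_", key)]] <- args[i + 1]
  i <- i + 2L
}
for (req in c("protein_alignment", "cds", "tree"))
  if (is.null(opt[[req]])) stop("missing --", gsub("_", "-", req))
dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

read_named <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

aln <- backtranslate(read_named(opt$protein_alignment), read_named(opt$cds))
tree <- ape::read.tree(opt$tree)

m0 <- fit_m0(aln, tree, optimize_branch_lengths = TRUE)
cat("Whole-gene M0:\n"); print(m0)

scan <- scan_omega(aln, m0$tree, window_size = 102, step = 3,
                   gene_fit = m0)
print(scan)
write.table(scan$windows, file.path(opt$out, "window_scan.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

grid <- site_loglik_grid(aln, m0$tree, kappa = m0$kappa)
f7 <- fit_m7(aln, m0$tree, engine = "grid", grid = grid)
f8 <- fit_m8(aln, m0$tree, engine = "grid", grid = grid, m7_fit = f7)
lrt <- lrt_m7_m8(f7, f8)
print(f7); print(f8); print(lrt)

beb <- beb_site_posteriors(aln, m0$tree, f8, threshold = 0.75,
                           reference = aln$taxa[1])
cat(sum(beb$flagged), "codons flagged at posterior probability >= 0.75\n")
write.table(as.data.frame(beb), file.path(opt$out, "beb_posteriors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fr <- fit_free_ratio(aln, tree)
print(fr)
write.table(branch_omega_table(fr), file.path(opt$out, "branch_omega.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (!is.null(opt$null_genes)) {
  files <- list.files(opt$null_genes, full.names = TRUE)
  genes <- lapply(files, read_codon_alignment)
  names(genes) <- basename(files)
  null <- build_empirical_null(genes, tree, n_windows = 1500,
                               seed = 1)
  print(null)
  write.table(data.frame(omega = null$omega, gene = null$sources),
              file.path(opt$out, "null_windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
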