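# In-frame codon alignment container and FASTA handling.

#' Build a codon alignment from aligned coding sequences
#'
#' Constructs the codon-alignment object used by every selection analysis in
#' the package. Sequences must be aligned (equal length), in frame (length
#' divisible by 3), and free of in-frame stop codons. Codons containing gap
#' characters are treated as gap columns for that taxon; codons containing
#' other non-ACGT characters are treated as ambiguous (missing data for the
#' likelihood, but not gaps for the window-scan gap rule).
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @param mask_stops If `TRUE`, in-frame stop codons are masked to missing
#'   data instead of raising an error.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `codon` (taxa x sites character matrix of codon strings), `idx`
#'   (integer codon states, `NA` when missing), `gap` (logical matrix),
#'   `n_sites`, and `nuc_length`.
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "ATGGCT", b = "ATG---"))
#' aln$n_sites
codon_alignment <- function(seqs, mask_stops = FALSE) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(vapply(seqs, as.character, ""))
  nlen <- unique(nchar(seqs))
  if (length(nlen) != 1L)
    stop("all rows must have equal length (aligned input required)")
  if (nlen %% 3L != 0L)
    stop("alignment nucleotide length (", nlen, ") not divisible by 3")
  n_sites <- nlen %/% 3L
  ntaxa <- length(seqs)
  codon <- matrix("", ntaxa, n_sites, dimnames = list(names(seqs), NULL))
  starts <- 3L * (seq_len(n_sites) - 1L) + 1L
  for (i in seq_len(ntaxa))
    codon[i, ] <- substring(seqs[[i]], starts, starts + 2L)

  gap <- matrix(grepl("-", codon, fixed = TRUE), ntaxa, n_sites)
  idx <- matrix(.codon_index(codon), ntaxa, n_sites)
  is_stop <- matrix(codon %in% .STOP_CODONS, ntaxa, n_sites)
  if (any(is_stop)) {
    if (!mask_stops) {
      w <- which(is_stop, arr.ind = TRUE)[1, ]
      stop("in-frame stop codon in taxon '", names(seqs)[w[1]],
           "' at codon position ", w[2],
           " (use mask_stops = TRUE to mask)")
    }
    idx[is_stop] <- NA_integer_
  }
  structure(list(taxa = names(seqs), codon = codon, idx = idx, gap = gap,
                 n_sites = n_sites, nuc_length = nlen),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", length(x$taxa), " taxa, ", x$n_sites,
      " codon sites (", x$nuc_length, " nt)\n", sep = "")
  cat("Taxa:", paste(x$taxa, collapse = ", "), "\n")
  ngap <- sum(x$gap)
  if (ngap > 0) cat("Gap codons:", ngap, "\n")
  invisible(x)
}

# site subset, keeping all metadata consistent
.subset_sites <- function(aln, sites) {
  structure(list(taxa = aln$taxa,
                 codon = aln$codon[, sites, drop = FALSE],
                 idx = aln$idx[, sites, drop = FALSE],
                 gap = aln$gap[, sites, drop = FALSE],
                 n_sites = length(sites),
                 nuc_length = 3L * length(sites)),
            class = "codon_alignment")
}

#' Read an aligned coding-sequence FASTA as a codon alignment
#'
#' @param path Path to an aligned FASTA file of in-frame coding sequences.
#' @inheritParams codon_alignment
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, mask_stops = FALSE) {
  x <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)),
                  mask_stops = mask_stops)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output file path.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codon, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, aln$taxa)), path)
  invisible(path)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Threads each unaligned coding sequence through its aligned protein row:
#' every amino-acid column becomes one codon column and every gap residue a
#' triple-gap codon. Each CDS must translate exactly to its ungapped protein
#' row under the universal code (a trailing stop codon on the CDS is
#' tolerated and dropped).
#'
#' @param protein_alignment Named character vector of aligned amino-acid
#'   sequences (gaps as `-`).
#' @param cds_by_taxon Named character vector of unaligned coding DNA, names
#'   matching `protein_alignment`.
#' @return A `codon_alignment`.
#' @export
#' @examples
#' backtranslate(c(t1 = "M-A"), c(t1 = "ATGGCT"))
backtranslate <- function(protein_alignment, cds_by_taxon) {
  if (!setequal(names(protein_alignment), names(cds_by_taxon)))
    stop("protein alignment and CDS sets name different taxa")
  out <- lapply(names(protein_alignment), function(tax) {
    prot <- toupper(as.character(protein_alignment[[tax]]))
    cds <- toupper(as.character(cds_by_taxon[[tax]]))
    aa <- strsplit(prot, "")[[1]]
    res <- aa[aa != "-"]
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length for taxon '", tax, "' not divisible by 3")
    n_codon <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * (seq_len(n_codon) - 1L) + 1L,
                        3L * seq_len(n_codon))
    if (n_codon == length(res) + 1L && codons[n_codon] %in% .STOP_CODONS) {
      codons <- codons[-n_codon]
      n_codon <- n_codon - 1L
    }
    if (n_codon != length(res))
      stop("CDS length for taxon '", tax, "' (", n_codon,
           " codons) does not match ungapped protein length (",
           length(res), ")")
    tr <- translate_codons(codons)
    bad <- which(tr != res)
    if (length(bad))
      stop("translation mismatch for taxon '", tax, "' at ungapped residue ",
           bad[1], ": codon ", codons[bad[1]], " -> ",
           tr[bad[1]], ", protein has ", res[bad[1]])
    row <- rep("---", length(aa))
    row[aa != "-"] <- codons
    paste0(row, collapse = "")
  })
  codon_alignment(stats::setNames(unlist(out), names(protein_alignment)))
}

#' F3x4 codon equilibrium frequencies
#'
#' Estimates the codon frequency vector from the nucleotide composition at
#' each of the three codon positions (the F3x4 model), with stop-codon mass
#' renormalized over the 61 sense codons. If any nucleotide has a zero count
#' at some codon position, a pseudocount is added to all four counts at that
#' position so every sense codon keeps positive mass.
#'
#' @param aln A `codon_alignment`.
#' @param pseudocount Count added to each nucleotide at a position whose
#'   composition contains a zero (default 0.5).
#' @return Numeric vector of length 61 summing to 1, named by codon.
#' @export
f3x4_frequencies <- function(aln, pseudocount = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"))
  ok <- !is.na(aln$idx)
  if (!any(ok)) stop("alignment has no unambiguous codons")
  cod <- aln$codon[ok]
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, .NUC))
  for (p in 1:3) {
    cnt <- table(factor(substring(cod, p, p), levels = .NUC))
    cnt <- as.numeric(cnt)
    if (any(cnt == 0)) cnt <- cnt + pseudocount
    pos_freq[p, ] <- cnt / sum(cnt)
  }
  n1 <- match(substring(.CODONS, 1, 1), .NUC)
  n2 <- match(substring(.CODONS, 2, 2), .NUC)
  n3 <- match(substring(.CODONS, 3, 3), .NUC)
  pi <- pos_freq[1, n1] * pos_freq[2, n2] * pos_freq[3, n3]
  pi <- pi / sum(pi)
  stats::setNames(pi, .CODONS)
}
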