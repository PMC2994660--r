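# Universal genetic code machinery shared by the rate matrix, the likelihood
# engine and the simulators. Codon state space: the 61 sense codons, ordered
# lexicographically over A < C < G < T.

.NUC <- c("A", "C", "G", "T")

.codon_tables <- local({
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC,
                   stringsAsFactors = FALSE)
  all64 <- paste0(g$p1, g$p2, g$p3)
  all64 <- sort(all64)
  aa64 <- unname(Biostrings::GENETIC_CODE[all64])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  stopifnot(length(sense) == 61L)

  nucmat <- do.call(rbind, strsplit(sense, ""))
  # ordered pairs (i < j) of sense codons differing at exactly one position
  pi_ <- integer(0); pj <- integer(0); ti <- logical(0); ns <- logical(0)
  for (i in 1:60) {
    for (j in (i + 1):61) {
      d <- which(nucmat[i, ] != nucmat[j, ])
      if (length(d) == 1L) {
        pi_ <- c(pi_, i); pj <- c(pj, j)
        pair <- sort(c(nucmat[i, d], nucmat[j, d]))
        ti <- c(ti, identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
        ns <- c(ns, aa[i] != aa[j])
      }
    }
  }
  list(codons = sense, aa = aa, stops = all64[aa64 == "*"],
       pair_i = pi_, pair_j = pj, pair_ti = ti, pair_ns = ns)
})

.CODONS <- .codon_tables$codons
.CODON_AA <- .codon_tables$aa
.STOP_CODONS <- .codon_tables$stops

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons, in the lexicographic
#'   (A < C < G < T) order used for all rate matrices and frequency vectors
#'   in this package.
#' @export
#' @examples
#' head(sense_codons())
sense_codons <- function() .CODONS

#' Translate codon strings under the universal code
#'
#' @param codons Character vector of 3-letter codon strings (A/C/G/T).
#' @return Character vector of one-letter amino acids, `"*"` for stop,
#'   `NA` for codons containing gaps or ambiguity characters.
#' @export
translate_codons <- function(codons) {
  i <- match(toupper(codons), .CODONS)
  out <- .CODON_AA[i]
  out[toupper(codons) %in% .STOP_CODONS] <- "*"
  out
}

# codon index (1..61) or NA for gap/ambiguous codons
.codon_index <- function(codons) match(toupper(codons), .CODONS)
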