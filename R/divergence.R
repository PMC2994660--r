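# Ortholog protein divergence: length-weighted percent identity over HSPs
# and the 5%-bin genome histogram.

#' Read tabular homology-search output (outfmt-6 style)
#'
#' Accepts the standard 12-column tab-separated format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score) or a minimal 5-column
#' form (query, subject, length, percent identity, E-value).
#'
#' @param path Path to the TSV file (no header).
#' @return Data frame with columns `query`, `subject`, `length`, `pident`,
#'   `evalue` (plus the remaining standard columns when present).
#' @export
read_hsp_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) == 12L) {
    names(x) <- c("query", "subject", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  } else if (ncol(x) == 5L) {
    names(x) <- c("query", "subject", "length", "pident", "evalue")
  } else {
    stop("expected 12-column outfmt-6 or 5-column minimal HSP table, got ",
         ncol(x), " columns")
  }
  .check_hsps(x)
  x
}

.check_hsps <- function(x) {
  stopifnot(all(x$pident >= 0 & x$pident <= 100),
            all(x$length >= 1), all(x$evalue >= 0))
  invisible(x)
}

#' Length-weighted percent identity for one ortholog pair
#'
#' Discards HSPs whose E-value exceeds the cutoff, then averages the HSP
#' percent identities weighted by HSP alignment length (gap columns
#' included, as reported by standard tabular search output - this
#' "will necessarily lead to some underestimation" of true divergence).
#'
#' @param hsps Data frame of HSPs for one query/subject pair, with columns
#'   `length`, `pident`, `evalue` (see [read_hsp_table()]).
#' @param e_cutoff E-value cutoff (default 1e-5).
#' @return A list of class `ortholog_identity`: `weighted_identity`,
#'   `total_length`, `n_hsps`, `n_filtered`, and `no_hit` (`TRUE` when all
#'   HSPs were filtered; `weighted_identity` is then `NA`).
#' @export
#' @examples
#' weighted_identity(data.frame(length = c(100, 300), pident = c(90, 70),
#'                              evalue = c(1e-9, 1e-9)))
weighted_identity <- function(hsps, e_cutoff = 1e-5) {
  stopifnot(nrow(hsps) >= 1)
  .check_hsps(hsps)
  keep <- hsps$evalue <= e_cutoff
  out <- if (!any(keep)) {
    list(weighted_identity = NA_real_, total_length = 0L, n_hsps = 0L,
         n_filtered = sum(!keep), no_hit = TRUE)
  } else {
    h <- hsps[keep, , drop = FALSE]
    list(weighted_identity = sum(h$length * h$pident) / sum(h$length),
         total_length = sum(h$length), n_hsps = nrow(h),
         n_filtered = sum(!keep), no_hit = FALSE)
  }
  structure(out, class = "ortholog_identity")
}

#' @export
print.ortholog_identity <- function(x, ...) {
  if (x$no_hit) cat("No HSP under the E-value cutoff (no-hit pair)\n")
  else cat(sprintf(
    "Weighted identity %.2f%% over %d HSPs (%d aligned columns)\n",
    x$weighted_identity, x$n_hsps, x$total_length))
  invisible(x)
}

#' Per-pair weighted identities for a full HSP table
#'
#' Groups an HSP table by query/subject pair and applies
#' [weighted_identity()] to each group.
#'
#' @inheritParams weighted_identity
#' @return Data frame with one row per pair: `query`, `subject`,
#'   `weighted_identity`, `n_hsps`, `total_length`, `no_hit`.
#' @export
summarize_ortholog_identity <- function(hsps, e_cutoff = 1e-5) {
  key <- paste(hsps$query, hsps$subject, sep = "\t")
  groups <- split(seq_len(nrow(hsps)), key)
  rows <- lapply(groups, function(i) {
    s <- weighted_identity(hsps[i, , drop = FALSE], e_cutoff)
    data.frame(query = hsps$query[i[1]], subject = hsps$subject[i[1]],
               weighted_identity = s$weighted_identity,
               n_hsps = s$n_hsps, total_length = s$total_length,
               no_hit = s$no_hit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of ortholog identities in fixed-width bins
#'
#' Bins percent identities into `[lo, lo + width)` bins over 0-100 (a value
#' of exactly 100 falls in the top bin). No-hit pairs (`NA` identity) are
#' excluded from the histogram and counted.
#'
#' @param identities Numeric vector of percent identities (0-100), e.g. the
#'   `weighted_identity` column of [summarize_ortholog_identity()].
#' @param bin_width Bin width in percent (default 5).
#' @return Data frame with `lo`, `hi`, `count`; attributes `n_na` (excluded
#'   no-hit pairs) and `bin_width`.
#' @export
identity_histogram <- function(identities, bin_width = 5) {
  stopifnot(bin_width > 0, 100 %% bin_width == 0)
  n_na <- sum(is.na(identities))
  x <- identities[!is.na(identities)]
  stopifnot(all(x >= 0 & x <= 100))
  lo <- seq(0, 100 - bin_width, by = bin_width)
  bin <- pmin(x %/% bin_width, length(lo) - 1)
  counts <- tabulate(bin + 1, nbins = length(lo))
  out <- data.frame(lo = lo, hi = lo + bin_width, count = counts)
  attr(out, "n_na") <- n_na
  attr(out, "bin_width") <- bin_width
  out
}

#' Which histogram bin holds a given identity value
#'
#' @param value Percent identity.
#' @param bin_width Bin width (default 5).
#' @return Named numeric vector `c(lo, hi)` of the containing bin.
#' @export
identity_bin <- function(value, bin_width = 5) {
  stopifnot(value >= 0, value <= 100)
  lo <- min(value %/% bin_width, 100 / bin_width - 1) * bin_width
  c(lo = lo, hi = lo + bin_width)
}
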