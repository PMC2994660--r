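# Hybrid-genome ChIP-Seq enrichment: per-base coverage, window medians,
# IP/Input ratios, region means with control normalization, correlations.
# Coordinates are 0-based half-open throughout.

#' Per-base coverage track
#'
#' @param contig Contig identifier.
#' @param counts Non-negative integer vector, one count per base.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig, counts) {
  counts <- as.numeric(counts)
  stopifnot(length(contig) == 1L, all(counts >= 0), all(is.finite(counts)))
  structure(list(contig = as.character(contig), counts = counts,
                 length = length(counts)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track %s: %d bases, median %.1f, total %.0f\n",
              x$contig, x$length, stats::median(x$counts), sum(x$counts)))
  invisible(x)
}

#' Build coverage tracks from mapped fragment intervals
#'
#' Count at base `b` = number of fragments with `start <= b < end`
#' (0-based half-open, mirroring mapped paired-end inserts).
#'
#' @param fragments Data frame with columns `contig`, `start`, `end`.
#' @param contig_lengths Named vector of contig lengths.
#' @return Named list of `coverage_track`, one per contig in
#'   `contig_lengths`.
#' @export
coverage_from_fragments <- function(fragments, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)),
            all(c("contig", "start", "end") %in% names(fragments)))
  bad <- which(fragments$start < 0 | fragments$end > unname(
    contig_lengths[fragments$contig]) | fragments$start >= fragments$end |
      !(fragments$contig %in% names(contig_lengths)))
  if (length(bad))
    stop("out-of-bounds or invalid fragment at index ", bad[1])
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    fr <- fragments[fragments$contig == ctg, , drop = FALSE]
    delta <- numeric(len + 1L)
    if (nrow(fr)) {
      d1 <- tabulate(fr$start + 1L, nbins = len + 1L)
      d2 <- tabulate(fr$end + 1L, nbins = len + 1L)
      delta <- d1 - d2
    }
    coverage_track(ctg, cumsum(delta)[seq_len(len)])
  })
  stats::setNames(out, names(contig_lengths))
}

#' Sliding-window medians of a coverage track
#'
#' Windows start at multiples of `step` from 0 and must fit entirely within
#' the contig (`end <= length`; trailing partial windows are dropped). The
#' median of an even number of bases is the mean of the two central order
#' statistics.
#'
#' @param track A `coverage_track`.
#' @param window Window size in bases (default 100).
#' @param step Step between window starts (default 50).
#' @return An object of class `window_median_track`: data frame `start`,
#'   `end`, `median` with the contig id attached.
#' @export
window_medians <- function(track, window = 100, step = 50) {
  stopifnot(inherits(track, "coverage_track"), window >= 1, step >= 1)
  if (track$length < window) {
    warning("contig ", track$contig, " shorter than window; empty track")
    out <- data.frame(start = integer(), end = integer(), median = numeric())
  } else {
    starts <- seq.int(0L, track$length - window, by = step)
    med <- vapply(starts, function(s)
      stats::median(track$counts[(s + 1L):(s + window)]), numeric(1))
    out <- data.frame(start = starts, end = starts + window, median = med)
  }
  attr(out, "contig") <- track$contig
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_median_track", "data.frame")
  out
}

#' Per-base IP/Input ratio track
#'
#' Bases with zero input coverage are masked (`NA`) rather than
#' pseudocounted; the masked fraction is attached as an attribute.
#'
#' @param ip,input `coverage_track` objects over the same contig.
#' @return Numeric vector of per-base ratios (`NA` where masked) with
#'   attributes `contig` and `masked_fraction`.
#' @export
per_base_ratio <- function(ip, input) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"))
  if (ip$contig != input$contig) stop("tracks describe different contigs")
  if (ip$length != input$length) stop("track length mismatch")
  ratio <- ifelse(input$counts > 0, ip$counts / input$counts, NA_real_)
  attr(ratio, "contig") <- ip$contig
  attr(ratio, "masked_fraction") <- mean(input$counts == 0)
  ratio
}

# windows (window_median_track rows) covering a region: >= 1 bp overlap
.covering <- function(wm, start, end) wm$start < end & wm$end > start

#' Region mean IP/Input enrichment with control normalization
#'
#' For each region, takes the IP/Input ratio of window medians over all
#' windows overlapping the region by at least 1 bp, averages them, and
#' divides by the same mean for the control region. The control region's
#' normalized ratio is exactly 1 by construction. Windows whose input
#' median is zero are dropped (counted per region). The standard error is
#' over the covering windows.
#'
#' @param ip_windows,input_windows A `window_median_track` (one contig) or
#'   a named list of them keyed by contig, on identical window grids.
#' @param regions Data frame with columns `contig`, `start`, `end`,
#'   `label` (0-based half-open; 600 bp regions conventionally - other
#'   widths draw a warning, not an error).
#' @param control Label (in `regions`) of the non-enriched control region.
#' @param expected_width Width regions are expected to have (default 600).
#' @return Data frame of class `enrichment_summary`: `label`, `n_windows`,
#'   `n_zero_input`, `mean_ratio`, `se`, `normalized`, `is_control`.
#' @export
region_enrichment <- function(ip_windows, input_windows, regions, control,
                              expected_width = 600) {
  as_list <- function(x) {
    if (inherits(x, "window_median_track"))
      stats::setNames(list(x), attr(x, "contig"))
    else x
  }
  ipw <- as_list(ip_windows); inw <- as_list(input_windows)
  stopifnot(all(c("contig", "start", "end", "label") %in% names(regions)))
  if (!control %in% regions$label)
    stop("control label '", control, "' not found among regions")
  if (any(regions$end - regions$start != expected_width))
    warning("some regions are not ", expected_width, " bp wide")

  one_region <- function(i) {
    ctg <- regions$contig[i]
    if (!ctg %in% names(ipw) || !ctg %in% names(inw))
      stop("no window tracks for contig '", ctg, "'")
    wi <- ipw[[ctg]]; wn <- inw[[ctg]]
    if (!identical(wi$start, wn$start))
      stop("IP and input window grids differ on contig '", ctg, "'")
    cov <- which(.covering(wi, regions$start[i], regions$end[i]))
    if (!length(cov))
      stop("region '", regions$label[i], "' has no covering windows")
    nz <- wn$median[cov] > 0
    r <- wi$median[cov][nz] / wn$median[cov][nz]
    if (!length(r))
      stop("region '", regions$label[i], "' has only zero-input windows")
    list(n = length(r), n_zero = sum(!nz), mean = mean(r),
         se = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_)
  }
  res <- lapply(seq_len(nrow(regions)), one_region)
  ctrl_mean <- res[[match(control, regions$label)]]$mean
  out <- data.frame(label = regions$label,
                    n_windows = vapply(res, `[[`, numeric(1), "n"),
                    n_zero_input = vapply(res, `[[`, numeric(1), "n_zero"),
                    mean_ratio = vapply(res, `[[`, numeric(1), "mean"),
                    se = vapply(res, `[[`, numeric(1), "se"))
  out$normalized <- out$mean_ratio / ctrl_mean
  out$is_control <- out$label == control
  class(out) <- c("enrichment_summary", "data.frame")
  out
}

#' Genome-wide correlation of window medians between two datasets
#'
#' Pearson correlation over paired window medians, concatenated across
#' contigs. The two collections must share the same window grids.
#'
#' @param a,b A `window_median_track` or named list of them (same contigs).
#' @return The Pearson correlation coefficient.
#' @export
window_correlation <- function(a, b) {
  as_list <- function(x) {
    if (inherits(x, "window_median_track"))
      stats::setNames(list(x), attr(x, "contig"))
    else x
  }
  la <- as_list(a); lb <- as_list(b)
  if (!setequal(names(la), names(lb)))
    stop("window collections cover different contigs")
  va <- numeric(0); vb <- numeric(0)
  for (ctg in sort(names(la))) {
    if (!identical(la[[ctg]]$start, lb[[ctg]]$start))
      stop("window grids differ on contig '", ctg, "'")
    va <- c(va, la[[ctg]]$median)
    vb <- c(vb, lb[[ctg]]$median)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in window medians; correlation undefined")
  stats::cor(va, vb)
}

#' Concatenate two genomes into a hybrid genome FASTA
#'
#' Emits all contigs of genome A then genome B with species-prefixed names
#' and returns a manifest mapping prefixed contig names to their source.
#'
#' @param genome_a,genome_b Paths to FASTA files.
#' @param prefix_a,prefix_b Prefixes (e.g. `"Sc_"`, `"Sb_"`).
#' @param out Path for the hybrid FASTA.
#' @return Invisibly, a manifest data frame with `contig` (prefixed name)
#'   and `source` (`"A"` or `"B"`).
#' @export
concat_hybrid_genome <- function(genome_a, genome_b, prefix_a, prefix_b,
                                 out) {
  a <- Biostrings::readBStringSet(genome_a)
  b <- Biostrings::readBStringSet(genome_b)
  strip <- function(nm) sub("\\s.*$", "", nm)
  if (length(a)) names(a) <- paste0(prefix_a, strip(names(a)))
  if (length(b)) names(b) <- paste0(prefix_b, strip(names(b)))
  both <- c(a, b)
  if (anyDuplicated(names(both)))
    stop("duplicate contig names after prefixing: ",
         names(both)[duplicated(names(both))][1])
  Biostrings::writeXStringSet(both, out)
  manifest <- data.frame(contig = names(both),
                         source = rep(c("A", "B"), c(length(a), length(b))))
  invisible(manifest)
}

#' Read a bedGraph-like coverage file as per-base tracks
#'
#' Four tab-separated columns (contig, start, end, value; 0-based
#' half-open), expanded to one value per base. Uncovered bases are 0.
#'
#' @param path Path to the bedGraph file.
#' @param contig_lengths Optional named vector; defaults to the maximum
#'   `end` seen per contig.
#' @return Named list of `coverage_track`.
#' @export
read_bedgraph <- function(path, contig_lengths = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "start", "end", "value"),
                         stringsAsFactors = FALSE)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(split(x$end, x$contig), max, numeric(1))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    v <- numeric(len)
    xx <- x[x$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(xx)))
      v[(xx$start[i] + 1):xx$end[i]] <- xx$value[i]
    coverage_track(ctg, v)
  })
  stats::setNames(out, names(contig_lengths))
}

#' Write coverage tracks as a bedGraph file
#'
#' Runs of equal counts are collapsed into single intervals.
#'
#' @param tracks A `coverage_track` or named list of them.
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    r <- rle(tr$counts)
    end <- cumsum(r$lengths)
    data.frame(contig = tr$contig, start = c(0L, end[-length(end)]),
               end = end, value = r$values)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like region file
#'
#' Columns: contig, start, end, label, and optionally role
#' (`query`/`control`). 0-based half-open coordinates.
#'
#' @param path Path to the BED-like file.
#' @return Data frame with `contig`, `start`, `end`, `label` (and `role`
#'   when present).
#' @export
read_regions <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("region file needs at least 4 columns")
  names(x)[1:4] <- c("contig", "start", "end", "label")
  if (ncol(x) >= 5) names(x)[5] <- "role"
  stopifnot(all(x$start >= 0), all(x$end > x$start))
  x[seq_len(min(5, ncol(x)))]
}
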