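# Sliding-window dN/dS scan and the empirical genome-window null.

#' Enumerate codon-frame alignment windows
#'
#' Windows are 0-based half-open intervals in alignment nucleotide
#' coordinates, starting at 0, `step`, `2*step`, ... with `end <= `
#' alignment length. Both size and step must be multiples of 3 so windows
#' hold whole codons. A window is gap-free when no taxon has a gap
#' character in any of its codon columns; gapped windows are retained in
#' the table but flagged, and the exclusion count is attached.
#'
#' @param aln A `codon_alignment`.
#' @param window_size Window width in nucleotides (default 102 = 34 codons).
#' @param step Step between window starts in nucleotides (default 3).
#' @return Data frame with `start`, `end`, `first_codon`, `n_codons`,
#'   `gap_free`; attribute `n_excluded` counts gapped windows.
#' @export
#' @examples
#' aln <- simulate_codon_alignment(sensu_stricto_tree(), 300, seed = 1)$alignment
#' nrow(enumerate_windows(aln))  # (900 - 102)/3 + 1 = 267
enumerate_windows <- function(aln, window_size = 102, step = 3) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (window_size %% 3L != 0L || step %% 3L != 0L)
    stop("window_size and step must be divisible by 3 (codon frame)")
  if (window_size > aln$nuc_length) {
    warning("window_size exceeds alignment length; no windows")
    out <- data.frame(start = integer(), end = integer(),
                      first_codon = integer(), n_codons = integer(),
                      gap_free = logical())
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  starts <- seq.int(0L, aln$nuc_length - window_size, by = step)
  n_codons <- window_size %/% 3L
  first_codon <- starts %/% 3L + 1L
  gap_col <- apply(aln$gap, 2, any)
  gap_cum <- c(0L, cumsum(gap_col))
  gap_in <- gap_cum[first_codon + n_codons] - gap_cum[first_codon] > 0L
  out <- data.frame(start = starts, end = starts + window_size,
                    first_codon = first_codon, n_codons = n_codons,
                    gap_free = !gap_in)
  attr(out, "n_excluded") <- sum(gap_in)
  out
}

# one-window M0 fit used by both the scan and the empirical null
.fit_window <- function(aln, sites, tree, mode, pi, omega_cap) {
  sub <- .subset_sites(aln, sites)
  fit <- tryCatch(
    fit_m0(sub, tree, optimize_branch_lengths = (mode == "refit-all"),
           pi = pi, omega_cap = omega_cap,
           starts = list(c(2, 0.4), c(2, 0.05))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(omega = NA_real_, kappa = NA_real_, lnL = NA_real_,
                converged = FALSE, capped = FALSE, zero_divergence = FALSE,
                failed = TRUE))
  list(omega = fit$omega, kappa = fit$kappa, lnL = fit$lnL,
       converged = fit$converged, capped = fit$capped,
       zero_divergence = fit$zero_divergence, failed = FALSE)
}

#' Sliding-window dN/dS scan
#'
#' Fits the single-ratio (M0) model in each gap-free window of the
#' alignment. In the default `"fixed-branch-lengths"` mode a whole-gene M0
#' fit supplies the branch lengths, and each window estimates kappa and
#' omega; `"refit-all"` re-estimates branch lengths per window as well.
#' Codon frequencies are the whole-alignment F3x4 vector in both modes
#' (34-codon windows are too short for stable frequency estimates). Window
#' fits that fail are flagged and do not abort the scan.
#'
#' @inheritParams enumerate_windows
#' @param tree Tree with branch lengths in substitutions per codon.
#' @param mode `"fixed-branch-lengths"` (default) or `"refit-all"`.
#' @param gene_fit Optional whole-gene M0 `codon_fit` supplying branch
#'   lengths and frequencies; computed if missing.
#' @param omega_cap Sentinel cap for per-window omega (default 99).
#' @return An object of class `omega_scan`: the window table with per-window
#'   `omega`, `kappa`, `lnL` and flags, plus a `summary` list (median, min,
#'   max, fraction of windows with omega > 1) and the scan settings.
#' @export
scan_omega <- function(aln, tree, window_size = 102, step = 3,
                       mode = c("fixed-branch-lengths", "refit-all"),
                       gene_fit = NULL, omega_cap = 99) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "codon_alignment"))
  .check_tree(tree, aln$taxa)
  win <- enumerate_windows(aln, window_size, step)
  if (!any(win$gap_free)) stop("no gap-free windows to scan")
  if (is.null(gene_fit))
    gene_fit <- fit_m0(aln, tree, optimize_branch_lengths = TRUE)
  use_tree <- if (mode == "fixed-branch-lengths") gene_fit$tree else tree
  pi <- gene_fit$pi

  rows <- which(win$gap_free)
  res <- lapply(rows, function(r) {
    sites <- win$first_codon[r]:(win$first_codon[r] + win$n_codons[r] - 1L)
    .fit_window(aln, sites, use_tree, mode, pi, omega_cap)
  })
  for (f in c("omega", "kappa", "lnL")) {
    win[[f]] <- NA_real_
    win[[f]][rows] <- vapply(res, `[[`, numeric(1), f)
  }
  for (f in c("converged", "capped", "zero_divergence", "failed")) {
    win[[f]] <- NA
    win[[f]][rows] <- vapply(res, `[[`, logical(1), f)
  }
  om <- win$omega[rows]
  om <- om[!is.na(om)]
  structure(list(windows = win,
                 summary = list(median_omega = stats::median(om),
                                min_omega = if (length(om)) min(om) else NA,
                                max_omega = if (length(om)) max(om) else NA,
                                frac_gt1 = mean(om > 1),
                                n_windows = length(om),
                                n_excluded = attr(win, "n_excluded")),
                 mode = mode, window_size = window_size, step = step),
            class = "omega_scan")
}

#' @export
print.omega_scan <- function(x, ...) {
  s <- x$summary
  cat("dN/dS window scan (", x$window_size, " nt windows, step ", x$step,
      ", mode ", x$mode, ")\n", sep = "")
  cat(sprintf("  %d windows fit (%d gapped excluded)\n",
              s$n_windows, s$n_excluded))
  cat(sprintf("  median omega %.4f, range [%.4f, %.4f], %.1f%% with omega > 1\n",
              s$median_omega, s$min_omega, s$max_omega, 100 * s$frac_gt1))
  invisible(x)
}

#' Empirical genome-window null distribution of window dN/dS
#'
#' Pools the gap-free windows of a collection of background gene
#' alignments, samples `n_windows` of them uniformly without replacement
#' (seeded), fits M0 in each, and records the sample, its median and its
#' central 95% interval. The interval bounds are order statistics of the
#' stored sample.
#'
#' @param gene_alignments Named list of `codon_alignment` objects.
#' @param tree Tree shared by all genes.
#' @param n_windows Target sample size (default 1500). If the pool is
#'   smaller, all windows are used with a warning.
#' @param window_size,step As in [enumerate_windows()].
#' @param seed Integer seed for the window sample.
#' @param mode Per-window fit mode, as in [scan_omega()].
#' @param omega_cap Sentinel cap.
#' @return An object of class `empirical_null` with the sampled `omega`
#'   values, `median`, `ci` (2.5% and 97.5% order statistics), `n`, `seed`
#'   and per-window source gene ids.
#' @export
build_empirical_null <- function(gene_alignments, tree, n_windows = 1500,
                                 window_size = 102, step = 3, seed = 1,
                                 mode = "fixed-branch-lengths",
                                 omega_cap = 99) {
  stopifnot(length(gene_alignments) >= 1)
  if (is.null(names(gene_alignments)))
    names(gene_alignments) <- sprintf("gene%03d", seq_along(gene_alignments))
  pool <- do.call(rbind, lapply(names(gene_alignments), function(g) {
    w <- enumerate_windows(gene_alignments[[g]], window_size, step)
    w <- w[w$gap_free, c("start", "first_codon", "n_codons"), drop = FALSE]
    if (nrow(w)) cbind(gene = g, w) else NULL
  }))
  if (is.null(pool) || nrow(pool) == 0) stop("no gap-free windows in pool")
  if (nrow(pool) < n_windows) {
    warning("pool has only ", nrow(pool), " gap-free windows; using all")
    take <- seq_len(nrow(pool))
  } else {
    take <- .with_seed(seed, sample.int(nrow(pool), n_windows))
  }
  sel <- pool[take, , drop = FALSE]

  gene_fits <- lapply(gene_alignments, fit_m0, tree = tree,
                      optimize_branch_lengths = TRUE)
  om <- vapply(seq_len(nrow(sel)), function(i) {
    g <- sel$gene[i]
    sites <- sel$first_codon[i]:(sel$first_codon[i] + sel$n_codons[i] - 1L)
    .fit_window(gene_alignments[[g]], sites, gene_fits[[g]]$tree,
                "fixed-branch-lengths", gene_fits[[g]]$pi, omega_cap)$omega
  }, numeric(1))
  ok <- !is.na(om)
  so <- sort(om[ok])
  n <- length(so)
  lo <- so[max(1L, ceiling(0.025 * n))]
  hi <- so[min(n, ceiling(0.975 * n))]
  structure(list(omega = om[ok], median = stats::median(so),
                 ci = c(lower = lo, upper = hi), n = n, seed = seed,
                 sources = sel$gene[ok], window_size = window_size),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf(
    "Empirical window null: n = %d, median omega = %.4f, 95%% in [%.4f, %.4f]\n",
    x$n, x$median, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Summarize a window scan against the empirical null
#'
#' @param scan An `omega_scan`.
#' @param null An `empirical_null`.
#' @param beb Optional `site_posteriors` table; flagged codons are mapped
#'   onto window coordinates.
#' @return A list: scan and null medians, fraction of scan windows above
#'   the null upper 97.5% bound, fraction with omega > 1, flagged codon
#'   positions (alignment codon index and nucleotide midpoint), and a
#'   plot-ready table of (window midpoint, omega).
#' @export
summarize_scan <- function(scan, null = NULL, beb = NULL) {
  stopifnot(inherits(scan, "omega_scan"))
  win <- scan$windows
  ok <- !is.na(win$omega)
  out <- list(scan_median = scan$summary$median_omega,
              frac_gt1 = scan$summary$frac_gt1,
              n_windows = scan$summary$n_windows,
              plot_table = data.frame(
                midpoint = (win$start[ok] + win$end[ok]) / 2,
                omega = win$omega[ok]))
  if (!is.null(null)) {
    stopifnot(inherits(null, "empirical_null"))
    out$null_median <- null$median
    out$null_ci <- null$ci
    out$frac_above_null_upper <- mean(win$omega[ok] > null$ci["upper"])
  }
  if (!is.null(beb)) {
    fl <- beb$site[beb$flagged]
    out$flagged_codons <- data.frame(codon = fl,
                                     nuc_midpoint = 3 * (fl - 1) + 1.5)
  }
  out
}
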