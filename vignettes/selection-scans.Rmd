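---
title: "Codon-model selection scans and windowed ChIP enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection scans and windowed ChIP enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscan)
```

coevoscan asks two kinds of questions about rapidly evolving loci. First,
at the sequence level: is a protein-coding gene — for instance a yeast
silencing factor diverging between closely related *Saccharomyces*
species — evolving under positive selection, and if so, at which codons
and on which lineages? Second, at the chromatin level: where does a
protein bind in a genome, measured as ChIP-Seq immunoprecipitate coverage
relative to input chromatin over a hybrid (two-species) genome? This
vignette records the models behind each answer, the tunable parameters
and their defaults, the numerical strategy, and what the synthetic-data
calibration does and does not demonstrate.

## The codon substitution model

All selection analyses rest on a Goldman-Yang-type Markov model on the 61
sense codons of the universal genetic code (stop codons are excluded from
the state space; the species of interest are nuclear yeast genes). The
instantaneous rate from codon $i$ to codon $j$ is

$$ q_{ij} = \begin{cases}
  0 & \text{more than one nucleotide differs} \\
  \pi_j & \text{synonymous transversion} \\
  \kappa \pi_j & \text{synonymous transition} \\
  \omega \pi_j & \text{nonsynonymous transversion} \\
  \kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases} $$

where $\kappa > 0$ is the transition/transversion rate ratio,
$\omega \ge 0$ the nonsynonymous/synonymous rate ratio (dN/dS), and
$\pi$ the codon equilibrium frequencies. $Q$ is scaled so that
$-\sum_i \pi_i q_{ii} = 1$: branch lengths are expected substitutions per
codon. $\omega < 1$ indicates purifying selection, $\omega = 1$
neutrality, $\omega > 1$ positive selection.

**Codon frequencies.** $\pi$ defaults to F3x4: the product of the
empirical nucleotide compositions at the three codon positions,
renormalized over sense codons. The choice is a convention, not an
inference; it is exposed as the `pi` argument everywhere. When a position
composition contains a zero count, a pseudocount of 0.5 is added to all
four counts at that position so no sense codon loses support.

**Likelihood.** Site likelihoods are computed by Felsenstein pruning with
transition probabilities $P(t) = e^{Qt}$ obtained by eigendecomposition of
the reversible rate matrix. Gap codons and ambiguous codons are missing
data (partial-likelihood vectors of ones); a column that is entirely gaps
contributes nothing. In-frame stop codons are rejected at load time
unless explicitly masked. Identical site patterns are collapsed and
weighted. With at most ten taxa the per-site likelihoods stay far from
the underflow threshold, so no per-node rescaling is performed; trees
with hundreds of tips are outside the intended scale of the package.

## Model hierarchy

* **M0** (`fit_m0`): one $\omega$ for all sites and branches. Parameters
  $\kappa$, $\omega$, optionally all branch lengths.
* **M7** (`fit_m7`): site $\omega \sim \mathrm{Beta}(p, q)$ on $(0, 1)$,
  discretized into $K = 10$ equal-probability classes represented by
  their class means (not medians); the site likelihood averages the class
  conditional likelihoods.
* **M8** (`fit_m8`): with probability $p_0$ a site follows the M7 beta;
  with probability $1 - p_0$ it has $\omega_s \ge 1$. The constraint
  $\omega_s \ge 1$ makes the M7-vs-M8 comparison one-sided toward
  positive selection; a fit driving $p_0 \to 1$ is a legitimate boundary
  result.
* **Free-ratio** (`fit_free_ratio`): an independent $\omega$ per branch,
  shared $\kappa$; branches are keyed by their child node. An unrooted
  five-taxon tree has seven branches.

**Common mixture scaling.** Within the site-mixture models all classes
share one overall scale factor: writing the unscaled flux as
$\nu(\omega) = \nu_s + \omega\,\nu_n$ (synonymous and nonsynonymous
parts), class $k$ multiplies the branch lengths by
$\nu(\omega_k) / \bar\nu$ with $\bar\nu$ the mixture average. Branch
lengths therefore remain expected substitutions per codon averaged over
sites, and — as in real data — codons under positive selection accumulate
more substitutions than conserved codons, which is precisely the signal
the site tests and the Bayes Empirical Bayes posteriors exploit. The
simulator uses the same convention, so round-trip recovery is a test of
inference, not of a private convention.

**Hypothesis tests.** `lrt_m7_m8` refers $2(\ell_8 - \ell_7)$, clipped at
zero, to $\chi^2_2$, the conventional reference for this comparison,
kept even though boundary theory suggests a mixture null. Because the null pins
$p_0$ and $\omega_s$ to a boundary, the $\chi^2_2$ reference
under-rejects: in the shipped calibration study the measured size at
$\alpha = 0.05$ is well below the nominal level (around half a percent),
so a significant result errs on the safe side; the calibration test
checks above all that the test is not anti-conservative. `constrain_equal_and_compare` likewise tests the
free-ratio model against M0 with branches$-1$ degrees of freedom — the
package's operationalization of "is any branch-specific shift supported",
since a per-branch test is not uniquely defined.

**BEB posteriors.** `beb_site_posteriors` integrates the per-site
probability that $\omega > 1$ over a uniform grid prior on the M8
parameters: ten values each for $p_0$ (midpoints of $[0,1]$), $p$ and $q$
(midpoints of $(0,2]$), and $\omega_s$ (midpoints of $[1,11]$), weighting
each grid cell by its data likelihood. Branch lengths, $\kappa$ and the
overall rate scale are held at the M8 estimates; only the mixture weights
and positions vary across the grid. The table reports, per codon column,
$P(\omega > 1)$, the posterior mean $\omega$, a flag at the chosen
threshold (0.75 by default, a conventional level for highlighting
candidate sites while reserving 0.95 for significance claims), and
optionally the amino-acid numbering of a reference sequence.

## Optimization and numerics

Fits maximize the log-likelihood with box-constrained quasi-Newton
(L-BFGS-B) on log-transformed parameters ($\mathrm{logit}$ for $p_0$;
$\log(\omega_s - 1)$ keeps the selected class at or above 1), from a
small fixed set of starting points; the best of the runs is returned with
a convergence flag and the evaluation count. $\omega$ is bounded in
$[10^{-4}, 99]$: a window or branch with no synonymous divergence reports
the capped sentinel 99 (flagged `capped`) rather than infinity, and an
alignment with no divergence at all reports `NA` with the
`zero_divergence` flag. M8 starting points include the M7 optimum placed
on the $p_0 \to 1$ boundary, which enforces the nesting inequality
$\ell_8 \ge \ell_7$ up to optimizer tolerance.

**Two engines for the site mixtures.** The `exact` engine recomputes all
class conditional likelihoods by pruning at every optimizer step and
co-estimates $\kappa$ (and, on request, branch lengths — the slowest,
most faithful mode). The `grid` engine first tabulates per-site
log-likelihoods on a fixed lattice of 40 $\omega$ values (uniform in
$\log(\omega + 0.01)$ over $[10^{-4}, 15]$) by 19 branch-scale values
(log-spaced over $[0.2, 32]$), holding $\kappa$ and branch lengths at
supplied values (conventionally the M0 estimates), then evaluates any
mixture by bilinear interpolation. On five-taxon, 500-codon data the
interpolation error is a few log-likelihood units per model and mostly
cancels in the M7-M8 difference (statistic error well under one unit);
in exchange, a full M7+M8 fit costs a fraction of a second, which is what
makes 200-replicate calibration studies and the BEB integration
desk-scale. The BEB computation always uses the grid.

## Sliding-window scan and the empirical null

`scan_omega` fits M0 in windows of 102 nt (34 codons) sliding by 3 nt,
a resolution fine enough to localize codon-level signal while keeping
enough codons per window to estimate a rate ratio. Windows are 0-based
half-open in alignment nucleotide coordinates, start at multiples of the
step from 0 (the phase is a convention), and must contain whole codons. A window is analyzed only if **no
taxon has a gap character in any of its columns** — the strictest reading
of "windows without gaps" — and the number excluded is reported.
Ambiguous codons do not exclude a window; they are just missing data.

Per-window fits default to `fixed-branch-lengths` mode: a whole-gene M0
fit supplies branch lengths (and the F3x4 vector — 34-codon windows are
too short for stable frequency estimates), and each window estimates its
own $\kappa$ and $\omega$. `refit-all` additionally re-estimates branch
lengths per window; the mode is recorded in the result. Window estimates
in short windows are noisy by construction; the scan summary therefore
leads with the median and the fraction of windows above 1.

Because a 34-codon $\hat\omega$ has a heavy right tail, raw scan values
need a reference distribution. `build_empirical_null` pools all gap-free
windows of a collection of background genes, samples `n_windows`
(default 1500) uniformly without replacement under a recorded seed, fits
M0 in each, and reports the median and the central 95% interval as order
statistics of the sample. Null windows could equally be drawn pooled
across genes or per gene; pooled uniform sampling is the package's
convention. `summarize_scan` then reports the scan median against
the null median, the fraction of scan windows above the null's 97.5%
bound, and maps BEB-flagged codons onto window coordinates as a
plot-ready table.

## Divergence summaries

`weighted_identity` reproduces the standard protein-divergence summary:
discard HSPs with E-value above $10^{-5}$, then average HSP percent
identities weighted by HSP alignment length. Lengths include gap columns
as reported by tabular search output; this "will necessarily lead to
some underestimation" of true divergence — rank order is
what the histogram consumes. `identity_histogram` bins pairs into
$[l, l+5)$ bins over 0-100 (a pair at exactly 100 falls in the top bin);
no-hit pairs are excluded and counted. Reducing a many-to-many hit table
to one subject per query is an ortholog-assignment problem in its own
right; `summarize_ortholog_identity` simply summarizes every
query-subject pair it is given, leaving ortholog assignment to the
caller.

## ChIP window enrichment over a hybrid genome

The ChIP arm starts after read mapping (mapping itself is out of scope):
inputs are per-base coverage, bedGraph intervals, or mapped fragment
intervals, over a genome built by `concat_hybrid_genome` (species-prefixed
contig names plus a manifest). All coordinates are 0-based half-open.

The pipeline follows the windowed enrichment procedure: per-base
counts; medians in
100 bp windows sliding by 50 bp (windows start at multiples of 50 and
must fit within the contig — no partial trailing windows; the median of
an even count is the mean of the central order statistics); per-base
IP/Input ratios with zero-input bases masked rather than pseudocounted
(window medians are robust to isolated zeros); and region-level
enrichment: for each (conventionally 600 bp) region, the mean over all
windows overlapping it by at least one base of the ratio of window
medians, normalized by the same mean over a non-enriched control region,
with the standard error taken over covering windows. The control
normalizes to exactly 1 by construction, and normalized ratios are
invariant to rescaling either library's depth. Region means can
reasonably be taken over window-median ratios or over averaged per-base
ratios; the window-median reading is the default (medians are robust to
isolated extreme bases), with a per-base variant available. `window_correlation` gives the genome-wide Pearson correlation
of window medians between datasets, the usual replicate-agreement
measure for coverage data.

## Synthetic data: what it emulates and what it does not

`simulate_codon_alignment` evolves codon sites along a tree: root states
from $\pi$, branch transitions from the scaled rate matrix, site $\omega$
drawn once per site from the model's mixture (beta draws use a fine
50-class discretization) and held fixed across the tree, matching the
site-model assumption. `simulate_chip_experiment` draws per-base counts
— negative binomial with dispersion 0.1 by default, since real ChIP
coverage is overdispersed; Poisson for oracle checks — around a mean of
`input_depth` for input and `ip_depth` times the planted fold inside
enriched regions for IP. Every generator takes an explicit seed and is
reproducible; none touches the caller's RNG stream.

Default study conditions, chosen once: a five-taxon tree with the sensu
stricto topology and branch lengths totalling 1.12 substitutions per
codon (`sensu_stricto_tree()`, the scale of a rapidly evolving gene);
M7-null calibration at $\mathrm{Beta}(0.5, 2)$ (mean site $\omega$ 0.2
with mass near both 0 and 1); the planted-selection gene with $p_0 =
0.95$, $\omega_s = 5$, whose mixture mean $\approx 0.44$ matches the
whole-gene dN/dS scale of a rapidly evolving silencing gene; ChIP depths
of 30x input and 10x IP (typical silencing-factor library depths) and
planted folds on the silencer scale (7-18.6).

Simulated data are idealized in ways real data are not: sites are
independent with no alignment error, the tree and frequencies are
homogeneous, coverage has no mappability or GC structure, and fragments
are uncorrelated between adjacent bases. Passing recovery and
calibration tests therefore certifies the estimators and the pipeline
plumbing under the stated generative models — not robustness to
misalignment, model misspecification, or mapping artifacts. The
replicate-correlation check is likewise driven by planted structure;
real genome-wide correlations also reflect shared coverage biases.
Expectations that depend on unrecorded simulation settings elsewhere
(such as the fraction of high-$\omega$ windows expected by chance) are
reported under this package's stated settings only. Reproducing the published gene-specific
numbers requires the external sequence data described in `repro/`.

## Problem sizes used by the shipped studies

The test-suite and acceptance studies run at: likelihood oracles on trees
of 2-4 tips and up to 3 sites; M0 recovery over 20 replicates of 1000
codons for each $\omega \in \{0.1, 0.44, 1.0\}$; LRT size over 200
replicates of 500 codons and power over 50 replicates of 1000 codons
(grid engine, branch lengths at generating values, $\kappa$ at its M0
estimate — calibration is conditional on the known tree); BEB recovery on
a 1000-codon gene with 5% of sites at $\omega_s = 5$; a 1200-codon
homogeneous window scan (1167 windows); a 1500-window empirical null from
30 background genes; and ChIP contigs of 6-50 kb. These sizes make the
whole battery reproducible on a single CPU while keeping Monte Carlo
error well inside the asserted bands.
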