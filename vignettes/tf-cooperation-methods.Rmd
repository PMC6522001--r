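---
title: "Detecting tissue-specific transcription factor cooperation from promoter motif co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue-specific transcription factor cooperation from promoter motif co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoop)
```

## The problem

Transcription factors (TFs) rarely act alone: tissue identity is largely
maintained by *pairs* (or larger complexes) of TFs binding near each other
in regulatory DNA. `tfcoop` infers such cooperations from two ingredients a
typical RNA-seq-era study already has: expression tables across tissues,
and promoter sequences. The workflow is:

1. select **tissue-specific genes** (TSGs) per tissue from expression
   matrices,
2. build a tissue-filtered, non-redundant **PWM library** of expressed TFs,
3. predict **binding sites** on the TSG promoters by log-odds scanning,
4. score every TF pair's **co-occurrence** at biologically plausible
   spacings with pointwise mutual information (PMI) and keep pairs with
   z-score at least 3,
5. subtract each pair's **background cooperation level** estimated from
   shuffled sequences to separate tissue-specific from generally important
   pairs, and
6. assemble the specific pairs into per-tissue **cooperation networks**.

Everything is testable end to end on synthetic data with planted ground
truth; the generators are first-class, seeded package functions.

## Tissue-specific gene selection

A gene $g$ is specific for tissue $t$ when

$$x_{g,t} \ge f \cdot \sum_{t'} x_{g,t'}, \qquad f = 2/3 \text{ by default},$$

with $x$ the replicate-averaged expression (TPM or RPKM). The boundary is
inclusive, matching the convention that a value *equal* to the fraction
qualifies; all-zero genes are assigned nowhere. Because $2/3 > 1/2$, a gene
can be specific for at most one tissue. Replicates are combined by the
arithmetic mean before the rule is applied — the simplest unit-preserving
choice; it is exposed through `aggregate_by_tissue()` should a study need a
robust alternative.

Genes never expressed above a threshold $\tau$ in any sample are removed
first. $\tau$ can be fixed (1.46 on the TPM scale is the conventional
default carried by `default_parameters()`) or estimated by
`estimate_threshold()`: all values are pooled, a Gaussian KDE with Scott's
bandwidth is fitted on the compressed axis $\log_{10}(x + 10^{-3})$ over a
512-point grid, and $\tau$ is the value at the first local minimum between
the two largest modes, mapped back to the original scale. The compression
is what makes the expressed/unexpressed bimodality visible; with a
unimodal density the function refuses and points the user to the fixed
mode. When a study spans several datasets the threshold is a per-dataset
setting, since units and depth differ; externally published TSG lists can
be imported as-is with `read_tsg()` instead of being recomputed. For
tissues covered by several datasets, `combine_tsg()` intersects the
per-dataset TSG lists according to an explicit per-tissue policy, which
compensates for experimental and between-animal variation.

## The motif library

PWMs are read from TRANSFAC flat files or JASPAR PFM records
(`parse_matrices()`), mapped to TF genes through a user-supplied
two-column table (no identifier translation is attempted), and normalized
to column probabilities with a pseudocount of 0.01 per cell — enough to
avoid infinite log-odds, negligible against real count matrices.

Two filters shape the per-tissue library:

* **Expression**: a motif is kept when at least one of its TF genes has
  expression $\ge \tau$ in the tissue (`filter_by_tf_expression()`; the
  boundary value is kept, only strictly smaller values are discarded).
  Restricting the library to expressed TFs is the main guard against the
  well-known false-positive burden of PWM scanning.
* **Redundancy**: motifs are compared by best-overlap Pearson correlation
  (`pwm_correlation()`): all ungapped offsets with at least
  `min(3, L)` overlapping columns, both orientations, flattened columns,
  maximum over alignments. Average-linkage hierarchical clustering on
  $1 - r$, cut at $1 - 0.8$, keeps the highest-information-content PWM per
  cluster (ties broken by motif id). Linkage and cut height are design
  choices, not forced by theory; both are exposed. One caveat found
  during development and worth knowing: for libraries of short, very
  sharp motifs, 3-column overlaps correlate near 1 by chance, so the
  minimum overlap (`min_overlap`) should be raised towards the motif
  length — the synthetic study preset uses 8.

## Binding-site prediction

`scan_sites()` slides each PWM over both strands (single-strand scanning
is a flag; both is the vertebrate-PWM convention) and reports every window
whose log-odds score

$$s = \sum_i \log_2 \frac{p_i(b_i)}{q(b_i)}$$

reaches the motif's cutoff, in 0-based half-open plus-strand coordinates.
Windows containing N are skipped.

Cutoffs are calibrated per motif by the min(FPR + FNR) rule
(`calibrate_threshold()`): positives are words sampled from the PWM's own
column distributions, negatives are words from a 2nd-order Markov model
fitted to the input promoters (sensitivity to nucleotide composition is
exactly why the negative model is fitted, not uniform), and the cutoff is
the midpoint between adjacent distinct observed scores minimizing the
summed error rates. Among tied candidates the largest (most stringent)
cutoff is chosen. The default sample size is 3000 per class in the
workflow wrappers: the cutoff location depends on extreme order statistics
of the sampled scores, and smaller samples make the realized
false-positive density noticeably run-to-run variable. The sampled scores
are kept on the returned object so the optimality of the cutoff can be
re-verified exhaustively, which the test suite does.

## PMI scoring of TF pairs

Two sites on the same promoter form a candidate dimer when the gap
between them — start of the downstream site minus end of the upstream
site — lies in $[d_{\min}, d_{\max}]$, 5–20 bp by default (the recommended
distance preferences for functionally cooperating TFs). Overlapping site
pairs are excluded unless explicitly allowed; distinct motifs hitting the
same position are legal sites, only the pair gap is constrained. The gap
is measured end-to-start (bp of free sequence between the sites); a
start-to-start alternative would shift the window by one motif length and
is intentionally not the default, since the biological statement is about
spacing *between* the bound footprints.

With $N$ counted pairs, pair counts $N_{ab}$ and slot counts
$S_a$ (homodimer pairs occupy two slots of the same motif):

$$f_{ab} = N_{ab}/N, \quad f_a = S_a/2N, \quad
\mathrm{PMI}(a,b) = \ln \frac{f_{ab}}{c \, f_a f_b}, \quad
c = \begin{cases} 2 & a \ne b \\ 1 & a = b \end{cases}$$

This slot formulation makes PMI exactly zero when the two slots of a pair
are filled independently — a property the test suite verifies directly by
permuting motif labels over fixed site positions — and handles homodimers
coherently through the factor $c$. Natural logarithm; any other base would
rescale all PMIs jointly and leave the subsequent ranking unchanged.
Pairs never observed are not scored (their PMI would be $-\infty$).
`zscore_transform()` centers and scales the scored PMIs with the
population SD; a cooperation is significant at $z \ge 3$ (boundary
inclusive). Counting is a global multiset count over all promoters; a
per-sequence weighting variant would be a different estimator and is out
of scope.

## Specific versus generally important pairs

Significant pairs still mix genuine distance-coupled cooperation with
pairs that co-occur merely because both motifs are frequent or because
the promoter set's composition favors them. The background cooperation
level of each pair, $\overline{\mathrm{PMI}}(a,b)$, is estimated by
rebuilding the whole scan-and-count pipeline on `n_background_sets`
(default 100) shuffled copies of the promoter set and averaging each
pair's PMI over the sets in which it was scored (never-scored pairs fall
back to 0; zero-imputation over unscored sets would drag averages towards
$-\infty$-censored values and is deliberately avoided). Each background
set $k$ is seeded with `seed + k`, making the estimate reproducible.

Shuffling is per-sequence and dinucleotide-preserving (Euler-path
algorithm): the output has exactly the input's dinucleotide multiset and
both terminal bases, so base composition, CpG content and
dinucleotide-driven PWM hits are preserved while positional coupling is
destroyed — precisely the contrast the subtraction needs. A plain
mononucleotide permutation is available for comparison.

The subtraction is

$$\mathrm{PMI}^{\mathrm{specific}}(a,b) =
  \mathrm{PMI}(a,b) - (1 + \alpha)\,\overline{\mathrm{PMI}}(a,b),
  \qquad \alpha \in [-1, 1],$$

applied to significant pairs (significance gates first, then the
subtraction classifies). A significant pair is **specific** when
$\mathrm{PMI}^{\mathrm{specific}} > 0$ (strictly), otherwise **common**.
At $\alpha = -1$ the subtraction vanishes and no differentiation occurs;
growing $\alpha$ subtracts more background and, for nonnegative
background averages, monotonically shrinks the specific set —
`alpha_sweep()` tabulates this. The default $\alpha = 0.5$ sits below the
regime where the specific set collapses.

## Networks

`build_network()` turns the specific pairs of a tissue into an undirected
`igraph` graph (nodes = TFs/motifs, edges annotated with $z$ and
$\mathrm{PMI}^{\mathrm{specific}}$; homodimers are self-loops).
Degrees count self-loops as 2, the graph-theory convention, so hub
rankings are well defined (`hub_degrees()`). `rank_pairs()` orders
specific pairs by $z$, descending by default; an ascending option exists
because published top-pair tables are sometimes printed in ascending
z-order, and neither convention is asserted as canonical.
`overlap_table()` reports exclusive (UpSet-style) intersection counts of
TFs or pairs across tissues; counts sum to the number of distinct items.

## The synthetic-data generators

`gen_expression()` emulates a small multi-organ RNA-seq study: the
default is three tissues (liver, lung, kidney — the organs such analyses
focus on most), two replicates each, 2000 genes whose means mix an
unexpressed mode (centered at 0.1) and an expressed mode (centered at 10)
with $\sigma_{\log_{10}} = 0.5$ — producing the bimodal density that
threshold estimation assumes. Planted TSGs multiply their tissue's mean
by `specific_fold`; multiplicative log-normal noise has mean 1 and CV
`noise_cv`. The feasibility bound `specific_fold >= 2 * (n_tissues - 1)`
is enforced because below it even noise-free planting cannot reach the
two-thirds rule; at the bound it reaches it exactly.

`gen_promoters()` writes 600-bp sequences (the span of a −500..+100
window around a transcription start site) from a seeded Markov chain
(default order 2, per-context Dirichlet transition probabilities around a
target composition). A coupled pair is planted in a chosen fraction of
sequences at gaps uniform over a range, with the upstream/downstream
order randomized; decoy motifs land Poisson-distributed at independent
uniform positions. Planted words are *sampled from the PWM columns*, not
consensus-only, so cutoff calibration is exercised realistically; all
planted coordinates go into a truth manifest.

`gen_motif_library()` draws Dirichlet-column PWMs, rejection-sampling
until the information content lands in a window. The coupled-pair study
preset uses 12–16 bits over 8–10 columns: high-confidence, sharply
defined motifs. This choice matters and was made when the study
conditions were designed: with soft motifs (IC below ~12 bits) the
min(FPR+FNR) cutoffs admit several false sites per promoter per motif,
and the planted signal of a realistic planting fraction drowns in
false-positive co-occurrence — an instructive property of PWM scanning in
itself, but not a useful validation condition.

What the generators do **not** emulate: promoter grammar (positional
preference relative to the TSS, strand bias, motif clustering beyond the
planted pair), overlapping/competing real motifs, GC isochores, and any
read-level noise. Passing the planted-recovery tests therefore shows the
statistical machinery is sound under its own assumptions, not that any
particular biological dataset will yield stable networks.

## Numerical choices and degenerate inputs

* Pseudocount 0.01 per cell at normalization; all-zero columns with a
  zero pseudocount are an error.
* KDE on $\log_{10}(x + 10^{-3})$, `bw = "nrd"` (Scott), 512 grid points;
  unimodal or constant input is an error advising the fixed threshold.
* Correlation offsets with zero variance are skipped; if every offset is
  degenerate the correlation is 0 with a warning.
* Cluster-representative ties break lexicographically by motif id.
* Calibration cutoffs are midpoints between adjacent distinct observed
  scores; ties on FNR+FPR break towards the largest cutoff. Degenerate
  (inseparable) motifs return a cutoff with the achieved rates rather
  than failing.
* `zscore_transform()` requires at least two scored pairs and a positive
  population SD; both degenerate cases are errors, since no pair could be
  significant.
* Empty background sets are skipped with a warning; if all are empty the
  background estimate is an error.
* All randomness flows from user-visible seeds; derived seeds use small
  additive offsets and stay below $2^{31}$.

## Problem sizes used by the test suite

The suite validates the statistical contracts at the study conditions the
generators define: 300 promoters of 600 bp with the pair planted in half
at gaps U[5, 20] over 8 decoys (20 seeds for recovery; 100
dinucleotide-shuffled background sets and 20 seeds for the
specific/common discrimination), 1000 random matrices for the TSG rule,
1000 random sequences for the shuffle contract, 50 random instances each
for the pair-enumeration and scanner brute-force equivalences, and 200
label permutations for the independence null. These sizes are the
package's own validation design and run comfortably on a laptop.

## Known limitations

* PMI on small counts is noisy; pairs observed a handful of times can
  reach large $|z|$ by chance. The z-gate plus background subtraction
  mitigates but does not remove this; a count floor is a reasonable
  extension.
* The background estimate conditions on a pair being scored in a shuffled
  set, which biases averages of very rare pairs upward slightly.
* The minSum-style cutoff is an empirical estimate; its realized
  per-window false-positive rate is not directly controlled.
* Redundancy clustering guarantees one representative per cluster, but
  average linkage does not guarantee that no two representatives from
  different clusters correlate above the cutoff.
* Higher-order (triplet and larger) cooperation is out of scope, as are
  FDR-style corrections across pairs — the fixed $z \ge 3$ rule is the
  contract.
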