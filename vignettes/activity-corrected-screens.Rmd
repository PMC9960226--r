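---
title: "Activity-corrected analysis of reporter-coupled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-corrected analysis of reporter-coupled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenv)
```

## The measurement and the model

In a reporter-coupled pooled screen each sgRNA expression cassette carries a
synthetic copy of its own protospacer (+PAM) — the *reporter* — embedded in
fixed flanking sequence on the same lentiviral insert. The guide that a cell
expresses cuts its own reporter with essentially the same efficiency as its
endogenous target, so paired-end sequencing of the cassette amplicon yields,
per read pair, the guide identity (read 2) and the reporter's edit state
(read 1). Aggregated per guide, this gives two numbers per timepoint: the
guide's frequency in the pool and the fraction of its reads whose reporter
carries an indel.

Three facts shape the correction implemented here.

1. **Coupling.** Reporter and target edit states agree within a cell with
   high fidelity (cell-level coupling of about 94% in selection
   experiments). A cell that drops out because its essential target was
   disrupted removes an *edited* reporter from the pool. The observed indel
   fraction among surviving reads therefore underestimates the fraction of
   cells that were ever edited, and it does so exactly in proportion to the
   depletion: with normalized fold change $FC_{norm}$ and observed indel
   fraction $indel$, the actual edited-cell fraction is
   $$X = 1 - FC_{norm} + FC_{norm}\cdot indel.$$

2. **Terminal fold change.** Modeling growth as a single terminal
   relative-abundance multiplier, a guide whose edited cells have relative
   viability $v$ shows
   $$FC = (v-1)\,X + 1,$$
   i.e. $FC = 1$ when $v = 1$ and $FC = 1 - X$ when $v = 0$ (every edited
   cell dies). Depletion below $1 - X$ is impossible under the model;
   observing it in real data is what motivates the coupling correction in
   the first place.

3. **Cutting is not free.** Negative-control guides — active cutters with no
   gene-level fitness consequence — still deplete slightly, in proportion to
   their activity, consistent with a DNA-damage response to Cas9 cutting.
   Two control regressions absorb this. Regression 1, of raw control fold
   change on observed indel frequency, extrapolates to the fold change
   $FC_0$ of a hypothetical zero-activity control (its intercept); all fold
   changes are normalized by it, $FC_{norm} = FC_{raw}/FC_0$, which also
   removes the global scale that frequency-based fold changes inherit from
   the library mean. Regression 2, of normalized control fold change on
   $X$, defines the line $FC_{v=1}(X) = aX + b$: the fold change a neutral
   gene's guide of activity $X$ is *expected* to show. The corrected
   viability is then
   $$v = \frac{FC_{norm} - (1-X)}{FC_{v=1}(X) - (1-X)},$$
   pinned to 0 at the all-edited-cells-die line and to 1 on the control
   line. $v$ is deliberately not clipped; values above 1 are meaningful in
   enrichment screens.

The identity behind the whole construction: if $FC = (v-1)X+1$ and
$indel = Xv/FC$, then `compute_x()` returns $X$ and `compute_v()` returns
$v$ exactly — the package tests this on a dense $(X, v)$ grid and end to end
against the simulator's closed-form expectations, to $10^{-9}$.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `pseudocount` | 0.5 | added to every guide's read count in both samples before frequency normalization; keeps fold changes finite for complete dropouts of essential genes without materially moving well-covered guides |
| `min_rpt` | 0.1 | reads-per-thousand representation floor in the reference sample; guides below it show replicate-scale drift and are flagged out of all fits and scores (kept in tables) |
| `x_min` | 0.05 | reliability floor for $v$: as $X \to 0$ the $v=0$ and $v=1$ reference lines converge and fold-change noise is amplified into large $v$ swings, so low-activity guides are flagged, not deleted. The correction is best behaved in the moderate-to-high activity range ($X > 0.44$) |
| `eps` | 1e-6 | denominator guard on the fold-change scale below which $v$ is returned as `NA` (degenerate), well below any meaningful effect size |
| `window` (w) | 10 nt | indel-window half-width around the cut site; the reporter cannot report large deletions that escape its footprint, so edit calls are local by construction |
| `max_mismatch` | 1 | Hamming tolerance for spacer assignment; ties are left unassigned. One sequencing error is tolerated without cross-assignment in a Hamming-separated library |
| `flank_len` / `flank_mm` | 12 / 2 | fixed-flank anchors used to cut the variable reporter core out of read 1 |
| `gap_opening` / `gap_extension` | 10 / 0.5 | affine gap penalties for the global alignment of the reporter core; gap opening far above the mismatch penalty so a single indel is preferred over runs of substitutions, the standard amplicon-indel convention |

Substitution-only reads count as *unedited* rather than being discarded:
sequencing error must not inflate indel frequencies, and the edits of
interest are indels. Reads whose reporter belongs to a different cassette
(template switching / PCR chimeras) are detected by their protospacer,
counted in `n_total`, and excluded from both the indel numerator and
denominator — pairing fidelity is a property reported separately by
`count_sample()`.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions for all tests:

* per-guide activity $X_{true} \sim U(0.05, 0.95)$ — an unoptimized,
  tiling-style library whose indel frequencies span nearly the full range;
* essential genes at $v \in [0.1, 0.3]$, neutral genes at $v = 1$, 20% of
  genes essential;
* cell-level coupling fidelity $\kappa = 0.94$: with probability $1-\kappa$
  a cell's reporter state is drawn independently of its target state
  (Bernoulli($X$)), so the expected observed indel fraction is
  $\kappa X v_{eff}/FC + (1-\kappa)X$. This is undetectable in reads and is
  the simplest independence null for the residual decoupling;
* a *separate* cassette-swap rate (default 0.2) for reads whose reporter
  derives from a different cassette. These carry another guide's
  protospacer, are detectable, and match the 70–80% correct-pairing rates
  typical of these libraries. Cell-level state decoupling and read-level
  cassette swapping are different physical processes with different
  observable signatures, hence two parameters rather than one;
* DDR slope $s = -0.1$: an edited cell's viability is multiplied by $1+s$
  regardless of the target, which is what the control regressions estimate
  and remove;
* log-normal initial abundance with `sdlog = 0.43`, putting ~89% of guides
  within twofold of the median — the representation quality of a
  well-constructed library;
* multinomial read sampling at 2M reads per sample, binomial coupling and
  edit counts per guide; FASTQ emission writes 1–3 nt deletions at the cut
  site for edited reads, swapped protospacers for uncoupled reads, and iid
  substitution errors.

Real screens contain noise sources the simulator deliberately omits:
off-target cutting, copy-number effects, chromatin-dependent editing
differences between reporter and endogenous locus, non-random indel size
spectra (including large deletions the reporter cannot see), cell-bottleneck
drift during passaging, and PCR jackpotting. Passing tests therefore
demonstrate that the estimator inverts its own generative model correctly
and robustly under sampling noise — not that every real-data pathology is
handled. Growth is a single terminal multiplier; time courses can be
emulated by interpolating $X$ across timepoints but per-day editing kinetics
are not modeled.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere; `cut_offset` is the
  index of the first base 3' of the blunt cut (between protospacer
  positions 17 and 18 for SpCas9).
* **Regression 1 is fit on observed indel frequency, regression 2 on
  $X$** — the literal order in which the quantities become available. At
  finite depth both slope estimates carry a small negative bias
  (about $-0.01$ at 2M reads / 1500 guides): shared sampling noise between
  $FC_{norm}$ and $\hat X$ correlates the regression's x and y errors, and
  raw fold changes carry the library-renormalization scale until $FC_0$
  removes it. The reported DDR slope should be read with that in mind; it
  does not propagate into $v$ beyond the same order.
* **Ranking conventions**: lower score = more depleted; essential genes are
  the positive class. ROC-AUC is computed as the tie-corrected Mann-Whitney
  pair probability (identical to the trapezoid area, invariant under
  monotone transforms); ties in rankings are broken by entity id so output
  is deterministic while AUC itself is tie-corrected and unaffected.
* **dAUC** is the difference between rank-prefix recovery AUCs: rank all
  entities ascending, track the fraction of the essential set recovered in
  the top $t\cdot N$ ranks as $t$ goes 0 to 1, take the area, subtract the
  same for the non-essential set.
* **ROC level.** Benchmarks of v against FC are run at *guide* level with
  gene-set labels. In tiling-style screens the positives are the guides of
  the known essential genes, and this is where activity correction shows:
  gene-level median aggregation already rescues fold change from most
  low-activity guides (a median over three guides rarely lands on the one
  weak guide), so both metrics saturate and cannot be distinguished, while
  at guide level low-activity essential guides genuinely interleave with
  neutral guides under FC and do not under v. Both levels are exposed
  (`guide_scores()`, `gene_scores()`).
* **Gene aggregation** defaults to the median of reliable guides (falling
  back to all guides, flagged, when none is reliable); mean and
  second-best are available.
* **Export rounding** is half-up (`floor(x + 0.5)`), deterministic and
  matching the integer-count expectations of MAGeCK/DrugZ; scaled counts
  floor at zero.
* **Replicates** are handled by computing fold change and indel frequency
  per replicate and averaging at the metric level (`average_quants()`)
  before a single correction — matching how replicate fold changes are
  averaged in practice — rather than pooling reads.
* **Degenerate inputs**: guides with zero coupled reads get `NA` indel
  frequency and are flagged; `fit_controls()` refuses fewer than three
  usable controls, zero indel variance, or a non-positive $FC_0$;
  `compute_x()` clips to $[0,1]$ but retains and flags the raw value.

## Problem sizes used by the test suite

The suite exercises: the $(X,v)$ identity on a 9x13 grid; noiseless
end-to-end recovery on 900 guides; sampled recovery on 1000 targeting
guides + 500 controls at 2M reads (median $|\hat v - v_{true}| < 0.05$ over
$X_{true} \ge 0.3$, control slope within $\pm 0.02$); ten 1600-guide screens
for the v-vs-FC ROC comparison; 10,000 read pairs for classifier-vs-truth
agreement ($\ge$ 99.9% at zero sequencing error); and 100-instance
brute-force oracle checks for the moving median, Mann-Whitney AUC and
recall/FDR sweeps. These sizes keep the full suite under a minute while
leaving the statistical margins comfortable.

## Known limitations

* $v$ is unstable for $X$ below ~0.05–0.1 (flagged, not removed); use
  activity-optimized libraries or the `reliable` flag when ranking.
* The reporter is blind to indels whose footprint misses the cut-site
  window, so $X$ underestimates activity for guides with unusually large
  deletion spectra.
* The DDR correction assumes a linear control relationship; strongly
  nonlinear cutting toxicity would leak into $v$.
* Gene-level inference here is deliberately simple (median/mean/second-best
  aggregation); for full hit calling export the scaled pseudocounts to
  MAGeCK or DrugZ.
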