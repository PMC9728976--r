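---
title: "Hit calling and signature scoring for pooled CRISPRa screens: methods"
author: "lncact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling and signature scoring for pooled CRISPRa screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncact)
```

# The problem

A pooled CRISPR-activation (CRISPRa/SAM) screen transduces a tumor cell line
with a library of guide RNAs that recruit a transcriptional activator to gene
promoters — here, the promoters of long non-coding RNAs — and applies a
selective pressure, coculture with cytotoxic CD8+ T cells. Guides whose
target gene protects the cell from T-cell killing become enriched among
survivors; guides whose target sensitizes the cell become depleted. The
analysis task is to go from sequencing reads to a ranked, replicated,
statistically controlled list of candidate genes, and then to connect a
candidate's downstream transcriptional program to patient cohorts through a
weighted expression signature.

`lncact` implements that computational path as reusable, tested functions:
spacer counting, normalization, guide-to-gene reannotation, two independent
gene-ranking statistics with permutation nulls, replicate combination and
intersection hit calling, signature construction and scoring, and the
survival/multiplicity utilities used in cohort association. Everything is
exercised on synthetic data whose generators are first-class, seeded package
functions.

# Counting and normalization

Reads are assigned to guides by exact matching: a read counts for a guide
when a constant anchor sequence occurs in the read and the following
spacer-length substring equals the guide's spacer exactly
(`count_spacers()`). No mismatch tolerance is attempted; with a
high-fidelity amplicon protocol the loss is small and the contract is
unambiguous. The anchor defaults to the conventional U6-vector junction
`CGAAACACCG` and is configurable, since different vectors place different
constant sequence ahead of the spacer.

Normalization (`normalize_counts()`) adds a pseudocount of 1 to every raw
count *before* computing per-sample totals, then scales to counts-per-million:

$$\tilde n_{gs} = \frac{n_{gs} + 1}{\sum_g (n_{gs} + 1)} \times 10^6 .$$

The order matters slightly (totals include the pseudocounts) and is fixed as
stated; the scale constant cancels in every fold change, so it only affects
presentation. Guide-level log2 fold changes divide treated by control
normalized counts; the five-sample design (plasmid `P`, controls `C1`/`C2`,
treated replicates `S1`/`S2`) uses `S1` vs `C2` and `S2` vs `C2` as the two
replicate comparisons, and `qc_correlations()` reports Pearson correlations
of raw counts between replicates and of fold changes between comparisons as
the reproducibility check.

# Guide library reannotation

Annotations drift; a library designed against one annotation release is
re-mapped against another before gene-level aggregation. Each spacer is
treated as a plain DNA motif and located exactly on both genomic strands
(`find_spacer_sites()`, backed by Biostrings dictionary matching and checked
in the tests against a naive quadratic scanner). PAM context and mismatch
scoring are deliberately out of scope: the reannotation treats spacers as
motifs, nothing more.

A transcript's promoter window covers 1000 bases upstream through 100 bases
downstream of its TSS, strand-aware. Internally coordinates are 0-based
half-open (GTF input/output is 1-based inclusive); with the TSS at 0-based
position $t$ the window is $[t-1000,\, t+100)$ on the plus strand and its
mirror $[t-100,\, t+1000)$ on the minus strand, clipped to chromosome
bounds. A guide is assigned to a transcript when any of its loci overlaps
the window by at least one base (full containment is available as an
option); a transcript with at least two assigned guides is a target
(`build_target_map()`). Guides matching several windows are kept in all of
them, and matches on either genomic strand may hit any transcript's window —
an activation complex binds double-stranded DNA, and the permissive default
can be tightened by the caller. Biotype classes (intergenic lncRNA,
antisense lncRNA, protein-coding) come from annotation tags when present,
otherwise from opposite-strand overlap with protein-coding transcripts
(`classify_biotype()`).

# Gene ranking

Two rank-based statistics aggregate guide fold changes to gene level; both
are invariant to monotone transforms of the fold changes, ties are broken by
average rank, and every empirical P value uses the $(b+1)/(N_\mathrm{perm}+1)$
correction so it is never exactly zero.

**Weighted rank statistic (RIGER-style).** Guides are ranked by
direction-signed fold change and converted to normalized rank scores
$r = \mathrm{rank}/N$. A gene's statistic is
$0.25\,r_{(1)} + 0.75\,r_{(2)}$ over its two best guides; the emphasis on
the *second*-best guide discounts single-guide outliers (off-target or
cloning artifacts). The null is built from random same-size guide sets drawn
from the full ranked list; an exhaustive-enumeration mode replaces sampling
on small instances and is compared against a brute-force oracle in the test
suite. The published description of this family of screens defers to
"recommended parameters", so the specific weighted-sum variant and its
0.25/0.75 weights are a documented, configurable reimplementation choice.

**alpha-RRA with a nontargeting-control null.** For a gene with $n$ guides
and sorted percentiles $p_{(1)} \le \dots \le p_{(n)}$, only guides in the
top `alpha_rra` fraction (default 0.25) contribute, and the gene score is

$$\rho = \min_{k:\, p_{(k)} \le \alpha} \Pr\!\left[\mathrm{Beta}(k,\, n-k+1)
\le p_{(k)}\right],$$

the minimum Beta order-statistic tail probability. Significance comes from
size-matched pseudo-genes drawn from the nontargeting controls. A gene with
no guide under the threshold is assigned P = 1.

*Percentile calibration.* By default (`calibrate = TRUE`) guide percentiles
are recomputed against the control distribution: a guide falling in rank
cell $j$ of the $n_c$ sorted controls maps to $(j+0.5)/(n_c+1)$, and the
pseudo-gene null draws uniformly over the $n_c + 1$ cells — exact under
exchangeability of a null guide with the controls. We adopted this default
after characterizing the alternative: drawing pseudo-genes from the
controls' raw full-list percentiles leaves gene P values at the mercy of the
realized control set, so the fraction of null genes below P < 0.05
fluctuates from screen to screen with a standard deviation near 0.02 at 500
controls (unbiased on average, but a single screen can show 0.03 or 0.09).
Calibration removes the shared shift and is how control guides are
conventionally used for both "normalization and null generation". The raw
behavior is retained as `calibrate = FALSE`. Even calibrated, an empirical
null built from 500 controls has limited resolution for a min-of-Beta
statistic; residual screen-to-screen variation in the realized type-I rate
of roughly ±0.015 is intrinsic and documented as a limitation below.

**Replicate combination and hit calling.** Per-gene replicate P values are
combined as

$$\mathrm{score} = \alpha \times
\frac{-\log_{10} p_{\mathrm{rep1}} - \log_{10} p_{\mathrm{rep2}}}{2},
\qquad
\alpha = \begin{cases}
2 & p_{\mathrm{rep1}} < 0.05 \text{ and } p_{\mathrm{rep2}} < 0.05\\
0.5 & p_{\mathrm{rep1}} \ge 0.05 \text{ and } p_{\mathrm{rep2}} \ge 0.05\\
1 & \text{otherwise,}
\end{cases}$$

rewarding replicated significance and shrinking jointly unconvincing genes
(`combine_replicates()`; the boundary uses $\ge$). A gene is a hit when its
P value is strictly below 0.05 in *both* treated replicates under *both*
ranking methods, in the same direction (`call_hits()`); positive
(protective) and negative (sensitizing) selections are scored on reversed
rankings and reported separately. Benjamini–Hochberg FDRs are computed and
carried alongside, but the hit rule follows the raw-P intersection — the
dual-method dual-replicate requirement is itself the multiplicity control
of this design. `guide_frequency_ttest()` adds the per-gene paired
(by guide) two-tailed t test of normalized frequencies between conditions.

# Activation signature

From a differential-expression table (gene, log2FC, signed test statistic
$w$, P), `build_signature()` takes the 190 strongest up- and 190 strongest
down-regulated genes among those with P < 0.05 — "strongest" means largest
|log2FC| within each direction, with ties broken by smaller P and then gene
id — and weights each selected gene by $k_i = w_i / \max_j |w_j|$, so
$k_i \in [-1, 1]$ with exactly one gene at unit magnitude. A sample is
scored by $S = \sum_i k_i z_i$, where $z_i$ is the gene's expression z-score
computed *within the sample across the full gene universe* of the supplied
matrix (`score_samples()`). That per-sample reading makes $S$ invariant to
shifting or positively rescaling a sample's expression vector — important
when cohorts are quantified differently — and is implemented as stated; a
per-gene (within-cohort) z-score is exposed as `z_within = "gene"` for
users who prefer cross-sample standardization. Signature genes missing from
a cohort are dropped and the coverage fraction reported. Composite immune
signatures (MHC-I: B2M, HLA-A/B/C; CTL: CD8A, CD8B, GZMA, GZMB, PRF1) are
unweighted member means, and `associate()` provides the Spearman/Pearson
correlations and two-tailed unpaired t tests used to link scores to
phenotypes.

# Survival and multiplicity

`km_curve()` and `logrank()` wrap the survival package's product-limit
estimator and two-group log-rank test (events processed before censorings at
tied times, the standard convention); `bh_fdr()` wraps the step-up
Benjamini–Hochberg adjustment. These are deliberately thin: the statistics
are classical, and the package's contribution is the pipeline around them.
`split_by_score()` dichotomizes cohorts for survival contrasts; the
published high/low cut is unstated, so the default is a median split (ties
to the lower group) with tertile and explicit-threshold options. Cox
modeling is out of scope.

# What the synthetic data emulate

`make_reference()` builds a toy genome in which each targeting spacer
occurs exactly once, planted inside its transcript's promoter window on a
random strand, with nontargeting spacers verified absent — so reannotation
has a known ground truth. Transcripts cycle through the three biotypes on
both strands, and each antisense lncRNA gets an untargeted protein-coding
partner overlapping it on the opposite strand to exercise the
classification fallback.

`simulate_screen()` draws negative-binomial counts around a log-normal
library-composition baseline (sdlog 0.5) shared across samples
(mean--variance relation $\mu + \phi\mu^2$), the standard model for pooled
screen counts; the published analysis states no noise model, so these are
conventional choices, not derived ones. Planted effects multiply the
abundance of a hit's *functional* guides by $2^{\mathrm{effect}}$ in the
treated replicates only, before renormalization to fixed depth — guide
efficacy is heterogeneous in real libraries, and the default 6 functional of
10 guides mirrors the observed pattern that roughly six of ten guides of a
validated hit carry the enrichment. Defaults describe the desk-scale study
condition used throughout the tests: 200 genes × 10 guides + 50
nontargeting controls, dispersion 0.2, depth $10^6$, 10 enriched and 10
depleted genes at effect 2. The calibration experiments use 1000 genes and
500 controls, the control-set size of the real library. These sizes keep
the full test suite in the minutes range while leaving every parameter
configurable up to realistic scales.

`simulate_activation_cohort()` plants 250 up- and 250 down-regulated genes
whose log-expression shifts linearly with a latent per-sample activation
level (activated and control groups half/half, within-group activation sd
0.25, effect sizes uniform on ±[0.5, 1.5], noise sd 1 — chosen so the
190+190 selection is comfortably feasible at the default 100 samples while
weak genes still straddle the significance gate), derives the DE table by
pooled two-sample t tests on the simulated matrix so its statistics are
consistent with the planted shifts by construction, and generates outcomes
with response log-odds and survival log-hazard proportional to the
activation level.

What passing tests do *not* show about real data: the generators have no
PCR/amplification artifacts, no guide-level off-target activity, no
batch structure across cohorts, and exact-match counting is by construction
lossless; real screens and cohorts violate all four. The recovery and
calibration results certify the statistical machinery, not the wet-lab
robustness of any particular screen.

# Numerical choices and degenerate inputs

* Empirical P values use the +1 correction; `combine_replicates()` rejects
  P = 0 outright.
* Fold-change ties get average ranks; this feeds the permutation nulls and
  is therefore fixed, not an implementation detail.
* Each user-facing seed derives independent child streams for independent
  operations (reference building, count drawing, permutations), all below
  $2^{31}$; identical configurations give byte-identical outputs.
* Window arithmetic clips at chromosome bounds; degenerate inputs (constant
  vectors in correlations, zero-variance guide differences in the paired t
  test, all-equal scores in `split_by_score()`) are flagged or rejected
  with informative errors rather than silently propagated.
* `riger_rank(exact = TRUE)` enumerates all same-size guide subsets and is
  intended for small instances; the sampled null is the default elsewhere.

# Known limitations

* Exact-match counting discards reads with sequencing errors in the spacer;
  counts are slight undercounts of true abundance, uniformly across guides.
* The alpha-RRA empirical null inherits the granularity of the control set;
  with 500 controls the realized per-screen type-I rate at the 0.05
  threshold varies by roughly ±0.015 around its nominal level even after
  calibration.
* The intersection hit rule follows the published raw-P design and is
  conservative by construction; genes just above 0.05 in any one cell are
  discarded regardless of the other three.
* Biotype fallback classification knows only opposite-strand overlap; sense
  intronic and bidirectional classes collapse into "other".
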