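# lncact

Hit calling and signature scoring for pooled CRISPR-activation screens.

## What this package is for

Genome-wide CRISPRa (SAM) screens of long non-coding RNAs under immune
selective pressure — tumor cells cocultured with cytotoxic CD8+ T cells —
produce guide-level count data from which candidate immune-regulatory genes
must be called, and whose downstream transcriptional programs are then
linked to immunotherapy response in patient cohorts. `lncact` implements
that analysis path for computational biologists working with such screens:

* **Counting & QC** — exact anchored spacer counting from FASTQ
  (`count_spacers`), pseudocount/counts-per-million normalization
  (`normalize_counts`), guide log2 fold changes (`log2fc`, `fc_table`),
  replicate Pearson correlations (`qc_correlations`).
* **Library reannotation** — exact genomic motif search on both strands
  (`find_spacer_sites`), strand-aware promoter windows −1000/+100 of the
  TSS (`promoter_windows`), guide→transcript assignment with the ≥2-guide
  target rule and biotype classes (`build_target_map`, `classify_biotype`).
* **Gene ranking & hit calling** — a RIGER-style weighted rank statistic
  with permutation null (`riger_rank`) and alpha-RRA against a
  nontargeting-control null (`rra_rank`); replicate combination by the
  weighted-average rule

  ```
  score = alpha * (-log10 p_rep1 - log10 p_rep2) / 2
  alpha = 2   if both p < 0.05
          0.5 if both p >= 0.05
          1   otherwise
  ```

  (`combine_replicates`), and the intersection rule — P < 0.05 in both
  treated replicates by both methods — for the final hit list
  (`call_hits`).
* **Activation signatures** — 190+190 signature genes gated at P < 0.05
  with weights `k = w / max|w|` (`build_signature`); per-sample score
  `S = sum(k_i * z_i)` over within-sample expression z-scores
  (`score_samples`); MHC-I/CTL composite means (`composite_score`) and
  score–phenotype association (`associate`).
* **Cohort statistics** — Kaplan–Meier curves, log-rank tests, score-based
  group splits, Benjamini–Hochberg FDR (`km_curve`, `logrank`,
  `split_by_score`, `bh_fdr`).
* **Synthetic data** — seeded generators for toy genome/annotation/library
  with planted spacers (`make_reference`), negative-binomial screen counts
  with planted enrichment/depletion (`simulate_screen`), and expression
  cohorts with a latent activation program and linked outcomes
  (`simulate_activation_cohort`).

See `vignettes/screen-pipeline.Rmd` for the models, parameter choices and
limitations.

## Worked example

A desk-scale screen: 200 transcripts × 10 guides + 50 nontargeting
controls, 10 enriched and 10 depleted genes planted at log2 effect 2 on
6 of 10 guides, depth 10⁶.

```r
library(lncact)

cfg <- sim_config(seed = 7)
ref <- make_reference(cfg)
scr <- simulate_screen(ref$library, cfg)

norm <- normalize_counts(scr$counts)
fc   <- fc_table(norm)                       # S1 vs C2, S2 vs C2
qc_correlations(scr$counts, fc)
#>     type                 pair     r         p    n note
#> 1 counts             S1 vs S2 0.589 1.27e-191 2050
#> 2 log2fc S1_vs_C2 vs S2_vs_C2 0.599 1.25e-199 2050

tgt  <- targets_from_library(ref$library)
ctrl <- ref$library$guide_id[ref$library$is_control]
riger <- rank_genes(fc, tgt, method = "riger", n_perm = 1000, seed = 7)
rra   <- rank_genes(fc, tgt, method = "rra", controls = ctrl,
                    n_perm = 1000, seed = 7)
hits  <- call_hits(riger, rra)
head(hits[, c("gene", "direction", "p_riger_rep1", "p_riger_rep2",
              "alpha", "score")])
#>     gene direction p_riger_rep1 p_riger_rep2 alpha score
#> 1 TX0017  positive      0.00300     0.000999     2  5.52
#> 2 TX0037  negative      0.00200     0.001998     2  5.40
#> 3 TX0083  positive      0.00500     0.000999     2  5.30
#> 4 TX0116  positive      0.00300     0.001998     2  5.22
#> 5 TX0167  positive      0.00999     0.000999     2  5.00
#> 6 TX0016  negative      0.00500     0.001998     2  5.00
```

Every hit carries `alpha = 2` (replicated significance); on this seed the
intersection recovers 19 of the 20 planted genes with no false discovery.
The replicate correlations (r ≈ 0.6) reflect the generator's dispersion,
and each hit's four P values (both methods × both replicates) sit below
0.05 by construction of the intersection rule.

Signature construction and cohort association on a simulated activation
cohort (100 samples, half activated):

```r
co  <- simulate_activation_cohort(cohort_sim_config(seed = 7))
sig <- build_signature(co$de_table)          # 190 up + 190 down, max|k| = 1
s   <- score_samples(co$expression, sig)
cor(s, co$truth$activation)
#> 0.996

oc <- co$outcomes
oc$group <- split_by_score(s)                # median split, ties low
logrank(oc)
#> log-rank chi-square = 18.70, P = 1.5e-05
```

The signature score tracks the latent activation level almost perfectly at
this noise level, and splitting the cohort by score separates survival as
planted through the outcome link.

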