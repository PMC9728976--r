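# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (loops, textbook formulas) and share no code with
# the package internals.

# O(n*m) exact motif scan of one chromosome string, both strands
naive_find_sites <- function(chrom_seq, spacer) {
  m <- nchar(spacer)
  L <- nchar(chrom_seq)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(spacer, "")[[1]]),
                                     collapse = ""))
  hits <- list()
  for (i in seq_len(L - m + 1L)) {
    sub <- substr(chrom_seq, i, i + m - 1L)
    if (sub == spacer)
      hits[[length(hits) + 1L]] <- c(start = i - 1L, strand = "+")
    if (sub == rc)
      hits[[length(hits) + 1L]] <- c(start = i - 1L, strand = "-")
  }
  hits
}

# brute-force interval overlap of loci vs windows (0-based half-open)
brute_assignments <- function(loci, windows) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(windows))) {
      if (loci$chrom[i] == windows$chrom[j] &&
          loci$start[i] < windows$end[j] &&
          windows$start[j] < loci$end[i]) {
        out[[length(out) + 1L]] <- data.frame(
          guide = loci$guide_id[i], tx = windows$transcript_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(guide = character(0),
                                      tx = character(0)))
  unique(do.call(rbind, out))
}

# textbook Pearson correlation
pearson_manual <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Spearman rho through the rank-difference formula (no ties)
spearman_manual <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# closed-form paired two-tailed t test
paired_t_manual <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, p.value = 2 * pt(-abs(t), n - 1))
}

# rank-based AUC (probability a random positive scores above a random
# negative, ties counted half)
auc_manual <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# brute-force RIGER permutation: exhaustive enumeration of all size-n
# guide subsets of the ranked list
riger_brute_p <- function(fc, gene_guides, direction,
                          weights = c(0.25, 0.75)) {
  s <- if (direction == "positive") -fc else fc
  r <- rank(s, ties.method = "average") / length(fc)
  stat <- function(ix) {
    top <- sort(r[ix])[1:2]
    weights[1] * top[1] + weights[2] * top[2]
  }
  obs <- stat(match(gene_guides, names(fc)))
  cmb <- combn(length(fc), length(gene_guides))
  null <- apply(cmb, 2, stat)
  mean(null <= obs)
}

# tiny reference used by several annotation tests
small_reference <- function(seed = 42) {
  make_reference(sim_config(
    seed = seed, n_genes = 6, guides_per_gene = 3, n_nontargeting = 4,
    n_functional_guides_per_hit = 2, n_planted_enriched = 1,
    n_planted_depleted = 1, depth_per_sample = 5e4))
}
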