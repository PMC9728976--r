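# Gene-level aggregation of guide fold changes.
#
# Both rankers are rank-based: any strictly monotone transform of the
# fold changes leaves results unchanged.  Ties are broken by average
# rank; empirical P values use the (b+1)/(n_perm+1) correction so they
# are never exactly zero (required by combine_replicates).

# normalized rank scores in (0, 1]: rank 1 = most extreme in `direction`
.direction_ranks <- function(fc, direction) {
  s <- if (direction == "positive") -fc else fc
  rank(s, ties.method = "average") / length(fc)
}

#' RIGER-style gene ranking with a permutation null
#'
#' Guides are ranked by direction-signed log2 fold change and converted
#' to normalized rank scores r = rank/N.  A gene's statistic is the
#' weighted sum of its two best (smallest) rank scores, weight 0.25 on
#' the best and 0.75 on the second best; smaller is more extreme.
#' Significance comes from `n_perm` random same-size guide sets drawn
#' from the full ranked list, with the +1 correction, or from exhaustive
#' enumeration of all guide subsets when `exact = TRUE`.
#'
#' @param fc named numeric vector of guide log2 fold changes (one
#'   comparison), including control guides.
#' @param targets a `target_map` (see [build_target_map()],
#'   [targets_from_library()]).
#' @param direction `"positive"` scores enrichment, `"negative"`
#'   depletion (scored on the reversed ranking).
#' @param n_perm permutation draws (>= 100).
#' @param seed integer seed for the permutation null.
#' @param weights weights on the best and second-best rank score.
#' @param exact enumerate all same-size guide subsets instead of
#'   sampling (feasible only for small guide lists).
#' @return data.frame of class `gene_score_table`: gene, n_guides,
#'   statistic, p, fdr (Benjamini-Hochberg), rank.
#' @export
riger_rank <- function(fc, targets, direction = c("positive", "negative"),
                       n_perm = 1000L, seed = 1L,
                       weights = c(0.25, 0.75), exact = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(targets, "target_map"), !is.null(names(fc)),
            length(weights) == 2L)
  if (!exact) n_perm <- .check_count(n_perm, "n_perm", min = 100L)
  r <- .direction_ranks(fc, direction)
  genes <- .usable_genes(targets, names(fc), "riger_rank")
  N <- length(r)

  stat_of <- function(rs) {
    top2 <- sort(rs, partial = 1:2)[1:2]
    weights[1L] * top2[1L] + weights[2L] * top2[2L]
  }
  obs <- vapply(genes, function(g) stat_of(r[g]), numeric(1))
  sizes <- lengths(genes)

  p <- withr::with_seed(.child_seed(seed, 11L), {
    null_by_size <- lapply(unique(sizes), function(n) {
      if (exact) {
        cmb <- combn(N, n)
        apply(cmb, 2L, function(ix) stat_of(r[ix]))
      } else {
        vapply(seq_len(n_perm), function(i) stat_of(r[sample.int(N, n)]),
               numeric(1))
      }
    })
    names(null_by_size) <- as.character(unique(sizes))
    vapply(seq_along(obs), function(i) {
      null <- null_by_size[[as.character(sizes[i])]]
      b <- sum(null <= obs[i])
      if (exact) b / length(null) else (b + 1) / (n_perm + 1)
    }, numeric(1))
  })
  .gene_score_table(names(genes), sizes, obs, p)
}

#' Alpha-RRA gene ranking against a nontargeting-control null
#'
#' Guide percentiles are computed against the full ranked list.  For a
#' gene with n guides and sorted percentiles p(1) <= ... <= p(n), only
#' percentiles at or below `alpha_rra` contribute; the gene score is
#' rho = min over contributing k of Pr\[Beta(k, n-k+1) <= p(k)\], the
#' Beta order-statistic tail probability.  Significance is estimated by
#' drawing size-matched pseudo-genes (with replacement) from the
#' nontargeting control guides' percentiles.  A gene with no guide under
#' `alpha_rra` is assigned P = 1.
#'
#' @inheritParams riger_rank
#' @param controls character vector of control guide ids (must be
#'   present in `fc`).
#' @param alpha_rra fraction of the ranked list within which guides may
#'   contribute (default 0.25).
#' @param calibrate when TRUE (default), guide percentiles are
#'   recomputed against the control guides' distribution (the fraction
#'   of controls at or beyond each guide), so the controls serve both as
#'   percentile normalization and as the null; this keeps gene P values
#'   calibrated when the control set is finite.  When FALSE, raw
#'   full-list percentiles are used and the null is drawn from the
#'   controls' raw percentiles.
#' @return data.frame of class `gene_score_table`: gene, n_guides,
#'   statistic (rho; 1 when no guide contributes), p, fdr, rank.
#' @export
rra_rank <- function(fc, targets, controls,
                     direction = c("positive", "negative"),
                     alpha_rra = 0.25, n_perm = 1000L, seed = 1L,
                     calibrate = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(targets, "target_map"), !is.null(names(fc)))
  n_perm <- .check_count(n_perm, "n_perm", min = 100L)
  alpha_rra <- .check_number(alpha_rra, "alpha_rra", min = 0, strict = TRUE)
  controls <- intersect(controls, names(fc))
  if (!length(controls))
    stop("no control guides present in the fold-change vector")
  u <- .direction_ranks(fc, direction)
  genes <- .usable_genes(targets, names(fc), "rra_rank")
  sizes <- lengths(genes)
  uc <- u[controls]
  if (calibrate) {
    nc <- length(uc)
    # percentile of each guide within the control distribution: a guide
    # falling in rank cell j of the nc controls (j = 0..nc) maps to
    # (j + 0.5)/(nc + 1).  By exchangeability a null guide occupies each
    # of the nc + 1 cells with equal probability, so the pseudo-gene
    # null draws uniformly from the full cell grid.
    u <- setNames((findInterval(u, sort(uc)) + 0.5) / (nc + 1), names(u))
    uc <- (seq_len(nc + 1L) - 0.5) / (nc + 1)
  }

  rho_vec <- function(us) {               # us already sorted
    n <- length(us)
    k <- which(us <= alpha_rra)
    if (!length(k)) return(NA_real_)
    min(pbeta(us[k], k, n - k + 1))
  }
  obs <- vapply(genes, function(g) rho_vec(sort(u[g])), numeric(1))

  p <- withr::with_seed(.child_seed(seed, 12L), {
    null_by_size <- lapply(unique(sizes), function(n) {
      draws <- matrix(sample(uc, n_perm * n, replace = TRUE), n_perm, n)
      draws <- t(apply(draws, 1L, sort))
      kmat <- matrix(seq_len(n), n_perm, n, byrow = TRUE)
      b <- pbeta(draws, kmat, n - kmat + 1)
      b[draws > alpha_rra] <- Inf
      rho <- do.call(pmin, as.data.frame(b))
      rho
    })
    names(null_by_size) <- as.character(unique(sizes))
    vapply(seq_along(obs), function(i) {
      if (is.na(obs[i])) return(1)
      null <- null_by_size[[as.character(sizes[i])]]
      (sum(null <= obs[i]) + 1) / (n_perm + 1)
    }, numeric(1))
  })
  obs[is.na(obs)] <- 1
  .gene_score_table(names(genes), sizes, obs, p)
}

# genes usable for ranking: guides restricted to those with fold changes,
# at least two remaining
.usable_genes <- function(targets, guide_universe, caller) {
  genes <- lapply(targets$transcripts, intersect, guide_universe)
  drop <- lengths(genes) < 2L
  if (any(drop)) {
    warning(sprintf("%s: %d gene(s) with fewer than 2 scored guides excluded",
                    caller, sum(drop)))
    genes <- genes[!drop]
  }
  if (!length(genes)) stop("no genes with >= 2 scored guides")
  genes
}

.gene_score_table <- function(gene, n_guides, statistic, p) {
  out <- data.frame(gene = gene, n_guides = as.integer(n_guides),
                    statistic = statistic, p = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$statistic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Rank genes across comparisons and directions
#'
#' Convenience wrapper running [riger_rank()] or [rra_rank()] for every
#' column of a fold-change matrix and both selection directions,
#' returning one long table suitable for [call_hits()].
#'
#' @param fc matrix of guide log2 fold changes, one column per
#'   comparison (see [fc_table()]).
#' @param targets a `target_map`.
#' @param method `"riger"` or `"rra"`.
#' @param controls control guide ids (required for `"rra"`).
#' @param directions selection directions to score.
#' @param n_perm,seed,... passed to the ranker; each comparison x
#'   direction cell gets a distinct child seed derived from `seed`.
#' @return data.frame: gene, comparison, direction, n_guides, statistic,
#'   p, fdr, rank.
#' @export
rank_genes <- function(fc, targets, method = c("riger", "rra"),
                       controls = NULL,
                       directions = c("positive", "negative"),
                       n_perm = 1000L, seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(is.matrix(fc), !is.null(colnames(fc)))
  if (method == "rra" && is.null(controls))
    stop("rra ranking requires control guide ids")
  out <- list()
  cell <- 0L
  for (cmp in colnames(fc)) {
    for (dir in directions) {
      cell <- cell + 1L
      tab <- if (method == "riger")
        riger_rank(fc[, cmp], targets, direction = dir, n_perm = n_perm,
                   seed = seed + 97L * cell, ...)
      else
        rra_rank(fc[, cmp], targets, controls, direction = dir,
                 n_perm = n_perm, seed = seed + 97L * cell, ...)
      tab$comparison <- cmp
      tab$direction <- dir
      out[[length(out) + 1L]] <- tab
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("gene", "comparison", "direction", "n_guides",
                 "statistic", "p", "fdr", "rank")]
  rownames(res) <- NULL
  res
}

#' Weighted-average combination of two replicate P values
#'
#' Combines a gene's P values from two treated replicates as
#' `alpha * (-log10(p1) - log10(p2)) / 2`, where alpha is 2 when both
#' P < 0.05, 0.5 when both P >= 0.05, and 1 otherwise.  The score is
#' nonnegative and monotone decreasing in each P value.
#'
#' @param p1,p2 replicate P values in (0, 1]; zero is rejected (callers
#'   should use +1-corrected empirical P values).  Vectorized.
#' @return data.frame: p_rep1, p_rep2, alpha, score.
#' @export
combine_replicates <- function(p1, p2) {
  .check_prob(p1, "p1"); .check_prob(p2, "p2")
  stopifnot(length(p1) == length(p2))
  alpha <- ifelse(p1 < 0.05 & p2 < 0.05, 2,
                  ifelse(p1 >= 0.05 & p2 >= 0.05, 0.5, 1))
  score <- alpha * (-log10(p1) - log10(p2)) / 2
  data.frame(p_rep1 = p1, p_rep2 = p2, alpha = alpha, score = score)
}

#' Call hits by dual-method, dual-replicate intersection
#'
#' A gene is a hit in a given direction when its P value is strictly
#' below `threshold` in both treated replicates under both ranking
#' methods.  Hits are scored by the weighted-average combination of the
#' RIGER replicate P values and reported separately per direction,
#' sorted by combined score.
#'
#' @param riger,rra long score tables from [rank_genes()]; must cover
#'   the same genes and the same two comparisons.
#' @param threshold significance threshold (default 0.05, strict
#'   inequality).
#' @param biotype optional named vector of per-gene biotype classes.
#' @return data.frame: gene, direction, p_riger_rep1, p_riger_rep2,
#'   p_rra_rep1, p_rra_rep2, alpha, score, biotype; attribute
#'   `comparisons` records the replicate comparison labels.
#' @export
call_hits <- function(riger, rra, threshold = 0.05, biotype = NULL) {
  .check_prob(threshold, "threshold")
  reps <- sort(unique(riger$comparison))
  if (!identical(reps, sort(unique(rra$comparison))))
    stop("replicate comparison sets differ between the two methods")
  if (length(reps) != 2L)
    stop("hit calling expects exactly two replicate comparisons")
  if (!setequal(unique(riger$gene), unique(rra$gene)))
    stop("the two score tables cover different genes")

  wide <- function(tab, dir) {
    t1 <- tab[tab$direction == dir & tab$comparison == reps[1L], ]
    t2 <- tab[tab$direction == dir & tab$comparison == reps[2L], ]
    merge(t1[, c("gene", "p")], t2[, c("gene", "p")],
          by = "gene", suffixes = c("_rep1", "_rep2"))
  }
  out <- list()
  for (dir in intersect(unique(riger$direction), unique(rra$direction))) {
    wr <- wide(riger, dir)
    wm <- wide(rra, dir)
    m <- merge(wr, wm, by = "gene",
               suffixes = c("", "_rra"))
    names(m) <- c("gene", "p_riger_rep1", "p_riger_rep2",
                  "p_rra_rep1", "p_rra_rep2")
    hit <- m$p_riger_rep1 < threshold & m$p_riger_rep2 < threshold &
      m$p_rra_rep1 < threshold & m$p_rra_rep2 < threshold
    if (!any(hit)) next
    m <- m[hit, , drop = FALSE]
    cs <- combine_replicates(m$p_riger_rep1, m$p_riger_rep2)
    m$alpha <- cs$alpha
    m$score <- cs$score
    m$direction <- dir
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) {
    res <- data.frame(gene = character(0), direction = character(0),
                      p_riger_rep1 = numeric(0), p_riger_rep2 = numeric(0),
                      p_rra_rep1 = numeric(0), p_rra_rep2 = numeric(0),
                      alpha = numeric(0), score = numeric(0),
                      biotype = character(0), stringsAsFactors = FALSE)
    attr(res, "comparisons") <- reps
    return(res)
  }
  res <- do.call(rbind, out)
  res$biotype <- if (is.null(biotype)) NA_character_
                 else unname(biotype[res$gene])
  res <- res[order(-res$score), c("gene", "direction", "p_riger_rep1",
                                  "p_riger_rep2", "p_rra_rep1",
                                  "p_rra_rep2", "alpha", "score",
                                  "biotype")]
  rownames(res) <- NULL
  attr(res, "comparisons") <- reps
  res
}

#' Paired t test on a gene's guide frequencies
#'
#' Compares the normalized frequencies of a gene's guides between
#' treated and control samples with a two-tailed paired Student's t
#' test, pairing by guide (each guide's mean over treated samples vs its
#' mean over control samples).
#'
#' @param norm normalized count matrix from [normalize_counts()].
#' @param gene transcript id to test.
#' @param targets a `target_map` supplying the gene's guides.
#' @param treated,control sample (column) names of the two conditions.
#' @return List: statistic, df, p.value, mean_difference (treated minus
#'   control), n_guides, and `degenerate` (TRUE when the guide-wise
#'   differences have zero variance, in which case P is reported as 1).
#' @export
guide_frequency_ttest <- function(norm, gene, targets, treated, control) {
  stopifnot(inherits(targets, "target_map"))
  guides <- intersect(targets$transcripts[[gene]], rownames(norm))
  if (length(guides) < 2L)
    stop("gene '", gene, "' has fewer than 2 guides with counts")
  x_t <- rowMeans(norm[guides, treated, drop = FALSE])
  x_c <- rowMeans(norm[guides, control, drop = FALSE])
  d <- x_t - x_c
  if (sd(d) == 0)
    return(list(statistic = 0, df = length(d) - 1L, p.value = 1,
                mean_difference = mean(d), n_guides = length(guides),
                degenerate = TRUE))
  tt <- t.test(x_t, x_c, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = unname(tt$estimate),
       n_guides = length(guides), degenerate = FALSE)
}
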