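#' Build a weighted activation signature from a DE table
#'
#' Among genes passing the P gate, selects the `n_per_direction` with
#' the largest log2 fold changes up and the smallest (most negative)
#' down, then weights each selected gene by its test statistic
#' normalized to the largest magnitude among the selected genes:
#' k = w / max(|w|), so k lies in \[-1, 1\] and exactly one gene attains
#' |k| = 1.  Fold-change ties are broken by smaller P, then gene id.
#'
#' @param de data.frame with columns `gene`, `log2fc`, `stat` (signed
#'   test statistic w) and `p`.
#' @param n_per_direction genes selected per direction (default 190).
#' @param p_gate significance gate on the DE P value (default 0.05,
#'   strict).
#' @return data.frame of class `activation_signature`: gene, direction
#'   (up/down), log2fc, w, k.
#' @export
build_signature <- function(de, n_per_direction = 190L, p_gate = 0.05) {
  stopifnot(all(c("gene", "log2fc", "stat", "p") %in% names(de)))
  n_per_direction <- .check_count(n_per_direction, "n_per_direction",
                                  min = 1L)
  .check_prob(p_gate, "p_gate")
  sig <- de[de$p < p_gate & is.finite(de$log2fc) & is.finite(de$stat), ]
  up_pool <- sig[sig$log2fc > 0, ]
  dn_pool <- sig[sig$log2fc < 0, ]
  if (nrow(up_pool) < n_per_direction || nrow(dn_pool) < n_per_direction)
    stop(sprintf(
      "insufficient genes passing P < %g: %d up / %d down available, %d needed per direction",
      p_gate, nrow(up_pool), nrow(dn_pool), n_per_direction))
  pick <- function(pool, decreasing) {
    o <- order(if (decreasing) -pool$log2fc else pool$log2fc,
               pool$p, pool$gene)
    pool[o[seq_len(n_per_direction)], ]
  }
  up <- pick(up_pool, TRUE)
  dn <- pick(dn_pool, FALSE)
  sel <- rbind(cbind(up, direction = "up"), cbind(dn, direction = "down"))
  k <- sel$stat / max(abs(sel$stat))
  out <- data.frame(gene = sel$gene, direction = sel$direction,
                    log2fc = sel$log2fc, w = sel$stat, k = k,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("activation_signature", "data.frame")
  out
}

#' Score expression profiles with an activation signature
#'
#' For each sample, gene expression is converted to z-scores within the
#' sample across the full gene universe of the matrix, and the signature
#' score is S = sum of k_i * z_i over the signature genes present.
#' Higher S means greater similarity to the activation profile.
#' Signature genes missing from the matrix are dropped and reported via
#' the `coverage` attribute.  Because of the within-sample z-scoring, S
#' is invariant to adding a constant to a sample or multiplying it by a
#' positive constant.
#'
#' @param expression numeric matrix, genes x samples (>= 2 genes).
#' @param sig an `activation_signature` from [build_signature()].
#' @param z_within `"sample"` (default) standardizes each sample across
#'   genes; `"gene"` standardizes each gene across samples (per-cohort
#'   alternative).
#' @return Named numeric vector of per-sample scores, with attributes
#'   `coverage` (fraction of signature genes present) and `missing`.
#' @export
score_samples <- function(expression, sig, z_within = c("sample", "gene")) {
  z_within <- match.arg(z_within)
  stopifnot(inherits(sig, "activation_signature"),
            is.matrix(expression), nrow(expression) >= 2L)
  if (!is.numeric(expression)) stop("expression must be numeric")
  if (z_within == "sample") {
    sds <- apply(expression, 2L, sd)
    if (any(sds == 0))
      stop("zero within-sample expression variance in sample(s): ",
           paste(head(colnames(expression)[sds == 0], 5L), collapse = ", "))
    z <- scale(expression)                      # column-wise: per sample
  } else {
    sds <- apply(expression, 1L, sd)
    if (any(sds == 0))
      stop("zero per-gene expression variance; cannot z-score by gene")
    z <- t(scale(t(expression)))
  }
  present <- intersect(sig$gene, rownames(expression))
  if (!length(present)) stop("no signature genes present in the matrix")
  k <- setNames(sig$k, sig$gene)[present]
  s <- colSums(z[present, , drop = FALSE] * k)
  attr(s, "coverage") <- length(present) / nrow(sig)
  attr(s, "missing") <- setdiff(sig$gene, present)
  s
}

#' Composite signature: mean expression of a gene set
#'
#' Unweighted per-sample mean expression of the member genes, as used
#' for the MHC-I (B2M, HLA-A/B/C) and CTL (CD8A, CD8B, GZMA, GZMB,
#' PRF1) immune signatures.
#'
#' @param expression numeric matrix, genes x samples.
#' @param members character vector of member gene ids.
#' @return Named numeric vector of per-sample values; attribute
#'   `missing` lists members absent from the matrix.
#' @export
composite_score <- function(expression, members) {
  present <- intersect(members, rownames(expression))
  if (!length(present))
    stop("none of the composite members are present in the matrix")
  v <- colMeans(expression[present, , drop = FALSE])
  attr(v, "missing") <- setdiff(members, present)
  v
}

#' Member genes of the MHC-I and CTL composite signatures
#' @return Named list of gene sets.
#' @export
immune_signature_genes <- function() {
  list(MHC_I = c("B2M", "HLA-A", "HLA-B", "HLA-C"),
       CTL = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1"))
}

#' Associate per-sample scores with a covariate or group label
#'
#' Spearman or Pearson correlation against a numeric covariate, or a
#' two-tailed unpaired Student's t test against a two-level group label.
#'
#' @param scores named numeric vector of per-sample values.
#' @param covariate numeric vector (correlation) or two-level
#'   factor/character (t test), aligned with `scores`.
#' @param method `"spearman"`, `"pearson"` or `"ttest"`.
#' @return List: method, estimate (rho / r / mean difference), p.value,
#'   n, and `degenerate` (TRUE when a constant input makes the
#'   statistic undefined; estimate and P are NA).
#' @export
associate <- function(scores, covariate,
                      method = c("spearman", "pearson", "ttest")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(covariate))
  if (method %in% c("spearman", "pearson")) {
    if (length(scores) < 3L) stop("need >= 3 paired observations")
    if (sd(scores) == 0 || sd(as.numeric(covariate)) == 0) {
      warning("constant input: correlation undefined")
      return(list(method = method, estimate = NA_real_, p.value = NA_real_,
                  n = length(scores), degenerate = TRUE))
    }
    ct <- suppressWarnings(
      cor.test(scores, as.numeric(covariate), method = method))
    list(method = method, estimate = unname(ct$estimate),
         p.value = ct$p.value, n = length(scores), degenerate = FALSE)
  } else {
    g <- as.factor(covariate)
    if (nlevels(g) != 2L) stop("t test requires exactly two groups")
    if (min(table(g)) < 2L) stop("need >= 2 samples per group")
    tt <- t.test(scores ~ g, var.equal = FALSE)
    list(method = "ttest",
         estimate = unname(diff(rev(tt$estimate))),
         p.value = tt$p.value, n = length(scores), degenerate = FALSE)
  }
}
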