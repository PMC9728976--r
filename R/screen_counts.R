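#' Count guide spacers in sequencing reads
#'
#' A read increments a guide's count when the anchor sequence occurs in
#' the read and the substring immediately following the (first) anchor
#' occurrence exactly equals that guide's spacer.  No mismatches are
#' tolerated.
#'
#' @param reads character vector, [Biostrings::DNAStringSet], or path to
#'   a FASTQ file (optionally gzipped); a named list of any of these
#'   yields a multi-sample count matrix.
#' @param library guide library data.frame with `guide_id` and `spacer`;
#'   all spacers must have equal length and be unique.
#' @param anchor constant sequence immediately preceding the spacer in a
#'   read (default: the conventional U6-vector junction).
#' @return For a single sample, a named integer vector of guide counts
#'   with attributes `n_reads`, `n_anchored` (reads containing the
#'   anchor) and `n_no_match` (anchored reads whose spacer matched no
#'   guide).  For a list input, an integer matrix guide x sample with a
#'   `stats` attribute (data.frame per sample).
#' @export
count_spacers <- function(reads, library, anchor = "CGAAACACCG") {
  stopifnot(nzchar(anchor), all(c("guide_id", "spacer") %in% names(library)))
  if (anyDuplicated(library$spacer))
    stop("duplicate spacers in library: counting would be ambiguous")
  sl <- unique(nchar(library$spacer))
  if (length(sl) != 1L)
    stop("all spacers must have the same length")

  if (is.list(reads) && !methods::is(reads, "DNAStringSet")) {
    per <- lapply(reads, count_spacers, library = library, anchor = anchor)
    counts <- do.call(cbind, per)
    stats <- do.call(rbind, lapply(names(per), function(s) {
      a <- per[[s]]
      data.frame(sample = s, n_reads = attr(a, "n_reads"),
                 n_anchored = attr(a, "n_anchored"),
                 n_no_match = attr(a, "n_no_match"),
                 stringsAsFactors = FALSE)
    }))
    dimnames(counts) <- list(library$guide_id, names(per))
    attr(counts, "stats") <- stats
    return(counts)
  }

  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  reads <- toupper(as.character(reads))

  pos <- regexpr(anchor, reads, fixed = TRUE)
  anchored <- pos > 0L
  sp_start <- pos[anchored] + nchar(anchor)
  found <- substr(reads[anchored], sp_start, sp_start + sl - 1L)
  idx <- match(found, library$spacer)
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$guide_id
  attr(counts, "n_reads") <- length(reads)
  attr(counts, "n_anchored") <- sum(anchored)
  attr(counts, "n_no_match") <- sum(is.na(idx))
  counts
}

#' Pseudocount/total-count normalization of screen counts
#'
#' Adds a pseudocount of 1 to every raw count, then divides by the
#' per-sample total of the pseudocounted counts and multiplies by
#' `scale`.  The pseudocount is applied before the totals are taken, so
#' normalized values are strictly positive and each column sums to
#' `scale` exactly.
#'
#' @param counts nonnegative integer matrix, guides x samples.
#' @param scale normalization scale constant (default 1e6,
#'   counts-per-million); any positive value cancels in fold changes.
#' @param pseudocount added to each raw count (default 1).
#' @return Numeric matrix of normalized counts, same dimnames.
#' @export
normalize_counts <- function(counts, scale = 1e6, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  .check_number(scale, "scale", min = 0, strict = TRUE)
  pc <- counts + pseudocount
  sweep(pc, 2L, colSums(pc), "/") * scale
}

#' Guide-level log2 fold change between two samples
#'
#' @param norm normalized count matrix from [normalize_counts()].
#' @param treated,control column names (or indices) of the comparison.
#' @return Named numeric vector: log2(treated / control) per guide.
#' @export
log2fc <- function(norm, treated, control) {
  if (is.character(treated) && !treated %in% colnames(norm))
    stop("treated sample '", treated, "' not found")
  if (is.character(control) && !control %in% colnames(norm))
    stop("control sample '", control, "' not found")
  setNames(log2(norm[, treated] / norm[, control]), rownames(norm))
}

#' Fold-change table over several treated-vs-control comparisons
#'
#' @param norm normalized count matrix.
#' @param comparisons named list; each element `c(treated, control)`,
#'   names label the comparisons.  Default is the two-replicate coculture
#'   design, S1 and S2 each against C2.
#' @return Numeric matrix guides x comparisons of log2 fold changes.
#' @export
fc_table <- function(norm, comparisons = list(S1_vs_C2 = c("S1", "C2"),
                                              S2_vs_C2 = c("S2", "C2"))) {
  stopifnot(length(comparisons) > 0L, !is.null(names(comparisons)))
  out <- vapply(comparisons,
                function(cc) log2fc(norm, cc[[1L]], cc[[2L]]),
                numeric(nrow(norm)))
  rownames(out) <- rownames(norm)
  out
}

#' Replicate-correlation quality control
#'
#' Pearson correlation of raw guide counts between replicate sample
#' pairs and of guide log2 fold changes between comparison pairs, as
#' used to judge screen reproducibility.
#'
#' @param counts raw count matrix (guides x samples); set `log = TRUE`
#'   to correlate log2(count + 1) instead.
#' @param fc optional fold-change matrix from [fc_table()].
#' @param count_pairs list of sample-name pairs to correlate (default
#'   the treated replicates S1/S2 when present).
#' @param log correlate counts on the log scale.
#' @return data.frame: type (counts / log2fc), pair, r, p, n.  Constant
#'   vectors give NA with a note in the `note` column.
#' @export
qc_correlations <- function(counts, fc = NULL, count_pairs = NULL,
                            log = FALSE) {
  if (is.null(count_pairs)) {
    count_pairs <- if (all(c("S1", "S2") %in% colnames(counts)))
      list(c("S1", "S2")) else list()
  }
  one <- function(x, y, type, pair) {
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(type = type, pair = pair, r = NA_real_,
                        p = NA_real_, n = length(x),
                        note = "constant vector: correlation undefined",
                        stringsAsFactors = FALSE))
    ct <- cor.test(x, y, method = "pearson")
    data.frame(type = type, pair = pair, r = unname(ct$estimate),
               p = ct$p.value, n = length(x), note = "",
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (pp in count_pairs) {
    x <- counts[, pp[[1L]]]; y <- counts[, pp[[2L]]]
    if (log) { x <- log2(x + 1); y <- log2(y + 1) }
    out[[length(out) + 1L]] <-
      one(x, y, "counts", paste(pp, collapse = " vs "))
  }
  if (!is.null(fc) && ncol(fc) >= 2L) {
    cmb <- combn(colnames(fc), 2L)
    for (k in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <-
        one(fc[, cmb[1L, k]], fc[, cmb[2L, k]], "log2fc",
            paste(cmb[, k], collapse = " vs "))
  }
  if (!length(out))
    return(data.frame(type = character(0), pair = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      note = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
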