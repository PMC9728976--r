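#' Locate guide spacers in a genome by exact motif search
#'
#' Treats each spacer as a plain DNA motif and reports every exact match
#' on either genomic strand, in 0-based half-open coordinates.  Guides
#' whose spacer contains ambiguous bases are skipped with a warning;
#' guides with no match anywhere (e.g. nontargeting controls) are listed
#' in the `unmatched` attribute.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @param library guide library data.frame with columns `guide_id` and
#'   `spacer`.
#' @return data.frame of loci: guide_id, chrom, start, end (0-based
#'   half-open), strand; one row per match, multi-matching guides keep
#'   all loci.  Attribute `unmatched` holds guide ids with zero matches.
#' @export
find_spacer_sites <- function(genome, library) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  stopifnot(all(c("guide_id", "spacer") %in% names(library)))

  spacer <- toupper(library$spacer)
  ok <- .is_dna(spacer)
  if (any(!ok)) {
    warning(sum(!ok), " guide(s) with ambiguous bases skipped: ",
            paste(head(library$guide_id[!ok], 5L), collapse = ", "))
    library <- library[ok, , drop = FALSE]
    spacer <- spacer[ok]
  }

  one_strand <- function(patterns, strand_label) {
    rows <- list()
    for (w in unique(nchar(patterns))) {       # PDict needs constant width
      sel <- which(nchar(patterns) == w)
      pd <- Biostrings::PDict(patterns[sel])
      for (ci in seq_along(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[ci]])
        n_hit <- lengths(m)
        if (sum(n_hit) == 0L) next
        st <- unlist(lapply(m, IRanges::start), use.names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          guide_id = rep(library$guide_id[sel], n_hit),
          chrom = names(genome)[ci],
          start = st - 1L,                     # to 0-based half-open
          end = st - 1L + w,
          strand = strand_label, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  loci <- rbind(one_strand(spacer, "+"),
                one_strand(.revcomp(spacer), "-"))
  if (is.null(loci))
    loci <- data.frame(guide_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
  loci <- loci[order(loci$guide_id, loci$chrom, loci$start, loci$strand), ,
               drop = FALSE]
  rownames(loci) <- NULL
  attr(loci, "unmatched") <- setdiff(library$guide_id, loci$guide_id)
  loci
}

#' Strand-aware promoter windows around transcription start sites
#'
#' For each transcript, the promoter window covers `upstream` bases
#' upstream through `downstream` bases downstream of the TSS.  The TSS
#' is the transcript start on the plus strand and the transcript end on
#' the minus strand, where "upstream" means higher coordinates.  Windows
#' are reported 0-based half-open and clipped to chromosome bounds when
#' lengths are supplied.
#'
#' @param annotation data.frame with columns transcript_id, chrom, start,
#'   end (1-based inclusive, GTF convention), strand.
#' @param upstream,downstream window extent in bases (defaults -1000/+100).
#' @param chrom_lengths optional named vector of chromosome lengths used
#'   to clip windows; windows are always clipped at 0 on the left.
#' @return data.frame: transcript_id, chrom, strand, tss (0-based),
#'   start, end (0-based half-open).
#' @export
promoter_windows <- function(annotation, upstream = 1000L,
                             downstream = 100L, chrom_lengths = NULL) {
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(annotation)))
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand for transcript(s): ",
         paste(head(annotation$transcript_id[bad], 5L), collapse = ", "))
  plus <- annotation$strand == "+"
  # 0-based TSS: interval start for plus, last base for minus
  tss0 <- ifelse(plus, annotation$start - 1L, annotation$end - 1L)
  w_start <- ifelse(plus, tss0 - upstream, tss0 - downstream)
  w_end <- ifelse(plus, tss0 + downstream, tss0 + upstream)
  w_start <- pmax(w_start, 0L)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[annotation$chrom]
    if (anyNA(len)) stop("chrom_lengths missing some chromosomes")
    w_end <- pmin(w_end, unname(len))
  }
  data.frame(transcript_id = annotation$transcript_id,
             chrom = annotation$chrom, strand = annotation$strand,
             tss = as.integer(tss0), start = as.integer(w_start),
             end = as.integer(w_end), stringsAsFactors = FALSE)
}

#' Assign guides to transcripts through promoter-window overlap
#'
#' A guide is assigned to a transcript when any of its genomic loci
#' overlaps the transcript's promoter window by at least one base
#' (`containment = TRUE` requires the full locus inside the window).
#' Transcripts with fewer than `min_guides` assigned guides are dropped
#' from the transcript-side map; guides overlapping several windows are
#' kept in all of them.
#'
#' @param loci data.frame from [find_spacer_sites()].
#' @param windows data.frame from [promoter_windows()].
#' @param min_guides minimum distinct guides for a transcript to count
#'   as a target (default 2).
#' @param biotype optional named vector of per-transcript biotype classes
#'   (e.g. from [classify_biotype()]) carried into the map.
#' @param containment require the whole locus inside the window instead
#'   of 1-base overlap.
#' @return Object of class `target_map`: list with `transcripts` (named
#'   list transcript -> guide ids, only transcripts passing
#'   `min_guides`), `guides` (named list guide -> transcript ids),
#'   `biotype` (named vector), and `summary` (data.frame of target
#'   counts per biotype class).
#' @export
build_target_map <- function(loci, windows, min_guides = 2L,
                             biotype = NULL, containment = FALSE) {
  min_guides <- .check_count(min_guides, "min_guides", min = 1L)
  if (nrow(loci) == 0L || nrow(windows) == 0L) {
    warning("empty loci or windows: returning an empty target map")
    return(.target_map(list(), list(), character(0)))
  }
  lg <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  wg <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  ov <- GenomicRanges::findOverlaps(
    lg, wg, type = if (containment) "within" else "any", minoverlap = 1L)
  pairs <- unique(data.frame(
    guide = loci$guide_id[S4Vectors::queryHits(ov)],
    tx = windows$transcript_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  guides <- split(pairs$tx, pairs$guide)
  tx_all <- split(pairs$guide, pairs$tx)
  keep <- vapply(tx_all, function(g) length(unique(g)) >= min_guides,
                 logical(1))
  transcripts <- tx_all[keep]
  bt <- if (is.null(biotype)) {
    setNames(rep("other", length(transcripts)), names(transcripts))
  } else {
    cls <- biotype[names(transcripts)]
    cls[is.na(cls)] <- "other"
    setNames(as.character(cls), names(transcripts))
  }
  .target_map(transcripts, guides, bt)
}

.target_map <- function(transcripts, guides, biotype) {
  summary <- as.data.frame(table(class = biotype),
                           responseName = "n_targets",
                           stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, guides = guides,
                 biotype = biotype, summary = summary),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", length(x$transcripts), "target transcripts,",
      length(x$guides), "assigned guides\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Build a target map from the library's nominal annotation
#'
#' Uses the `nominal_target` column instead of genomic reannotation;
#' handy for simulations and for comparing nominal vs reannotated maps.
#'
#' @param library guide library data.frame.
#' @param min_guides minimum guides per transcript (default 2).
#' @return A `target_map` (see [build_target_map()]).
#' @export
targets_from_library <- function(library, min_guides = 2L) {
  keep <- !library$is_control & nzchar(library$nominal_target)
  tx_all <- split(library$guide_id[keep], library$nominal_target[keep])
  tx <- tx_all[lengths(tx_all) >= min_guides]
  guides <- split(rep(names(tx), lengths(tx)), unlist(tx, use.names = FALSE))
  .target_map(tx, guides, setNames(rep("other", length(tx)), names(tx)))
}

#' Classify transcript biotypes
#'
#' Uses the annotation's `biotype` column when present (GENCODE-style
#' tags are mapped: `protein_coding` to protein-coding, `lincRNA` to
#' lncRNA-intergenic, `antisense` to lncRNA-antisense).  Transcripts
#' without a recognized tag are classified by overlap: a transcript
#' overlapping a protein-coding transcript on the opposite strand is
#' lncRNA-antisense; one with no protein-coding overlap is
#' lncRNA-intergenic; anything else is "other".
#'
#' @param annotation data.frame with transcript_id, chrom, start, end,
#'   strand and optionally biotype.
#' @return Named character vector of classes per transcript:
#'   lncRNA-intergenic, lncRNA-antisense, protein-coding or other.
#' @export
classify_biotype <- function(annotation) {
  n <- nrow(annotation)
  cls <- rep(NA_character_, n)
  tag <- if ("biotype" %in% names(annotation)) annotation$biotype
         else rep(NA_character_, n)
  cls[tag %in% c("protein_coding", "protein-coding")] <- "protein-coding"
  cls[tag %in% c("lincRNA", "lncRNA-intergenic")] <- "lncRNA-intergenic"
  cls[tag %in% c("antisense", "lncRNA-antisense")] <- "lncRNA-antisense"

  todo <- which(is.na(cls))
  if (length(todo)) {
    pc <- which(cls == "protein-coding")
    gr <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(annotation$start, annotation$end),
      strand = annotation$strand)
    if (length(pc)) {
      ov <- GenomicRanges::findOverlaps(gr[todo], gr[pc],
                                        ignore.strand = TRUE)
      opp <- annotation$strand[todo][S4Vectors::queryHits(ov)] !=
        annotation$strand[pc][S4Vectors::subjectHits(ov)]
      anti <- unique(S4Vectors::queryHits(ov)[opp])
      any_pc <- unique(S4Vectors::queryHits(ov))
      cls[todo[anti]] <- "lncRNA-antisense"
      cls[todo[setdiff(seq_along(todo), any_pc)]] <- "lncRNA-intergenic"
      cls[is.na(cls)] <- "other"   # same-strand protein-coding overlap
    } else {
      cls[todo] <- "lncRNA-intergenic"
    }
  }
  setNames(cls, annotation$transcript_id)
}
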