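# Readers and writers for the pipeline's plain-text interchange formats.
# Internal coordinates are 0-based half-open; GTF is written/read 1-based
# inclusive and BED 0-based half-open, as those formats require.

#' Read / write a guide library TSV
#'
#' Columns: guide_id, spacer, nominal_target, is_control.  Controls have
#' an empty nominal_target.
#'
#' @param path file path.
#' @return data.frame guide library.
#' @export
read_guide_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(nominal_target = "character"))
  stopifnot(all(c("guide_id", "spacer", "nominal_target",
                  "is_control") %in% names(lib)))
  if (anyDuplicated(lib$guide_id)) stop("duplicate guide ids in library")
  lib$is_control <- as.logical(lib$is_control)
  lib$nominal_target[is.na(lib$nominal_target)] <- ""
  lib
}

#' @rdname read_guide_library
#' @param library guide library data.frame.
#' @export
write_guide_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a guide-by-sample count table TSV
#'
#' First column `guide_id`, one column per sample.
#'
#' @param path file path.
#' @return Integer matrix with guide rownames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  stopifnot(names(tab)[1L] == "guide_id")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$guide_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts matrix guides x samples.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(
    data.frame(guide_id = rownames(counts), counts, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic reference to FASTA / GTF / TSV files
#'
#' @param ref an `lncact_reference` from [make_reference()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "lncact_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  lib <- file.path(dir, "library.tsv")
  Biostrings::writeXStringSet(ref$genome, fasta)
  write_annotation_gtf(ref$annotation, gtf)
  write_guide_library(ref$library, lib)
  c(genome = fasta, annotation = gtf, library = lib)
}

#' Read / write transcript annotation as GTF
#'
#' `write_annotation_gtf` emits one `transcript` feature per row with
#' gene_id, transcript_id and gene_biotype attributes;
#' `read_annotation_gtf` returns the transcript features of a GTF as
#' the annotation data.frame the package uses (1-based inclusive
#' coordinates).
#'
#' @param path GTF file path.
#' @return data.frame: transcript_id, gene_id, chrom, start, end,
#'   strand, biotype.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "transcript"]
  md <- S4Vectors::mcols(gr)
  bt <- if ("gene_biotype" %in% names(md)) md$gene_biotype
        else if ("biotype" %in% names(md)) md$biotype
        else rep(NA_character_, length(gr))
  data.frame(transcript_id = md$transcript_id, gene_id = md$gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             biotype = bt, stringsAsFactors = FALSE)
}

#' @rdname read_annotation_gtf
#' @param annotation annotation data.frame (see [make_reference()]).
#' @export
write_annotation_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = "transcript",
    source = "lncact",
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    gene_biotype = annotation$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write spacer loci as BED (0-based half-open)
#'
#' @param loci data.frame from [find_spacer_sites()].
#' @param path BED file path.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end),
    strand = loci$strand)
  names(gr) <- loci$guide_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a target map as TSV
#'
#' One row per target transcript: transcript_id, biotype_class,
#' n_guides, guide_ids (semicolon-joined).
#'
#' @param map a `target_map`.
#' @param path file path.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  tx <- names(map$transcripts)
  tab <- data.frame(
    transcript_id = tx,
    biotype_class = unname(map$biotype[tx]),
    n_guides = vapply(map$transcripts, function(g) length(unique(g)),
                      integer(1)),
    guide_ids = vapply(map$transcripts,
                       function(g) paste(sort(unique(g)), collapse = ";"),
                       character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
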