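# a hand-built two-chromosome genome with known plants
.toy_genome <- function() {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  chrA <- sample(bases, 400, replace = TRUE)
  chrB <- sample(bases, 300, replace = TRUE)
  sp1 <- "ACGTACGTACGTACGTACGA"          # plant forward on chrA at 0-based 50
  sp2 <- "TTGACCTGAAGGTCATTGCA"          # plant reverse on chrB at 0-based 120
  chrA[51:70] <- strsplit(sp1, "")[[1]]
  rc2 <- chartr("ACGT", "TGCA",
                paste(rev(strsplit(sp2, "")[[1]]), collapse = ""))
  chrB[121:140] <- strsplit(rc2, "")[[1]]
  genome <- c(chrA = paste(chrA, collapse = ""),
              chrB = paste(chrB, collapse = ""))
  lib <- data.frame(guide_id = c("g1", "g2", "g3"),
                    spacer = c(sp1, sp2, "GGGGGGGGGGGGGGGGGGGG"),
                    nominal_target = c("t1", "t2", ""),
                    is_control = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  list(genome = genome, lib = lib)
}

test_that("find_spacer_sites reports exact matches on both strands", {
  toy <- .toy_genome()
  loci <- find_spacer_sites(toy$genome, toy$lib)
  g1 <- loci[loci$guide_id == "g1", ]
  expect_equal(nrow(g1), 1)
  expect_identical(g1$chrom, "chrA")
  expect_equal(g1$start, 50)
  expect_equal(g1$end, 70)
  expect_identical(g1$strand, "+")
  g2 <- loci[loci$guide_id == "g2", ]
  expect_equal(nrow(g2), 1)
  expect_identical(g2$strand, "-")
  expect_equal(g2$start, 120)
  expect_identical(attr(loci, "unmatched"), "g3")
})

test_that("a spacer and its reverse complement planted give distinct strands, matching a naive scan", {
  set.seed(7)
  chr <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  sp <- "ATCGGATTACCAGGTTCAAC"            # palindrome-free
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(sp, "")[[1]]), collapse = ""))
  chr[101:120] <- strsplit(sp, "")[[1]]
  chr[301:320] <- strsplit(rc, "")[[1]]
  genome <- c(chr1 = paste(chr, collapse = ""))
  lib <- data.frame(guide_id = "g", spacer = sp, nominal_target = "t",
                    is_control = FALSE, stringsAsFactors = FALSE)
  loci <- find_spacer_sites(genome, lib)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$strand, c("+", "-"))
  oracle <- naive_find_sites(genome[["chr1"]], sp)
  expect_equal(sort(loci$start),
               sort(vapply(oracle, function(h) as.integer(h["start"]),
                           integer(1))))
})

test_that("ambiguous-base spacers are skipped with a warning", {
  toy <- .toy_genome()
  lib <- rbind(toy$lib,
               data.frame(guide_id = "gN", spacer = "ACGTNACGTNACGTNACGTN",
                          nominal_target = "tN", is_control = FALSE))
  expect_warning(loci <- find_spacer_sites(toy$genome, lib), "ambiguous")
  expect_false("gN" %in% loci$guide_id)
})

test_that("promoter windows follow the strand-aware -1000/+100 rule", {
  ann <- data.frame(
    transcript_id = c("plus", "minus", "edge"),
    chrom = "chr1",
    start = c(5001, 3001, 301),        # 1-based inclusive
    end = c(6000, 5001, 900),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- promoter_windows(ann, chrom_lengths = c(chr1 = 10000))
  # plus-strand TSS at 0-based 5000: [4000, 5100)
  expect_equal(unlist(w[w$transcript_id == "plus", c("start", "end")],
                      use.names = FALSE), c(4000, 5100))
  # minus-strand TSS at 0-based 5000: [4900, 6000)
  expect_equal(unlist(w[w$transcript_id == "minus", c("start", "end")],
                      use.names = FALSE), c(4900, 6000))
  # TSS at 0-based 300 clips at the chromosome edge: [0, 400)
  expect_equal(unlist(w[w$transcript_id == "edge", c("start", "end")],
                      use.names = FALSE), c(0, 400))
  expect_error(promoter_windows(transform(ann, strand = ".")),
               "unknown strand")
})

test_that("build_target_map applies the >=2-guide rule, edge inclusion and multi-mapping", {
  windows <- data.frame(
    transcript_id = c("tx1", "tx2", "tx3"),
    chrom = "chr1", strand = "+",
    tss = c(2000, 6000, 2080),
    start = c(1000, 5000, 1080), end = c(2100, 6100, 2180),
    stringsAsFactors = FALSE)
  loci <- data.frame(
    guide_id = c("a", "b", "c", "d"),
    chrom = "chr1",
    # a at tx1 window start (TSS-1000), b ends at TSS+99 inclusive,
    # c single guide in tx2, d overlaps both tx1 and tx3 windows
    start = c(1000, 2079, 5500, 2085),
    end = c(1020, 2099, 5520, 2105),
    strand = "+", stringsAsFactors = FALSE)
  tm <- build_target_map(loci, windows, min_guides = 2)
  # tx1 keeps a (at TSS-1000), b (ending at TSS+99) and d; tx3 keeps
  # b and d; tx2 is dropped with a single in-window guide
  expect_setequal(names(tm$transcripts), c("tx1", "tx3"))
  expect_setequal(tm$transcripts$tx1, c("a", "b", "d"))
  expect_setequal(tm$transcripts$tx3, c("b", "d"))
  expect_setequal(tm$guides$d, c("tx1", "tx3"))     # guide-side keeps both
  expect_false("tx2" %in% names(tm$transcripts))
  # agreement with the brute-force overlap oracle
  br <- brute_assignments(loci, windows)
  for (g in unique(br$guide))
    expect_setequal(tm$guides[[g]], br$tx[br$guide == g])
  expect_warning(empty <- build_target_map(loci[0, ], windows), "empty")
  expect_length(empty$transcripts, 0)
})

test_that("enlarging the window never removes assignments", {
  ref <- small_reference()
  loci <- find_spacer_sites(ref$genome, ref$library)
  w1 <- promoter_windows(ref$annotation, 1000, 100)
  w2 <- promoter_windows(ref$annotation, 2000, 400)
  t1 <- build_target_map(loci, w1)
  t2 <- build_target_map(loci, w2)
  for (g in names(t1$guides))
    expect_true(all(t1$guides[[g]] %in% t2$guides[[g]]))
})

test_that("reverse-complementing the genome and flipping strands leaves the target map invariant", {
  ref <- small_reference(seed = 6)
  loci <- find_spacer_sites(ref$genome, ref$library)
  win <- promoter_windows(ref$annotation)
  tm <- build_target_map(loci, win)

  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  genome_rc <- Biostrings::reverseComplement(ref$genome)
  names(genome_rc) <- names(ref$genome)
  ann <- ref$annotation
  new_start <- lens[ann$chrom] - ann$end + 1L
  new_end <- lens[ann$chrom] - ann$start + 1L
  ann$start <- unname(new_start)
  ann$end <- unname(new_end)
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  loci2 <- find_spacer_sites(genome_rc, ref$library)
  win2 <- promoter_windows(ann)
  tm2 <- build_target_map(loci2, win2)

  expect_setequal(names(tm$transcripts), names(tm2$transcripts))
  for (tx in names(tm$transcripts))
    expect_setequal(tm$transcripts[[tx]], tm2$transcripts[[tx]])
})

test_that("biotype classification uses tags, then opposite-strand overlap", {
  ann <- data.frame(
    transcript_id = c("pc", "linc", "as", "lone", "inside"),
    chrom = c("chr1", "chr1", "chr1", "chr9", "chr1"),
    start = c(1000, 20000, 1200, 100, 1300),
    end = c(2000, 21000, 1800, 900, 1700),
    strand = c("+", "+", "-", "+", "-"),
    biotype = c("protein_coding", "lincRNA", "antisense", NA, NA),
    stringsAsFactors = FALSE)
  cls <- classify_biotype(ann)
  expect_identical(unname(cls["pc"]), "protein-coding")
  expect_identical(unname(cls["linc"]), "lncRNA-intergenic")
  expect_identical(unname(cls["as"]), "lncRNA-antisense")
  # untagged, fully inside a coding gene on the opposite strand
  expect_identical(unname(cls["inside"]), "lncRNA-antisense")
  # untagged, on a gene-free contig
  expect_identical(unname(cls["lone"]), "lncRNA-intergenic")
})
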