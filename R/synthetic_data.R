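#' Configuration for a synthetic CRISPRa screen
#'
#' Bundles the parameters of the synthetic screen generator.  Defaults
#' describe a desk-scale screen: 200 targeted transcripts with 10 guides
#' each plus 50 nontargeting controls, two treated replicates against
#' plasmid/control samples at a depth of 10^6 reads, with 10 enriched and
#' 10 depleted transcripts planted at a mean log2 effect of 2 carried by
#' 6 of each hit's 10 guides.
#'
#' @param seed integer seed; the same configuration always yields
#'   byte-identical outputs.
#' @param n_genes number of targeted transcripts.
#' @param guides_per_gene guides designed against each transcript's
#'   promoter.
#' @param n_nontargeting nontargeting control guides whose spacers occur
#'   nowhere in the genome.
#' @param n_functional_guides_per_hit how many of a planted hit's guides
#'   actually carry the effect (guide efficacy is heterogeneous in real
#'   libraries; must not exceed `guides_per_gene`).
#' @param effect_log2fc planted mean log2 enrichment (depletion uses the
#'   negated value).
#' @param dispersion negative-binomial overdispersion of the counts
#'   (variance = mu + dispersion * mu^2); must be > 0.
#' @param depth_per_sample total sequencing reads per sample.
#' @param n_planted_enriched,n_planted_depleted number of transcripts
#'   planted as enriched / depleted in the treated replicates.
#' @param spacer_length spacer width in nucleotides.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [make_reference()], [simulate_screen()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       guides_per_gene = 10L,
                       n_nontargeting = 50L,
                       n_functional_guides_per_hit = 6L,
                       effect_log2fc = 2,
                       dispersion = 0.2,
                       depth_per_sample = 1e6,
                       n_planted_enriched = 10L,
                       n_planted_depleted = 10L,
                       spacer_length = 20L) {
  cfg <- list(
    seed = .check_count(seed, "seed"),
    n_genes = .check_count(n_genes, "n_genes", min = 1L),
    guides_per_gene = .check_count(guides_per_gene, "guides_per_gene", min = 1L),
    n_nontargeting = .check_count(n_nontargeting, "n_nontargeting"),
    n_functional_guides_per_hit =
      .check_count(n_functional_guides_per_hit, "n_functional_guides_per_hit"),
    effect_log2fc = .check_number(effect_log2fc, "effect_log2fc"),
    dispersion = .check_number(dispersion, "dispersion", min = 0, strict = TRUE),
    depth_per_sample = .check_number(depth_per_sample, "depth_per_sample",
                                     min = 0, strict = TRUE),
    n_planted_enriched = .check_count(n_planted_enriched, "n_planted_enriched"),
    n_planted_depleted = .check_count(n_planted_depleted, "n_planted_depleted"),
    spacer_length = .check_count(spacer_length, "spacer_length", min = 10L)
  )
  if (cfg$n_functional_guides_per_hit > cfg$guides_per_gene)
    stop("n_functional_guides_per_hit must not exceed guides_per_gene")
  if (cfg$n_planted_enriched + cfg$n_planted_depleted > cfg$n_genes)
    stop("more planted hits than genes")
  structure(cfg, class = "sim_config")
}

# layout constants of the toy genome: one gene slot every `pitch` bases,
# transcripts of fixed length, at most `per_chrom` slots per chromosome
.GENE_PITCH <- 3000L
.TX_LEN <- 800L
.SLOTS_PER_CHROM <- 50L
.UP <- 1000L     # promoter window: UP bases upstream ...
.DOWN <- 100L    # ... through DOWN bases downstream of the TSS

#' Generate a toy genome, transcript annotation and guide library
#'
#' Builds a random genome in which every targeting guide's spacer is
#' planted exactly once, inside the promoter window (-1000/+100 of the
#' TSS, strand-aware) of its intended transcript, on a randomly chosen
#' genomic strand.  Nontargeting spacers are random sequences verified to
#' occur nowhere in the genome.  Transcripts cycle through biotypes
#' (intergenic lncRNA, antisense lncRNA, protein-coding) on alternating
#' strands; each antisense lncRNA is accompanied by an untargeted
#' protein-coding partner overlapping it on the opposite strand so that
#' overlap-based biotype classification is exercised.
#'
#' @param config a [sim_config()].
#' @return A list of class `lncact_reference` with elements
#'   `genome` (a [Biostrings::DNAStringSet]),
#'   `annotation` (data.frame: transcript_id, gene_id, chrom, start, end
#'   in 1-based inclusive coordinates, strand, biotype, targeted), and
#'   `library` (data.frame: guide_id, spacer, nominal_target, is_control).
#' @details Every planted spacer is verified against the finished genome
#'   on both strands; a spacer that matches more than once (or a
#'   nontargeting spacer that matches at all) aborts generation with an
#'   error rather than returning an inconsistent reference.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.child_seed(config$seed, 1L), {
    n <- config$n_genes
    sl <- config$spacer_length
    gpg <- config$guides_per_gene
    biotypes <- rep(c("lincRNA", "antisense", "protein_coding"),
                    length.out = n)
    strands <- rep(c("+", "-"), length.out = n)
    chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% .SLOTS_PER_CHROM + 1L)
    slot <- (seq_len(n) - 1L) %% .SLOTS_PER_CHROM
    center <- 1500L + slot * .GENE_PITCH     # 0-based TSS anchor
    chroms <- unique(chrom_of)
    chrom_len <- vapply(chroms, function(ch) {
      max(center[chrom_of == ch]) + .GENE_PITCH
    }, integer(1))

    # random background, kept as per-chromosome character vectors so
    # spacers can be planted by in-place substitution
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(chrom_len, function(L) sample(bases, L, replace = TRUE))
    names(seqs) <- chroms

    tx_id <- sprintf("TX%04d", seq_len(n))
    # 0-based half-open transcript bodies; plus-strand TSS at interval
    # start, minus-strand TSS at the last base of the interval
    tx_start0 <- center
    tx_end0 <- center + .TX_LEN
    tss0 <- ifelse(strands == "+", tx_start0, tx_end0 - 1L)
    win_start0 <- ifelse(strands == "+", tss0 - .UP, tss0 - .DOWN)

    # distinct non-overlapping slots inside the 1100-base window
    n_slots <- (.UP + .DOWN) %/% (sl + 2L)
    if (gpg > n_slots)
      stop("guides_per_gene too large for the promoter window")
    guide_rows <- vector("list", n)
    for (i in seq_len(n)) {
      offs <- sort(sample.int(n_slots, gpg) - 1L) * (sl + 2L)
      pos0 <- win_start0[i] + offs
      gstrand <- sample(c("+", "-"), gpg, replace = TRUE)
      spacers <- vapply(seq_len(gpg), function(j)
        paste(sample(bases, sl, replace = TRUE), collapse = ""), character(1))
      planted <- ifelse(gstrand == "+", spacers, .revcomp(spacers))
      for (j in seq_len(gpg)) {
        idx <- (pos0[j] + 1L):(pos0[j] + sl)       # 1-based into char vector
        seqs[[chrom_of[i]]][idx] <- strsplit(planted[j], "")[[1]]
      }
      guide_rows[[i]] <- data.frame(
        guide_id = sprintf("%s_g%02d", tx_id[i], seq_len(gpg)),
        spacer = spacers, nominal_target = tx_id[i], is_control = FALSE,
        stringsAsFactors = FALSE)
    }
    nt <- if (config$n_nontargeting > 0L) {
      data.frame(
        guide_id = sprintf("NT_g%03d", seq_len(config$n_nontargeting)),
        spacer = vapply(seq_len(config$n_nontargeting), function(j)
          paste(sample(bases, sl, replace = TRUE), collapse = ""),
          character(1)),
        nominal_target = "", is_control = TRUE, stringsAsFactors = FALSE)
    } else NULL
    library <- rbind(do.call(rbind, guide_rows), nt)
    rownames(library) <- NULL
    if (anyDuplicated(library$spacer))
      stop("spacer collision: duplicate spacer drawn during generation")

    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = ""))
    names(genome) <- chroms

    # untargeted antisense partners: protein-coding gene overlapping each
    # antisense lncRNA on the opposite strand, promoter pointing away from
    # the lncRNA's guide-bearing window
    anti <- which(biotypes == "antisense")
    partner <- if (length(anti)) {
      data.frame(
        transcript_id = sprintf("PC%04d", anti),
        gene_id = sprintf("PCG%04d", anti),
        chrom = chrom_of[anti],
        start = center[anti] + 201L,            # 1-based inclusive
        end = center[anti] + 900L,
        strand = ifelse(strands[anti] == "+", "-", "+"),
        biotype = "protein_coding",
        targeted = FALSE, stringsAsFactors = FALSE)
    } else NULL
    annotation <- rbind(
      data.frame(transcript_id = tx_id, gene_id = gsub("^TX", "G", tx_id),
                 chrom = chrom_of, start = tx_start0 + 1L, end = tx_end0,
                 strand = strands, biotype = biotypes, targeted = TRUE,
                 stringsAsFactors = FALSE),
      partner)
    rownames(annotation) <- NULL

    .verify_spacer_uniqueness(genome, library)
    structure(list(genome = genome, annotation = annotation,
                   library = library),
              class = "lncact_reference")
  })
}

# exhaustive both-strand occurrence check of every spacer in the genome
.verify_spacer_uniqueness <- function(genome, library) {
  pd_f <- Biostrings::PDict(library$spacer)
  pd_r <- Biostrings::PDict(.revcomp(library$spacer))
  hits <- rowSums(Biostrings::vcountPDict(pd_f, genome)) +
    rowSums(Biostrings::vcountPDict(pd_r, genome))
  bad_t <- !library$is_control & hits != 1L
  bad_c <- library$is_control & hits != 0L
  if (any(bad_t))
    stop("spacer collision: targeting spacer(s) not unique in genome: ",
         paste(head(library$guide_id[bad_t], 5L), collapse = ", "))
  if (any(bad_c))
    stop("spacer collision: nontargeting spacer(s) present in genome: ",
         paste(head(library$guide_id[bad_c], 5L), collapse = ", "))
  invisible(TRUE)
}

#' Simulate screen counts with planted enrichment and depletion
#'
#' Draws a guide-by-sample count matrix for the five-sample design used
#' in coculture screens: plasmid library `P`, two control cultures
#' `C1`/`C2`, and two treated (T-cell cocultured) replicates `S1`/`S2`.
#' Per-guide baseline abundances follow a log-normal library-composition
#' draw shared across samples; counts are negative binomial around
#' depth-scaled abundances.  In `S1`/`S2` only, the functional guides of
#' planted-enriched transcripts have their abundance multiplied by
#' `2^effect_log2fc` (planted-depleted divided by it) before per-sample
#' renormalization to the fixed sequencing depth.
#'
#' @param library guide library data.frame as from [make_reference()].
#' @param config a [sim_config()].
#' @return List with elements `counts` (integer matrix, guides x samples
#'   P,C1,C2,S1,S2), `roles` (named character: plasmid/control/treated),
#'   and `truth` (list: `enriched`, `depleted` transcript ids and
#'   `functional_guides`, the guide ids carrying the planted effect).
#' @export
simulate_screen <- function(library, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("guide_id", "nominal_target", "is_control") %in%
                  names(library)))
  if (config$effect_log2fc == 0 &&
      config$n_planted_enriched + config$n_planted_depleted > 0L)
    warning("effect_log2fc = 0: planted hits are indistinguishable from null")
  withr::with_seed(.child_seed(config$seed, 2L), {
    genes <- unique(library$nominal_target[!library$is_control])
    n_hit <- config$n_planted_enriched + config$n_planted_depleted
    planted <- if (n_hit > 0L) sample(genes, n_hit) else character(0)
    enriched <- planted[seq_len(config$n_planted_enriched)]
    depleted <- setdiff(planted, enriched)

    functional <- character(0)
    for (g in planted) {
      gg <- library$guide_id[library$nominal_target == g]
      functional <- c(functional,
                      sample(gg, min(config$n_functional_guides_per_hit,
                                     length(gg))))
    }

    G <- nrow(library)
    base <- exp(rnorm(G, mean = 0, sd = 0.5))   # library composition skew
    names(base) <- library$guide_id
    mult <- rep(1, G)
    names(mult) <- library$guide_id
    eff <- 2^config$effect_log2fc
    mult[library$guide_id %in% functional &
           library$nominal_target %in% enriched] <- eff
    mult[library$guide_id %in% functional &
           library$nominal_target %in% depleted] <- 1 / eff

    samples <- c("P", "C1", "C2", "S1", "S2")
    roles <- c(P = "plasmid", C1 = "control", C2 = "control",
               S1 = "treated", S2 = "treated")
    size <- 1 / config$dispersion
    counts <- matrix(0L, G, length(samples),
                     dimnames = list(library$guide_id, samples))
    for (s in samples) {
      ab <- if (roles[[s]] == "treated") base * mult else base
      mu <- config$depth_per_sample * ab / sum(ab)
      counts[, s] <- rnbinom(G, mu = mu, size = size)
    }
    list(counts = counts, roles = roles,
         truth = list(enriched = enriched, depleted = depleted,
                      functional_guides = functional))
  })
}

#' Synthesize sequencing reads from a count column
#'
#' Produces the reads that [count_spacers()] expects: a short random
#' 5' stagger, the constant anchor, the spacer, and a constant scaffold
#' filler, truncated to `read_length`.  Intended for round-trip testing
#' of the counter; counts are usually consumed directly.
#'
#' @param counts named integer vector (one sample's guide counts).
#' @param library guide library data.frame.
#' @param anchor constant sequence immediately preceding the spacer.
#' @param read_length total read length.
#' @param seed integer seed for the stagger and read shuffling.
#' @return A [Biostrings::DNAStringSet] of reads in shuffled order.
#' @export
simulate_reads <- function(counts, library, anchor = "CGAAACACCG",
                           read_length = 60L, seed = 1L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  idx <- match(names(counts), library$guide_id)
  if (anyNA(idx)) stop("counts contain guide ids absent from the library")
  withr::with_seed(.child_seed(seed, 3L), {
    spacer <- rep(library$spacer[idx], times = counts)
    stagger <- vapply(sample.int(4L, length(spacer), replace = TRUE),
                      function(k) paste(sample(c("A", "C", "G", "T"), k,
                                               replace = TRUE),
                                        collapse = ""), character(1))
    scaffold <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTG"
    reads <- substr(paste0(stagger, anchor, spacer, scaffold),
                    1L, read_length)
    out <- Biostrings::DNAStringSet(sample(reads))
    names(out) <- sprintf("read%07d", seq_along(out))
    out
  })
}

#' Configuration for a synthetic activation cohort
#'
#' Parameters of the expression-cohort generator backing signature
#' construction and outcome association.  Half the samples are
#' "activated": their latent activation level is shifted by
#' `activation_effect` relative to controls (within-group spread 0.25).
#'
#' @param seed integer seed.
#' @param n_genes_expr genes in the expression matrix; must be at least
#'   600 so that 190 up- plus 190 down-regulated signature genes can be
#'   selected from the 250 planted per direction.
#' @param n_samples cohort size (activated/control split half and half).
#' @param activation_effect mean latent-activation difference between
#'   activated and control samples.
#' @param noise_sd residual expression noise (log-scale SD); must be > 0.
#' @param outcome_link strength tying response log-odds and survival
#'   log-hazard to the latent activation level.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed = 1L, n_genes_expr = 1000L,
                              n_samples = 100L, activation_effect = 1,
                              noise_sd = 1, outcome_link = 1) {
  cfg <- list(
    seed = .check_count(seed, "seed"),
    n_genes_expr = .check_count(n_genes_expr, "n_genes_expr", min = 2L),
    n_samples = .check_count(n_samples, "n_samples", min = 4L),
    activation_effect = .check_number(activation_effect, "activation_effect"),
    noise_sd = .check_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    outcome_link = .check_number(outcome_link, "outcome_link")
  )
  structure(cfg, class = "cohort_sim_config")
}

.N_TRUE_PER_DIR <- 250L  # planted signature-true genes per direction

#' Simulate an expression cohort with a planted activation program
#'
#' Generates a gene-by-sample log-expression matrix in which 250 genes
#' per direction shift linearly with a latent per-sample activation
#' level, a differential-expression table comparing activated vs control
#' samples (pooled two-sample t statistics, analogous to the test
#' statistic of a DE caller), and outcome tables: binary response with
#' log-odds `outcome_link * activation`, and exponential survival with
#' log-hazard `-outcome_link * activation` (higher activation, longer
#' survival), under uniform administrative censoring.
#'
#' @param config a [cohort_sim_config()].
#' @return List with `de_table` (gene, log2fc, stat, p), `expression`
#'   (matrix genes x samples), `truth` (list: `activation` per-sample
#'   latent level, `group` activated/control, `up_genes`, `down_genes`),
#'   and `outcomes` (data.frame: sample, response, time, event).
#' @export
simulate_activation_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (config$n_genes_expr < 2L * .N_TRUE_PER_DIR + 100L)
    stop(sprintf(
      "n_genes_expr = %d is too small to support selecting 190 genes per direction (need >= %d)",
      config$n_genes_expr, 2L * .N_TRUE_PER_DIR + 100L))
  withr::with_seed(.child_seed(config$seed, 4L), {
    n <- config$n_samples
    p <- config$n_genes_expr
    group <- rep(c("control", "activated"), length.out = n)
    a <- (group == "activated") * config$activation_effect + rnorm(n, 0, 0.25)
    genes <- sprintf("GENE%05d", seq_len(p))
    up <- genes[seq_len(.N_TRUE_PER_DIR)]
    down <- genes[.N_TRUE_PER_DIR + seq_len(.N_TRUE_PER_DIR)]
    beta <- numeric(p)
    names(beta) <- genes
    beta[up] <- runif(.N_TRUE_PER_DIR, 0.5, 1.5)
    beta[down] <- -runif(.N_TRUE_PER_DIR, 0.5, 1.5)
    mu <- rnorm(p, 5, 2)
    expr <- mu + outer(beta, a) +
      matrix(rnorm(p * n, 0, config$noise_sd), p, n)
    dimnames(expr) <- list(genes, sprintf("SAMPLE%03d", seq_len(n)))

    # pooled two-sample t per gene, activated vs control
    act <- group == "activated"
    n1 <- sum(act); n2 <- sum(!act)
    m1 <- rowMeans(expr[, act, drop = FALSE])
    m2 <- rowMeans(expr[, !act, drop = FALSE])
    v1 <- apply(expr[, act, drop = FALSE], 1, stats::var)
    v2 <- apply(expr[, !act, drop = FALSE], 1, stats::var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    de <- data.frame(gene = genes, log2fc = m1 - m2, stat = tstat,
                     p = 2 * pt(-abs(tstat), df), stringsAsFactors = FALSE)

    ac <- a - mean(a)
    response <- rbinom(n, 1L, stats::plogis(config$outcome_link * ac))
    ttrue <- rexp(n, rate = exp(-config$outcome_link * ac))
    cens <- runif(n, 0, 2 * stats::quantile(ttrue, 0.9))
    outcomes <- data.frame(
      sample = colnames(expr),
      response = ifelse(response == 1L, "responder", "non-responder"),
      time = pmin(ttrue, cens), event = as.integer(ttrue <= cens),
      stringsAsFactors = FALSE)

    list(de_table = de, expression = expr,
         truth = list(activation = setNames(a, colnames(expr)),
                      group = setNames(group, colnames(expr)),
                      up_genes = up, down_genes = down),
         outcomes = outcomes)
  })
}
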