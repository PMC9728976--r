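# a deterministic fold-change vector with known ranks: guide i of N has
# fold change N - i, so rank i under positive selection
.ranked_fc <- function(N) setNames(as.numeric(N - seq_len(N)),
                                   sprintf("u%02d", seq_len(N)))

.map_of <- function(gene_guides) {
  lib <- data.frame(
    guide_id = unlist(gene_guides, use.names = FALSE),
    nominal_target = rep(names(gene_guides), lengths(gene_guides)),
    is_control = FALSE, stringsAsFactors = FALSE)
  targets_from_library(lib)
}

test_that("a gene holding the top two ranks attains the minimal statistic and floor P", {
  fc <- .ranked_fc(40)
  tm <- .map_of(list(best = c("u01", "u02"), mid = c("u20", "u21")))
  tab <- riger_rank(fc, tm, "positive", n_perm = 2000, seed = 1)
  best <- tab[tab$gene == "best", ]
  expect_equal(best$statistic, 0.25 * (1 / 40) + 0.75 * (2 / 40))
  # +1-corrected empirical P: never zero, at the extreme scale set by
  # the chance of a null draw tying the minimal statistic (1/choose(40,2))
  expect_gte(best$p, 1 / 2001)
  expect_lt(best$p, 0.01)
  expect_gt(tab$p[tab$gene == "mid"], best$p)
})

test_that("riger permutation P matches exhaustive enumeration on small instances", {
  fc <- setNames(c(3.1, -0.5, 1.2, 0.7, -2.0, 0.1, 2.2, -1.4),
                 paste0("u", 1:8))
  genes <- list(gA = c("u1", "u3", "u7"), gB = c("u2", "u5"),
                gC = c("u4", "u6", "u8"))
  tm <- .map_of(genes)
  for (dir in c("positive", "negative")) {
    tab <- riger_rank(fc, tm, dir, exact = TRUE, seed = 1)
    for (g in names(genes)) {
      expect_equal(tab$p[tab$gene == g],
                   riger_brute_p(fc, genes[[g]], dir),
                   label = paste(g, dir))
    }
  }
  # sampled permutations converge on the enumerated value
  samp <- riger_rank(fc, tm, "positive", n_perm = 4000, seed = 2)
  exct <- riger_rank(fc, tm, "positive", exact = TRUE, seed = 2)
  expect_equal(samp$p[order(samp$gene)], exct$p[order(exct$gene)],
               tolerance = 0.12)
})

test_that("rank-based scores are invariant to monotone transforms of the fold changes", {
  set.seed(5)
  fc <- setNames(rnorm(60), sprintf("u%02d", 1:60))
  tm <- .map_of(list(g1 = sprintf("u%02d", 1:5),
                     g2 = sprintf("u%02d", 11:15),
                     g3 = sprintf("u%02d", 21:25)))
  t1 <- riger_rank(fc, tm, "positive", n_perm = 500, seed = 9)
  t2 <- riger_rank(tanh(fc) * 3 + 1, tm, "positive", n_perm = 500, seed = 9)
  expect_equal(t1, t2)
  ctrl <- sprintf("u%02d", 41:60)
  r1 <- rra_rank(fc, tm, ctrl, "positive", n_perm = 500, seed = 9)
  r2 <- rra_rank(exp(fc), tm, ctrl, "positive", n_perm = 500, seed = 9)
  expect_equal(r1, r2)
})

test_that("rra rho follows the Beta order-statistic closed form", {
  # raw (uncalibrated) percentiles so the closed form applies directly
  N <- 100
  fc <- .ranked_fc(N)
  # gene with one guide at percentile 10/N and three hopeless guides
  genes <- list(g = c("u10", "u90", "u95", "u99"),
                dud = c("u80", "u85"))
  tm <- .map_of(genes)
  ctrl <- sprintf("u%02d", 30:69)
  tab <- rra_rank(fc, tm, ctrl, "positive", alpha_rra = 0.25,
                  n_perm = 500, seed = 3, calibrate = FALSE)
  p1 <- 10 / N
  expect_equal(tab$statistic[tab$gene == "g"], pbeta(p1, 1, 4))
  expect_equal(pbeta(p1, 1, 4), 1 - (1 - p1)^4)    # the closed form
  # no guide under alpha: rho empty, P assigned 1
  expect_equal(tab$statistic[tab$gene == "dud"], 1)
  expect_equal(tab$p[tab$gene == "dud"], 1)
  expect_error(rra_rank(fc, tm, "absent", "positive"), "no control guides")
})

test_that("planted screens are recovered by both rankers in the right direction", {
  cfg <- sim_config(seed = 31, n_genes = 60, n_nontargeting = 30,
                    depth_per_sample = 4e5, n_planted_enriched = 3,
                    n_planted_depleted = 3)
  lib <- make_reference(cfg)$library
  scr <- simulate_screen(lib, cfg)
  fc <- log2fc(normalize_counts(scr$counts), "S1", "C2")
  tm <- targets_from_library(lib)
  ctrl <- lib$guide_id[lib$is_control]
  ri <- riger_rank(fc, tm, "positive", n_perm = 1000, seed = 2)
  rr <- rra_rank(fc, tm, ctrl, "positive", n_perm = 1000, seed = 2)
  expect_true(all(scr$truth$enriched %in% head(ri$gene, 5)))
  expect_true(all(scr$truth$enriched %in% head(rr$gene, 5)))
  expect_true(all(rr$p[rr$gene %in% scr$truth$enriched] < 0.05))
  rn <- rra_rank(fc, tm, ctrl, "negative", n_perm = 1000, seed = 2)
  expect_true(all(rn$p[rn$gene %in% scr$truth$depleted] < 0.05))
})

test_that("single-guide genes are excluded with a warning", {
  fc <- .ranked_fc(20)
  lib <- data.frame(guide_id = c("u01", "u02", "u05"),
                    nominal_target = c("ok", "ok", "solo"),
                    is_control = FALSE, stringsAsFactors = FALSE)
  tm <- targets_from_library(lib, min_guides = 1)
  expect_warning(tab <- riger_rank(fc, tm, "positive", n_perm = 200,
                                   seed = 1),
                 "fewer than 2")
  expect_false("solo" %in% tab$gene)
})

test_that("combine_replicates reproduces the piecewise weighted-average rule", {
  # independent arithmetic oracle over a grid spanning all alpha branches
  grid <- expand.grid(p1 = c(0.001, 0.01, 0.049, 0.05, 0.2, 1),
                      p2 = c(0.0005, 0.02, 0.05, 0.6, 1))
  got <- combine_replicates(grid$p1, grid$p2)
  for (i in seq_len(nrow(grid))) {
    p1 <- grid$p1[i]; p2 <- grid$p2[i]
    a <- if (p1 < 0.05 && p2 < 0.05) 2
         else if (p1 >= 0.05 && p2 >= 0.05) 0.5 else 1
    expect_equal(got$alpha[i], a)
    expect_equal(got$score[i], a * (-log10(p1) - log10(p2)) / 2)
  }
  # worked examples, boundary uses >=
  expect_equal(combine_replicates(0.05, 0.05)$score, 0.650515,
               tolerance = 1e-6)
  expect_equal(combine_replicates(0.01, 0.001)$alpha, 2)
  expect_equal(combine_replicates(0.01, 0.001)$score, 5)
  expect_equal(combine_replicates(1, 1)$score, 0)
  expect_error(combine_replicates(0, 0.5), "p1")
})

test_that("the combined score is monotone decreasing in each replicate P", {
  ps <- c(0.001, 0.01, 0.049, 0.05, 0.3, 1)
  for (p2 in ps) {
    s <- combine_replicates(ps, rep(p2, length(ps)))$score
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("call_hits demands strict P < threshold in all four cells", {
  mk <- function(p_list) {
    do.call(rbind, lapply(names(p_list), function(cmp) {
      data.frame(gene = names(p_list[[cmp]]), comparison = cmp,
                 direction = "positive", p = unname(p_list[[cmp]]),
                 stringsAsFactors = FALSE)
    }))
  }
  genes <- c(hit = 0.01, borderline = 0.049, miss = 0.2)
  riger <- mk(list(S1_vs_C2 = genes, S2_vs_C2 = genes))
  rra_p <- genes
  rra_p["borderline"] <- 0.051                    # one cell at 0.051
  rra <- mk(list(S1_vs_C2 = genes, S2_vs_C2 = rra_p))
  hits <- call_hits(riger, rra)
  expect_identical(hits$gene, "hit")
  expect_equal(hits$alpha, 2)
  expect_false("borderline" %in% hits$gene)
  # mismatched replicate sets error
  bad <- mk(list(S1_vs_C2 = genes))
  expect_error(call_hits(riger, bad), "comparison")
})

test_that("guide frequency t test matches the closed form and flags degeneracy", {
  norm <- matrix(c(10, 20, 30, 40, 50,
                   11, 22, 29, 41, 55,
                   9, 18, 33, 38, 52,
                   10, 21, 30, 39, 51) , 5, 4,
                 dimnames = list(paste0("g", 1:5), c("S1", "S2", "C1", "C2")))
  tm <- .map_of(list(tx = paste0("g", 1:5)))
  res <- guide_frequency_ttest(norm, "tx", tm, c("S1", "S2"), c("C1", "C2"))
  xo <- rowMeans(norm[, c("S1", "S2")])
  yo <- rowMeans(norm[, c("C1", "C2")])
  oracle <- paired_t_manual(xo, yo)
  expect_equal(res$statistic, oracle$statistic)
  expect_equal(res$p.value, oracle$p.value)
  expect_false(res$degenerate)

  dup <- norm[, c("S1", "S2", "S1", "S2")]
  colnames(dup) <- c("S1", "S2", "C1", "C2")
  same <- guide_frequency_ttest(dup, "tx", tm,
                                c("S1", "S2"), c("C1", "C2"))
  expect_true(same$degenerate)
  expect_equal(same$p.value, 1)
  expect_equal(same$statistic, 0)
})
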