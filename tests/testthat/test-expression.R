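fake_de <- function(genes, fc) {
  data.frame(gene_id = genes, mean_pos = NA_real_, mean_neg = NA_real_,
             fold_change = fc, log2_fc = log2(fc), p_value = NA_real_,
             direction = "none", stringsAsFactors = FALSE)
}

test_that("differential expression handles degenerate genes by contract", {
  vals <- rbind(flat = rep(3, 8),        # identical in both groups
                silent = rep(0, 8),      # zero everywhere
                shift = c(rep(1, 4), rep(10, 4)))
  colnames(vals) <- sprintf("s%d", 1:8)
  em <- expression_matrix(vals)
  de <- differential_expression(em, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(de$fold_change[de$gene_id == "flat"], 1)
  expect_equal(de$direction[de$gene_id == "flat"], "none")
  expect_equal(de$p_value[de$gene_id == "flat"], 1)
  # pseudocount keeps silent genes finite and inert
  expect_equal(de$fold_change[de$gene_id == "silent"], 1)
  expect_equal(de$p_value[de$gene_id == "silent"], 1)
  expect_equal(de$direction[de$gene_id == "shift"], "down")
  expect_lt(de$fold_change[de$gene_id == "shift"], 1 / 1.19)

  expect_error(differential_expression(em, c("s1", "s2"), c("s2", "s3")),
               "overlap")
})

test_that("direction needs both the fold border and significance", {
  set.seed(31)
  # strong shift but tiny fold change: significant p, no direction
  x <- 100 + rnorm(10, sd = 0.1)
  y <- 101 + rnorm(10, sd = 0.1)
  vals <- matrix(c(x, y), 1, dimnames = list("g", sprintf("s%d", 1:20)))
  de <- differential_expression(expression_matrix(vals),
                                sprintf("s%d", 11:20), sprintf("s%d", 1:10))
  expect_lt(de$p_value, 0.05)
  expect_equal(de$direction, "none")
})

test_that("paralogue concordance applies the 1.19 border to both axes", {
  genes <- sprintf("g%d", 1:6)
  de_a <- fake_de(genes, c(1.5, 1.3, 1.0, 0.9, 0.7, 1.25))
  de_b <- fake_de(genes, c(1.4, 1.1, 1.0, 0.8, 0.6, 1.30))
  pc <- paralogue_concordance(de_a, de_b)
  expect_setequal(pc$common_up, c("g1", "g6"))
  expect_setequal(pc$common_down, "g5")

  # identity and sign-flip extremes
  self <- paralogue_concordance(de_a, de_a)
  expect_equal(self$pearson_r, 1)
  expect_setequal(self$common_up, c("g1", "g2", "g6"))
  flip <- de_a
  flip$log2_fc <- -de_a$log2_fc
  flip$fold_change <- 1 / de_a$fold_change
  pcf <- paralogue_concordance(de_a, flip)
  expect_equal(pcf$pearson_r, -1)
  expect_length(pcf$common_up, 0)
  expect_length(pcf$common_down, 0)

  expect_error(paralogue_concordance(de_a, fake_de("gX", 1)), "universes")
})

test_that("cross-cancer commonality follows the consistency policy", {
  genes <- c("up_all", "up_two_down_one", "down_all", "quiet")
  mk <- function(dirs) {
    de <- fake_de(genes, 1)
    de$direction <- dirs
    de
  }
  des <- list(
    A = mk(c("up", "up",   "down", "none")),
    B = mk(c("up", "up",   "down", "none")),
    C = mk(c("up", "down", "down", "none")),
    D = mk(c("up", "none", "down", "none")))
  cc <- cross_cancer_common_genes(des, min_types = 2)
  expect_setequal(cc$up, "up_all")       # opposite call excludes g2
  expect_setequal(cc$down, "down_all")
  expect_setequal(cross_cancer_common_genes(des, min_types = 4)$up, "up_all")

  # monotone non-increasing in min_types
  cohortwide <- lapply(1:4, function(i) {
    de <- fake_de(sprintf("g%d", 1:30), 1)
    set.seed(i)
    de$direction <- sample(c("up", "down", "none"), 30, replace = TRUE)
    de
  })
  sizes <- vapply(1:4, function(k)
    length(cross_cancer_common_genes(cohortwide, min_types = k)$up),
    integer(1))
  expect_true(all(diff(sizes) <= 0))

  expect_error(cross_cancer_common_genes(des[1]), "at least 2")
})

test_that("CTA score matches the hand-computed toy and its invariants", {
  # g1 log2(TPM+1) = 1,2,3 across samples; g2 constant (zero variance)
  vals <- rbind(g1 = 2^c(1, 2, 3) - 1, g2 = c(5, 5, 5))
  colnames(vals) <- sprintf("s%d", 1:3)
  em <- expression_matrix(vals)
  samples <- sample_table(sprintf("s%d", 1:3), "CT01", "tumor")
  sc <- cta_score(em, samples, c("g1", "g2"), k = 2)
  expect_equal(sc$score[match(sprintf("s%d", 1:3), sc$sample_id)],
               c(-1, 0, 1))  # sample SD (ddof = 1) of (1,2,3) is 1
  expect_equal(attr(sc, "selected_genes")$CT01, "g1")  # g2 excluded

  # all genes constant -> error
  flat <- expression_matrix(matrix(5, 2, 3,
                                   dimnames = list(c("g1", "g2"),
                                                   sprintf("s%d", 1:3))))
  expect_error(cta_score(flat, samples, c("g1", "g2")), "positive variance")

  # per-gene multiplicative TPM rescale is a log-shift: scores identical
  vals2 <- vals
  vals2["g1", ] <- (vals["g1", ] + 1) * 4 - 1
  sc2 <- cta_score(expression_matrix(vals2), samples, c("g1", "g2"), k = 2)
  expect_equal(sc2$score, sc$score)

  # scores sum to zero within each cancer type, exactly
  cohort <- simulate_cohort(cohort_config(seed = 8, samples_per_type = 25))
  scc <- cta_score(cohort$expr, cohort$samples,
                   cohort$ground_truth$cta_genes)
  sums <- c(tapply(scc$score, scc$cancer_type, sum))
  expect_equal(unname(sums), rep(0, length(sums)), tolerance = 1e-10)
})

test_that("compare_scores is one-sided per cancer type", {
  scores <- data.frame(sample_id = sprintf("s%d", 1:8),
                       cancer_type = "CT01",
                       score = c(5, 6, 7, 8, 1, 2, 3, 4))
  out <- compare_scores(scores, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(out$p_value, 1 / choose(8, 4))
  # identical score multisets in both groups -> p of 1 territory
  tied <- data.frame(sample_id = sprintf("s%d", 1:6), cancer_type = "CT01",
                     score = rep(c(1, 2, 3), 2))
  out2 <- compare_scores(tied, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_gt(out2$p_value, 0.5)
  expect_error(compare_scores(scores, "s1", "s1"), "overlap")
})

test_that("marker panel comparison is a restricted DE run", {
  set.seed(33)
  vals <- matrix(rlnorm(5 * 12, log(10), 0.2), 5,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:12)))
  em <- expression_matrix(vals)
  gp <- sprintf("s%d", 1:6); gn <- sprintf("s%d", 7:12)
  expect_equal(nrow(marker_panel_comparison(em, character(), gp, gn)), 0L)
  one <- marker_panel_comparison(em, "g2", gp, gn)
  expect_equal(one$gene_id, "g2")
  full <- differential_expression(em, gp, gn, genes = "g2")
  expect_equal(one$p_value, full$p_value)

  # panel read from annotation category flags
  cats <- list("coding", c("coding", "marker_panel:histones"),
               c("coding", "marker_panel:histones"), "coding", "coding")
  ann <- gene_annotation(rownames(vals), chromosome = "chr1",
                         start = 1:5 * 100L, end = 1:5 * 100L + 50L,
                         categories = cats)
  two <- marker_panel_comparison(em, ann, gp, gn, panel_name = "histones")
  expect_setequal(two$gene_id, c("g2", "g3"))
})

test_that("X:autosome ratio is a per-sample TPM quotient", {
  vals <- rbind(x1 = c(2, 4), x2 = c(3, 6), a1 = c(4, 4), a2 = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  ann <- gene_annotation(rownames(vals),
                         chromosome = c("chrX", "chrX", "chr2", "chr7"),
                         start = rep(1L, 4), end = rep(10L, 4),
                         categories = rep(list("coding"), 4))
  em <- expression_matrix(vals)
  out <- x_autosome_ratio(em, ann, "s1", "s2")
  expect_equal(unname(out$ratios["s1"]), 1)          # 5 / 5
  expect_equal(unname(out$ratios["s2"]), 2)          # doubling chrX doubles it
  all_x <- gene_annotation(rownames(vals), chromosome = "chrX",
                           start = rep(1L, 4), end = rep(10L, 4),
                           categories = rep(list("coding"), 4))
  expect_error(x_autosome_ratio(em, all_x, "s1", "s2"), "both chrX")
})

test_that("locus neighborhood verdicts and window errors", {
  set.seed(34)
  base <- matrix(rlnorm(3 * 16, log(10), 0.05), 3)
  dimnames(base) <- list(c("focal", "near", "far"), sprintf("s%d", 1:16))
  gp <- sprintf("s%d", 1:8); gn <- sprintf("s%d", 9:16)
  ann <- gene_annotation(c("focal", "near", "far"), chromosome = "chrX",
                         start = c(1000L, 3000L, 900000L),
                         end = c(1999L, 3999L, 901000L),
                         categories = rep(list("coding"), 3))
  up <- base; up["focal", gp] <- up["focal", gp] * 10
  res <- locus_neighborhood(expression_matrix(up), ann, "focal", 5000,
                            gp, gn)
  expect_equal(res$neighbors, "near")
  expect_equal(res$verdict, "locus_restricted")

  up2 <- up; up2["near", gp] <- up2["near", gp] * 10
  res2 <- locus_neighborhood(expression_matrix(up2), ann, "focal", 5000,
                             gp, gn)
  expect_equal(res2$verdict, "regional")

  expect_error(locus_neighborhood(expression_matrix(up), ann, "focal", 10,
                                  gp, gn), "enlarge the window")
})
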