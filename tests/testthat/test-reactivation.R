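make_status_fixture <- function() {
  # 4 samples x 2 paralogues with all three status levels represented
  vals <- rbind(H2AFB1 = c(2.0, 0.3, 1.0, 1.5),
                H2AFB2 = c(0.1, 4.0, 0.2, 0.0),
                g1 = c(5, 5, 5, 5))
  colnames(vals) <- sprintf("s%d", 1:4)
  expr <- expression_matrix(vals)
  ann <- gene_annotation(rownames(vals), chromosome = c("chrX", "chrX", "chr1"),
                         start = c(1L, 1000L, 1L), end = c(500L, 1500L, 500L),
                         categories = list(c("coding", "sH2A_paralogue"),
                                           c("coding", "sH2A_paralogue"),
                                           "coding"),
                         paralogue = c("H2AFB1", "H2AFB2", NA))
  list(expr = expr, ann = ann)
}

test_that("status thresholds are strict on both boundaries", {
  fx <- make_status_fixture()
  st <- classify_sh2a_status(fx$expr, fx$ann)
  b1 <- st[st$paralogue == "H2AFB1", ]
  expect_equal(b1$status[match(sprintf("s%d", 1:4), b1$sample_id)],
               c("positive",       # 2.0 > 1.5
                 "negative",       # 0.3 < 0.5
                 "intermediate",   # 1.0 in [0.5, 1.5]
                 "intermediate"))  # exactly 1.5: strict inequality
  # partition is exhaustive and disjoint
  expect_equal(nrow(st), 4 * 2)
  expect_true(all(st$status %in% c("positive", "negative", "intermediate")))

  # all-zero expression is all-negative
  z <- toy_expr(rep(0, 4), genes = c("H2AFB1", "g1"))
  zt <- classify_sh2a_status(z, toy_annotation(c("H2AFB1", "g1"), "H2AFB1"))
  expect_true(all(zt$status == "negative"))

  # no sH2A gene present -> error
  expect_error(classify_sh2a_status(toy_expr(1:4),
                                    toy_annotation(c("g1", "g2"))),
               "no sH2A")
})

test_that("positive set is invariant to tau_neg (property)", {
  cohort <- simulate_cohort(cohort_config(seed = 5, samples_per_type = 30))
  a <- classify_sh2a_status(cohort$expr, cohort$annotation, tau_neg = 0.5)
  b <- classify_sh2a_status(cohort$expr, cohort$annotation, tau_neg = 0.01)
  expect_identical(a$status == "positive", b$status == "positive")
})

test_that("any-positive rule ignores intermediates", {
  fx <- make_status_fixture()
  st <- classify_sh2a_status(fx$expr, fx$ann)
  pos <- any_paralogue_positive(st)
  expect_identical(unname(pos[sprintf("s%d", 1:4)]),
                   c(TRUE, TRUE, FALSE, FALSE))  # s4: intermediate only
  expect_error(any_paralogue_positive(st, c("H2AFB1", "H2AFB3")),
               "H2AFB3")
})

test_that("reactivation frequency uses the all-tumors denominator", {
  st <- data.frame(sample_id = rep(sprintf("s%d", 1:10), 1),
                   paralogue = "H2AFB1", gene_id = "H2AFB1",
                   tpm = c(rep(2, 5), rep(0, 5)),
                   status = c(rep("positive", 5), rep("negative", 5)))
  samples <- sample_table(sprintf("s%d", 1:10), "DLBC", "tumor")
  fr <- reactivation_frequency(st, samples, min_group = 3)
  expect_equal(fr$frequency, 0.5)
  expect_equal(fr$pct, 50)
  expect_true(fr$reportable)

  st$status <- "negative"
  fr0 <- reactivation_frequency(st, samples, min_group = 3)
  expect_equal(fr0$frequency, 0)
  expect_false(fr0$reportable)

  # intermediates stay in the denominator
  st$status <- c(rep("positive", 5), rep("intermediate", 5))
  expect_equal(reactivation_frequency(st, samples)$frequency, 0.5)
})

test_that("co-expression matrix is restricted to any-positive samples", {
  st <- expand.grid(sample_id = c("s1", "s2"),
                    paralogue = c("H2AFB1", "H2AFB2", "H2AFB3"),
                    stringsAsFactors = FALSE)
  st$gene_id <- st$paralogue
  st$tpm <- 0
  st$status <- "negative"
  st$status[st$sample_id == "s1" &
            st$paralogue %in% c("H2AFB2", "H2AFB3")] <- "positive"
  cm <- coexpression_matrix(st, c("H2AFB1", "H2AFB2", "H2AFB3"))
  expect_equal(rownames(cm), "s1")
  expect_equal(unname(cm["s1", ]), c(0L, 1L, 1L))

  st$status <- "negative"
  expect_equal(nrow(coexpression_matrix(st)), 0L)

  st$status[st$sample_id == "s2"] <- "positive"
  cm3 <- coexpression_matrix(st)
  expect_equal(unname(cm3["s2", ]), c(1L, 1L, 1L))
})

test_that("expression percentile ranks the gene among expressed genes", {
  # 5 genes with medians 1..5 across 3 samples; query g3 sits at 50%
  vals <- matrix(rep(1:5, 3), 5, dimnames = list(sprintf("g%d", 1:5),
                                                 sprintf("s%d", 1:3)))
  em <- expression_matrix(vals)
  expect_equal(expression_percentile(em, "g3")$percentile, 50)
  expect_equal(expression_percentile(em, "g5")$percentile, 100)
  expect_equal(expression_percentile(em, "g1")$percentile, 0)

  # a silent gene ranks below every expressed gene
  vals2 <- rbind(vals, g0 = c(0, 0, 0))
  expect_equal(expression_percentile(expression_matrix(vals2),
                                     "g0")$percentile, 0)
  expect_error(expression_percentile(em, "nope"), "not in matrix")
})
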