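# Group differential expression and the summaries built on it:
# paralogue concordance, cross-cancer common gene sets, the composite
# CTA score, marker-panel comparisons, X:autosome dosage ratio, and
# locus-neighborhood checks.

.check_groups <- function(expr, group_pos, group_neg) {
  if (length(intersect(group_pos, group_neg)))
    stop("groups overlap: ", intersect(group_pos, group_neg)[1L])
  miss <- setdiff(c(group_pos, group_neg), sample_ids(expr))
  if (length(miss)) stop("sample(s) not in matrix: ", miss[1L])
  if (length(group_pos) == 0L || length(group_neg) == 0L)
    stop("both groups must be non-empty")
}

#' Differential expression between two sample groups
#'
#' Per gene, fold change is computed on group mean TPMs with a
#' pseudocount (`(mean_pos + eps) / (mean_neg + eps)`) and the p-value
#' from [mann_whitney_u()]. Direction is the composite rule: `up` iff
#' `fold_change > fc_border` and `p < alpha`; `down` iff
#' `fold_change < 1/fc_border` and `p < alpha`; otherwise `none`.
#' Intermediate-status samples should be excluded before calling.
#'
#' @param expr an `ExpressionMatrix`.
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param alternative passed to [mann_whitney_u()] (default two-sided).
#' @param fc_border fold-change border (default 1.19).
#' @param alpha significance level (default 0.05).
#' @param pseudocount TPM added to both group means (default 0.1).
#' @param genes optional subset of gene ids to test.
#' @param adjust `"none"` (default; raw Mann-Whitney p-values) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values used in the
#'   direction rule.
#' @return `data.frame` with `gene_id`, `mean_pos`, `mean_neg`,
#'   `fold_change`, `log2_fc`, `p_value`, `direction`.
#' @export
differential_expression <- function(expr, group_pos, group_neg,
                                    alternative = "two_sided",
                                    fc_border = 1.19, alpha = 0.05,
                                    pseudocount = 0.1,
                                    genes = gene_ids(expr),
                                    adjust = c("none", "BH")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  adjust <- match.arg(adjust)
  .check_groups(expr, group_pos, group_neg)
  vp <- expr$values[genes, group_pos, drop = FALSE]
  vn <- expr$values[genes, group_neg, drop = FALSE]
  mp <- rowMeans(vp)
  mn <- rowMeans(vn)
  p <- vapply(seq_along(genes), function(i) {
    mann_whitney_u(vp[i, ], vn[i, ], alternative = alternative)$p
  }, numeric(1))
  fc <- (mp + pseudocount) / (mn + pseudocount)
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  direction <- ifelse(p_eff < alpha & fc > fc_border, "up",
                      ifelse(p_eff < alpha & fc < 1 / fc_border, "down",
                             "none"))
  data.frame(gene_id = genes, mean_pos = unname(mp), mean_neg = unname(mn),
             fold_change = unname(fc), log2_fc = unname(log2(fc)),
             p_value = unname(p_eff), direction = direction,
             stringsAsFactors = FALSE)
}

#' Concordance of two differential-expression comparisons
#'
#' Pearson correlation of paired log2 fold-changes across the shared
#' gene universe, plus the genes commonly up- (fold change above the
#' border in both) or downregulated (below its reciprocal in both).
#'
#' @param de_a,de_b results of [differential_expression()] over the
#'   same gene universe.
#' @param fc_border fold-change border (default 1.19).
#' @return List with `pearson_r`, `common_up`, `common_down`, `n_genes`.
#' @export
paralogue_concordance <- function(de_a, de_b, fc_border = 1.19) {
  if (!setequal(de_a$gene_id, de_b$gene_id))
    stop("comparisons cover different gene universes")
  b <- de_b[match(de_a$gene_id, de_b$gene_id), ]
  r <- cor(de_a$log2_fc, b$log2_fc, method = "pearson")
  list(pearson_r = r,
       common_up = de_a$gene_id[de_a$fold_change > fc_border &
                                b$fold_change > fc_border],
       common_down = de_a$gene_id[de_a$fold_change < 1 / fc_border &
                                  b$fold_change < 1 / fc_border],
       n_genes = nrow(de_a))
}

#' Genes consistently regulated across cancer types
#'
#' Default consistency policy: a gene is commonly up iff it is called
#' `up` in at least `min_types` cancer types and `down` in none
#' (symmetric for down). The output shrinks (never grows) as
#' `min_types` increases.
#'
#' @param de_by_cancer named list of [differential_expression()]
#'   results, one per cancer type.
#' @param min_types minimum number of types with a concordant call;
#'   default: half the analyzed types, rounded up.
#' @param allow_opposite number of opposite-direction calls tolerated
#'   (default 0).
#' @return List with gene-id sets `up` and `down`, plus the per-gene
#'   count tables `n_up` and `n_down`.
#' @export
cross_cancer_common_genes <- function(de_by_cancer,
                                      min_types = ceiling(length(de_by_cancer) / 2),
                                      allow_opposite = 0) {
  if (length(de_by_cancer) < 2L) stop("need at least 2 cancer types")
  genes <- de_by_cancer[[1L]]$gene_id
  for (de in de_by_cancer)
    if (!setequal(de$gene_id, genes)) stop("gene universes differ across types")
  n_up <- n_down <- setNames(integer(length(genes)), genes)
  for (de in de_by_cancer) {
    idx <- match(genes, de$gene_id)
    n_up <- n_up + (de$direction[idx] == "up")
    n_down <- n_down + (de$direction[idx] == "down")
  }
  list(up = genes[n_up >= min_types & n_down <= allow_opposite],
       down = genes[n_down >= min_types & n_up <= allow_opposite],
       n_up = n_up, n_down = n_down)
}

#' Composite cancer-testis antigen (CTA) score per sample
#'
#' Within each cancer type (tumor samples only): log-transform CTA
#' TPMs as `log2(TPM + pseudocount)`, rank CTA genes by the sample
#' variance of log expression across that type's samples, keep the top
#' `k` with positive variance, Z-normalize each kept gene (subtract
#' mean, divide by sample SD), and score each sample by the sum of its
#' Z-scores. By construction scores average exactly 0 within a type.
#'
#' @param expr an `ExpressionMatrix`.
#' @param samples a `SampleTable` covering the matrix samples.
#' @param cta_genes gene ids flagged as CTAs.
#' @param k number of most-variable CTAs to keep (default 40).
#' @param pseudocount TPM added before the log (default 1).
#' @return `data.frame` with `sample_id`, `cancer_type`, `score`, and
#'   attribute `selected_genes` (named list per cancer type).
#' @export
cta_score <- function(expr, samples, cta_genes, k = 40, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(samples, "SampleTable"))
  cta_genes <- intersect(cta_genes, gene_ids(expr))
  if (length(cta_genes) == 0L) stop("no CTA gene present in the matrix")
  tum <- samples[samples$tissue_class == "tumor" &
                 samples$sample_id %in% sample_ids(expr), ]
  sel <- list()
  res <- do.call(rbind, lapply(split(tum$sample_id, tum$cancer_type),
                               function(sids) {
    if (length(sids) < 2L) stop("need >= 2 tumor samples per cancer type")
    lx <- log2(expr$values[cta_genes, sids, drop = FALSE] + pseudocount)
    v <- apply(lx, 1L, var)
    keep <- names(sort(v[v > 0], decreasing = TRUE))
    if (length(keep) == 0L)
      stop("no CTA gene with positive variance in type")
    keep <- keep[seq_len(min(k, length(keep)))]
    z <- t(scale(t(lx[keep, , drop = FALSE])))
    ct <- tum$cancer_type[match(sids[1L], tum$sample_id)]
    sel[[ct]] <<- keep
    data.frame(sample_id = sids, cancer_type = ct,
               score = unname(colSums(z)), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "selected_genes") <- sel
  res
}

#' Compare CTA scores between groups, per cancer type
#'
#' One-sided Mann-Whitney test of the positive group's scores being
#' greater (by default).
#'
#' @param scores output of [cta_score()].
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param alternative test direction (default `"x_greater"` with x =
#'   positive group).
#' @return `data.frame` with `cancer_type`, `n_pos`, `n_neg`, `p_value`.
#' @export
compare_scores <- function(scores, group_pos, group_neg,
                           alternative = "x_greater") {
  if (length(intersect(group_pos, group_neg))) stop("groups overlap")
  out <- do.call(rbind, lapply(split(scores, scores$cancer_type), function(d) {
    sp <- d$score[d$sample_id %in% group_pos]
    sn <- d$score[d$sample_id %in% group_neg]
    if (length(sp) == 0L || length(sn) == 0L) return(NULL)
    data.frame(cancer_type = d$cancer_type[1L], n_pos = length(sp),
               n_neg = length(sn),
               p_value = mann_whitney_u(sp, sn, alternative = alternative)$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Differential expression restricted to a named marker panel
#'
#' Same machinery as [differential_expression()], limited to panel
#' genes (e.g. replication-independent histone variants H2AFZ, H3F3A,
#' H2AFX and the chaperone NAP1L1, or immune cell-type markers).
#'
#' @param expr an `ExpressionMatrix`.
#' @param panel gene ids, or a `GeneAnnotation` plus `panel_name` to
#'   read membership from `marker_panel:<name>` category flags.
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param alternative,fc_border,alpha,pseudocount as in
#'   [differential_expression()].
#' @param panel_name when `panel` is a `GeneAnnotation`, the panel name.
#' @return `data.frame` as from [differential_expression()]; zero rows
#'   for an empty panel.
#' @export
marker_panel_comparison <- function(expr, panel, group_pos, group_neg,
                                    alternative = "two_sided",
                                    fc_border = 1.19, alpha = 0.05,
                                    pseudocount = 0.1, panel_name = NULL) {
  if (inherits(panel, "GeneAnnotation")) {
    if (is.null(panel_name)) stop("panel_name required with an annotation")
    panel <- genes_with_category(panel, paste0("marker_panel:", panel_name))
  }
  panel <- intersect(panel, gene_ids(expr))
  if (length(panel) == 0L)
    return(data.frame(gene_id = character(), mean_pos = numeric(),
                      mean_neg = numeric(), fold_change = numeric(),
                      log2_fc = numeric(), p_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  differential_expression(expr, group_pos, group_neg,
                          alternative = alternative, fc_border = fc_border,
                          alpha = alpha, pseudocount = pseudocount,
                          genes = panel)
}

#' X-chromosome to autosome expression ratio per sample
#'
#' Per sample, the ratio of summed TPM over chrX genes to summed TPM
#' over autosomal genes; groups compared by a two-sided Mann-Whitney
#' test. A flat ratio between reactivated and silent samples argues
#' against X-ploidy gain or broad X derepression as the cause of
#' short-H2A expression.
#'
#' @param expr an `ExpressionMatrix`.
#' @param annotation `GeneAnnotation` giving chromosomes.
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param x_label chromosome label for X (default `"chrX"`).
#' @return List with `ratios` (named per-sample vector over both
#'   groups), and `p_value`.
#' @export
x_autosome_ratio <- function(expr, annotation, group_pos, group_neg,
                             x_label = "chrX") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  .check_groups(expr, group_pos, group_neg)
  ann <- annotation[match(gene_ids(expr), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) stop("annotation missing genes from the matrix")
  on_x <- ann$chromosome == x_label
  if (!any(on_x) || all(on_x)) stop("need genes on both chrX and autosomes")
  sids <- c(group_pos, group_neg)
  xs <- colSums(expr$values[on_x, sids, drop = FALSE])
  as_ <- colSums(expr$values[!on_x, sids, drop = FALSE])
  if (any(as_ == 0)) stop("sample with zero autosomal expression")
  ratios <- xs / as_
  list(ratios = ratios,
       p_value = mann_whitney_u(ratios[group_pos], ratios[group_neg],
                                alternative = "two_sided")$p)
}

#' Is upregulation restricted to a focal locus?
#'
#' Tests the focal gene and every annotated neighbor (same chromosome,
#' gene span within `window_bp` of the focal span) for differential
#' expression and returns the verdict: `locus_restricted` iff the focal
#' gene is up and no neighbor is, `regional` otherwise.
#'
#' @param expr an `ExpressionMatrix`.
#' @param annotation a `GeneAnnotation`.
#' @param focal_gene gene id of the locus of interest.
#' @param window_bp neighborhood half-width in base pairs.
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param ... passed to [differential_expression()].
#' @return List with `de` (focal + neighbors), `neighbors`, `verdict`.
#' @export
locus_neighborhood <- function(expr, annotation, focal_gene, window_bp,
                               group_pos, group_neg, ...) {
  idx <- match(focal_gene, annotation$gene_id)
  if (is.na(idx)) stop("focal gene not annotated")
  foc <- annotation[idx, ]
  same_chr <- annotation$chromosome == foc$chromosome &
    annotation$gene_id != focal_gene
  gap <- pmax(annotation$start - foc$end, foc$start - annotation$end, 0L)
  neighbors <- annotation$gene_id[same_chr & gap <= window_bp]
  neighbors <- intersect(neighbors, gene_ids(expr))
  if (length(neighbors) == 0L)
    stop("no annotated neighbor within ", window_bp,
         " bp; enlarge the window")
  de <- differential_expression(expr, group_pos, group_neg,
                                genes = c(focal_gene, neighbors), ...)
  focal_up <- de$direction[de$gene_id == focal_gene] == "up"
  any_nb_up <- any(de$direction[de$gene_id %in% neighbors] == "up")
  list(de = de, neighbors = neighbors,
       verdict = if (focal_up && !any_nb_up) "locus_restricted" else "regional")
}
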