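# Per-sample classification of short-H2A expression status and the
# frequency / co-expression / percentile summaries built on it.
#
# Thresholds follow standard practice for calling a testis-restricted
# gene "reactivated" in a tumor: strictly above tau_pos TPM = positive,
# strictly below tau_neg TPM = negative, the band in between =
# intermediate (excluded from differential analyses downstream but kept
# in frequency denominators).

#' Classify short-H2A expression status per sample and paralogue
#'
#' @param expr an `ExpressionMatrix` (TPM).
#' @param annotation a `GeneAnnotation` flagging at least one
#'   `sH2A_paralogue` gene present in the matrix.
#' @param tau_pos positive threshold in TPM (status `positive` iff
#'   TPM > tau_pos; default 1.5).
#' @param tau_neg negative threshold in TPM (status `negative` iff
#'   TPM < tau_neg; default 0.5). TPM in `[tau_neg, tau_pos]` is
#'   `intermediate`; both inequalities are strict, so TPM exactly 1.5
#'   is intermediate.
#' @return A `data.frame` with one row per (sample, paralogue):
#'   `sample_id`, `paralogue`, `gene_id`, `tpm`, `status`.
#' @export
classify_sh2a_status <- function(expr, annotation, tau_pos = 1.5,
                                 tau_neg = 0.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"), tau_neg <= tau_pos)
  sh2a <- annotation[vapply(annotation$categories,
                            function(cc) "sH2A_paralogue" %in% cc, logical(1)), ]
  sh2a <- sh2a[sh2a$gene_id %in% gene_ids(expr), ]
  if (nrow(sh2a) == 0L)
    stop("no sH2A paralogue gene present in the expression matrix")
  out <- do.call(rbind, lapply(seq_len(nrow(sh2a)), function(i) {
    tpm <- expr$values[sh2a$gene_id[i], ]
    data.frame(sample_id = sample_ids(expr),
               paralogue = sh2a$paralogue[i],
               gene_id = sh2a$gene_id[i],
               tpm = unname(tpm),
               status = ifelse(tpm > tau_pos, "positive",
                               ifelse(tpm < tau_neg, "negative",
                                      "intermediate")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample flag: is any paralogue positive?
#'
#' Intermediate status never counts as positive.
#'
#' @param statuses output of [classify_sh2a_status()].
#' @param paralogue_set paralogues to consider (default: all present).
#' @return Named logical vector over samples.
#' @export
any_paralogue_positive <- function(statuses,
                                   paralogue_set = unique(statuses$paralogue)) {
  miss <- setdiff(paralogue_set, statuses$paralogue)
  if (length(miss)) stop("statuses do not cover paralogue(s): ",
                         paste(miss, collapse = ", "))
  st <- statuses[statuses$paralogue %in% paralogue_set, ]
  pos <- c(tapply(st$status == "positive", st$sample_id, any))
  pos[unique(statuses$sample_id)]
}

#' Reactivation frequency per cancer type
#'
#' Frequency = (tumors with any paralogue positive) / (all tumors of
#' the type, including intermediates). Types whose positive count falls
#' below `min_group` are flagged, not dropped.
#'
#' @param statuses output of [classify_sh2a_status()].
#' @param samples a `SampleTable`; only `tissue_class == "tumor"`
#'   samples enter the table.
#' @param min_group reporting filter: minimum positive tumors for an
#'   unflagged row (default 10).
#' @param paralogue_set paralogues considered for "any positive".
#' @return `data.frame` with `cancer_type`, `n_tumors`, `n_positive`,
#'   `frequency` (in \[0, 1\]), `pct` and `reportable`.
#' @export
reactivation_frequency <- function(statuses, samples, min_group = 10,
                                   paralogue_set = unique(statuses$paralogue)) {
  stopifnot(inherits(samples, "SampleTable"))
  if (!all(unique(statuses$sample_id) %in% samples$sample_id))
    stop("statuses contain samples absent from the sample table")
  pos <- any_paralogue_positive(statuses, paralogue_set)
  tum <- samples[samples$tissue_class == "tumor", ]
  tum$positive <- pos[tum$sample_id]
  agg <- do.call(rbind, lapply(split(tum, tum$cancer_type), function(d) {
    data.frame(cancer_type = d$cancer_type[1L], n_tumors = nrow(d),
               n_positive = sum(d$positive, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  agg$frequency <- agg$n_positive / agg$n_tumors
  agg$pct <- 100 * agg$frequency
  agg$reportable <- agg$n_positive >= min_group
  rownames(agg) <- NULL
  agg[order(-agg$frequency), ]
}

#' Binary co-expression matrix over any-positive samples
#'
#' Rows are samples positive for at least one paralogue in the set;
#' entries are 1 iff that sample is positive for that paralogue.
#'
#' @param statuses output of [classify_sh2a_status()].
#' @param paralogue_set paralogues forming the columns.
#' @return Integer 0/1 matrix, samples x paralogues (possibly 0 rows).
#' @export
coexpression_matrix <- function(statuses,
                                paralogue_set = unique(statuses$paralogue)) {
  st <- statuses[statuses$paralogue %in% paralogue_set, ]
  wide <- matrix(0L, nrow = length(unique(st$sample_id)),
                 ncol = length(paralogue_set),
                 dimnames = list(unique(st$sample_id), paralogue_set))
  wide[cbind(st$sample_id, st$paralogue)] <- as.integer(st$status == "positive")
  wide[rowSums(wide) > 0L, , drop = FALSE]
}

#' Percentile of a gene's expression among expressed genes
#'
#' Summarizes each gene by its median TPM across the chosen samples,
#' applies `expressed_rule` to define the expressed-gene universe, and
#' returns the percentile rank (0--100) of the query gene within it
#' (mid-ranks for ties; 0 = below every expressed gene, 100 = above).
#'
#' @param expr an `ExpressionMatrix`.
#' @param gene_id the query gene.
#' @param sample_set sample ids to summarize over (default: all).
#' @param expressed_rule function mapping the vector of per-gene
#'   summaries to a logical "expressed" mask; default: median TPM > 0.
#' @return List with `percentile`, `summary_tpm`, `n_expressed`.
#' @export
expression_percentile <- function(expr, gene_id,
                                  sample_set = sample_ids(expr),
                                  expressed_rule = function(m) m > 0) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!gene_id %in% gene_ids(expr)) stop("gene '", gene_id, "' not in matrix")
  vals <- expr$values[, sample_set, drop = FALSE]
  med <- apply(vals, 1L, median)
  expressed <- expressed_rule(med)
  universe <- med[expressed | names(med) == gene_id]
  n <- length(universe)
  if (n < 2L) stop("fewer than 2 genes in the expressed universe")
  r <- rank(universe)[names(universe) == gene_id]
  list(percentile = unname(100 * (r - 1) / (n - 1)),
       summary_tpm = unname(med[gene_id]),
       n_expressed = sum(expressed))
}
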