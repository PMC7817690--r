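# Trimmed mean of M-values normalization, computed on coding genes.
# Per sample k vs a reference r, after library-size normalization
# (p = value / column sum), M = log2(p_k / p_r) and A = (log2 p_k +
# log2 p_r) / 2 over genes nonzero in both samples. The upper and lower
# trim_m fraction by M and trim_a fraction by A are discarded and the
# scaling factor is 2^(weighted mean M), with inverse-abundance
# precision weights; factors are rescaled to geometric mean 1.

.tmm_pair <- function(pk, pr, libk, libr, trim_m, trim_a, do_weighting) {
  keep <- pk > 0 & pr > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 genes nonzero in both sample and reference")
  pk <- pk[keep]; pr <- pr[keep]
  M <- log2(pk) - log2(pr)
  A <- (log2(pk) + log2(pr)) / 2
  if (max(abs(M)) < 1e-6) return(1)   # columns proportional
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep2)) stop("trimming removed every gene; reduce trim fractions")
  w <- if (do_weighting)
    1 / ((1 - pk[keep2]) / (libk * pk[keep2]) +
         (1 - pr[keep2]) / (libr * pr[keep2]))
  else rep(1, sum(keep2))
  2^(sum(w * M[keep2]) / sum(w))
}

#' TMM scaling factors for an expression matrix
#'
#' Computes trimmed-mean-of-M-values scaling factors across samples,
#' restricted to genes flagged `coding` in the annotation (all genes if
#' no annotation is given). Genes zero in either the sample or the
#' reference are excluded; returned factors are rescaled so their
#' geometric mean is 1. Dividing each column by its factor (after any
#' library-size scaling) aligns the bulk of the log-ratio distribution
#' across samples.
#'
#' @param expr an `ExpressionMatrix`.
#' @param annotation optional `GeneAnnotation` supplying the `coding`
#'   flags.
#' @param reference `"auto"` (sample whose upper-quartile expression is
#'   closest to the mean upper quartile, as in standard TMM practice) or
#'   a sample id.
#' @param trim_m fraction trimmed from each end by M (default 0.30).
#' @param trim_a fraction trimmed from each end by A (default 0.05).
#' @param do_weighting use binomial precision weights as count-based TMM
#'   does. Off by default: the weights assume count sampling noise, which
#'   TPM values do not carry, and they break invariance to uniform
#'   per-sample rescaling. Enable for count matrices.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(expr, annotation = NULL, reference = "auto",
                        trim_m = 0.30, trim_a = 0.05, do_weighting = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  vals <- expr$values
  if (!is.null(annotation)) {
    coding <- genes_with_category(annotation, "coding")
    coding <- intersect(rownames(vals), coding)
    if (length(coding) < 2L) stop("fewer than 2 coding genes in matrix")
    vals <- vals[coding, , drop = FALSE]
  }
  if (ncol(vals) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(vals)
  if (any(lib <= 0)) stop("sample with zero total expression")
  p <- sweep(vals, 2L, lib, "/")
  if (identical(reference, "auto")) {
    uq <- apply(p, 2L, function(col) quantile(col[col > 0], 0.75))
    ref_idx <- which.min(abs(uq - mean(uq)))
  } else {
    ref_idx <- match(reference, colnames(vals))
    if (is.na(ref_idx)) stop("reference sample '", reference, "' not found")
  }
  f <- vapply(seq_len(ncol(vals)), function(k) {
    if (k == ref_idx) return(1)
    .tmm_pair(p[, k], p[, ref_idx], lib[k], lib[ref_idx],
              trim_m, trim_a, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(vals))
}

#' Apply TMM factors to an expression matrix
#'
#' @param expr a raw `ExpressionMatrix`.
#' @param factors factors from [tmm_factors()], one per sample.
#' @return An `ExpressionMatrix` with each column divided by its factor
#'   and `normalized = TRUE`.
#' @export
apply_tmm <- function(expr, factors) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalized) stop("matrix is already normalized")
  factors <- factors[colnames(expr$values)]
  if (anyNA(factors)) stop("factors missing for some samples")
  expression_matrix(sweep(expr$values, 2L, factors, "/"), normalized = TRUE)
}
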