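# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately use a different algorithm than the package code
# they check.

# Brute-force Mann-Whitney: enumerate every assignment of the pooled
# values into groups of sizes (n1, n2) and compute the permutation
# p-value of U directly.
bf_mann_whitney <- function(x, y, alternative = "two_sided") {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         x_less = p_le, x_greater = p_ge,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Spreadsheet-style TMM for two library-size-normalized columns:
# unweighted trimmed mean of M over doubly-trimmed genes.
bf_tmm_two_sample <- function(a, b, trim_m = 0.30, trim_a = 0.05) {
  pa <- a / sum(a); pb <- b / sum(b)
  keep <- pa > 0 & pb > 0
  M <- log2(pa[keep] / pb[keep])
  A <- (log2(pa[keep]) + log2(pb[keep])) / 2
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  sel <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  2^mean(M[sel])
}

# small expression matrix with named genes/samples
toy_expr <- function(values, genes = NULL, samps = NULL) {
  m <- if (is.matrix(values)) values
    else if (is.null(genes)) matrix(values, ncol = 1L)
    else matrix(values, nrow = length(genes))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samps)) samps <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samps)
  expression_matrix(m)
}

# annotation flagging one sH2A paralogue gene plus plain coding genes
toy_annotation <- function(gene_ids, sh2a = character()) {
  cats <- lapply(gene_ids, function(g)
    if (g %in% sh2a) c("coding", "sH2A_paralogue") else "coding")
  gene_annotation(gene_ids, chromosome = "chr1",
                  start = seq_along(gene_ids) * 1000L,
                  end = seq_along(gene_ids) * 1000L + 500L,
                  categories = cats,
                  paralogue = ifelse(gene_ids %in% sh2a, "H2AFB1",
                                     NA_character_))
}

psi_from_rows <- function(rows, classes, samps) {
  psi_table(sprintf("ev%d", seq_len(nrow(rows))), classes,
            matrix(rows, nrow = nrow(rows),
                   dimnames = list(NULL, samps)))
}
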