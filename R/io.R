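# Tabular and sequence I/O. All tables are tab-delimited UTF-8 with a
# header row; writers emit a deterministic column order so round trips
# are byte-stable.

.tsv_header <- function(path) {
  strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
}

#' Read a gene x sample TPM matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Values must be non-negative and numeric; duplicate gene or sample ids
#' are rejected.
#'
#' @param path file path.
#' @param orientation only `"genes_in_rows"` is supported.
#' @return An [expression_matrix()] with `normalized = FALSE`.
#' @export
read_expression_matrix <- function(path, orientation = "genes_in_rows") {
  orientation <- match.arg(orientation, "genes_in_rows")
  header <- .tsv_header(path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("expression TSV needs gene id column plus samples")
  ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -1L, with = FALSE], is.numeric, logical(1)))[1L]
    stop("non-numeric expression values in column '", header[-1L][bad], "'")
  }
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, header[-1L])  # fread mangles duplicate names
  expression_matrix(vals, normalized = FALSE)
}

#' Write an expression matrix to TSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output file path.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  dt <- data.table::data.table(gene_id = gene_ids(expr))
  dt <- cbind(dt, data.table::as.data.table(expr$values))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a Psi table from TSV
#'
#' Columns: `event_id`, `event_class`, then one Psi column per sample.
#' Empty cells are missing values (`NA`), never zero.
#'
#' @param path file path.
#' @return A [psi_table()].
#' @export
read_psi_table <- function(path) {
  header <- .tsv_header(path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2), na.strings = "")
  need <- c("event_id", "event_class")
  if (!all(need %in% colnames(dt)[1:2]))
    stop("Psi TSV must start with columns: event_id, event_class")
  psi <- as.matrix(dt[, -(1:2), with = FALSE])
  if (!is.numeric(psi)) stop("non-numeric Psi values")
  storage.mode(psi) <- "double"
  colnames(psi) <- header[-(1:2)]
  psi_table(dt$event_id, dt$event_class, psi)
}

#' Write a Psi table to TSV
#' @param psi a `PsiTable`.
#' @param path output file path.
#' @export
write_psi_table <- function(psi, path) {
  stopifnot(inherits(psi, "PsiTable"))
  dt <- data.table::data.table(event_id = psi$event_id,
                               event_class = psi$event_class)
  dt <- cbind(dt, data.table::as.data.table(psi$psi))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a somatic mutation table (minimal MAF dialect)
#'
#' Requires columns `sample_id`, `gene_symbol`, `protein_change`,
#' `cancer_type`; extra MAF columns are ignored, not errors. Protein
#' changes are parsed into reference residue, 1-based canonical
#' position, and alternate residue; unparseable rows error with their
#' row number.
#'
#' @param path file path.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample_id", "gene_symbol", "protein_change", "cancer_type")
  miss <- setdiff(need, colnames(dt))
  if (length(miss)) stop("mutation TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  mutation_table(dt$sample_id, dt$gene_symbol, dt$protein_change,
                 dt$cancer_type)
}

#' Write a mutation table to TSV
#' @param muts a `MutationTable`.
#' @param path output file path.
#' @export
write_mutation_table <- function(muts, path) {
  stopifnot(inherits(muts, "MutationTable"))
  cols <- c("sample_id", "gene_symbol", "protein_change", "cancer_type")
  data.table::fwrite(as.data.frame(muts)[, cols], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#' @param path file path with columns `sample_id`, `cancer_type`,
#'   `tissue_class` (extra columns become `extra_labels`).
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample_id", "cancer_type", "tissue_class")
  miss <- setdiff(need, colnames(dt))
  if (length(miss)) stop("sample TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(dt), need)
  sample_table(dt$sample_id, dt$cancer_type, dt$tissue_class,
               extra_labels = if (length(extra)) as.list(dt[, extra, with = FALSE]))
}

#' Write a sample table to TSV
#' @param samples a `SampleTable`.
#' @param path output file path.
#' @export
write_sample_table <- function(samples, path) {
  stopifnot(inherits(samples, "SampleTable"))
  data.table::fwrite(as.data.frame(samples), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Coordinates are 1-based inclusive. The `categories` column holds
#' comma-separated category flags (empty for none).
#'
#' @param path file path.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("gene_id", "symbol", "chromosome", "start", "end", "strand",
            "paralogue", "categories")
  miss <- setdiff(need, colnames(dt))
  if (length(miss)) stop("annotation TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  cats <- lapply(strsplit(ifelse(is.na(dt$categories), "", dt$categories), ","),
                 function(x) x[nzchar(x)])
  gene_annotation(dt$gene_id, dt$symbol, dt$chromosome, dt$start, dt$end,
                  dt$strand, categories = cats, paralogue = dt$paralogue)
}

#' Write a gene annotation table to TSV
#' @param annotation a `GeneAnnotation`.
#' @param path output file path.
#' @export
write_gene_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  df <- as.data.frame(annotation)[, c("gene_id", "symbol", "chromosome",
                                      "start", "end", "strand", "paralogue")]
  df$categories <- vapply(annotation$categories, paste, character(1),
                          collapse = ",")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gapped protein alignment from FASTA
#'
#' All records must have equal gapped length and the canonical record
#' must be present.
#'
#' @param path FASTA file path.
#' @param canonical_name record name anchoring ungapped coordinates.
#' @return A [protein_alignment()].
#' @export
read_alignment_fasta <- function(path, canonical_name) {
  seqs <- Biostrings::readBStringSet(path)
  protein_alignment(setNames(as.character(seqs), names(seqs)), canonical_name)
}

#' Write a protein alignment to FASTA
#' @param aln a `ProteinAlignment`.
#' @param path output file path.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "ProteinAlignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}
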