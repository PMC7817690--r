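# Closed vocabularies shared across the pipeline ------------------------------

#' Splicing event classes understood by the pipeline
#'
#' Cassette exons (SE), retained introns (RI), alternative 3'/5' splice
#' sites, mutually exclusive exons, tandem 3'UTR (alternative
#' polyadenylation, where Psi is the proximal-site usage fraction),
#' alternative first/last exons, and constitutive junctions.
#' @export
EVENT_CLASSES <- c("SE", "RI", "A3SS", "A5SS", "MXE", "TandemUTR",
                   "AFE", "ALE", "constitutive")

#' Tissue classes for cohort samples
#' @export
TISSUE_CLASSES <- c("tumor", "adjacent_normal", "cell_line")

#' Short-H2A paralogue names
#'
#' The X-linked short H2A variant genes: the three H2A.B paralogues
#' plus H2A.P (HYPM) and the unannotated H2A.Q.
#' @export
SH2A_PARALOGUES <- c("H2AFB1", "H2AFB2", "H2AFB3", "HYPM", "H2A.Q")

.CATEGORY_FIXED <- c("sH2A_paralogue", "CTA", "canonical_histone_H2A",
                     "canonical_histone_H2B", "coding")

.valid_category <- function(x) {
  x %in% .CATEGORY_FIXED | grepl("^marker_panel:", x)
}

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ExpressionMatrix ------------------------------------------------------------

#' Construct an expression matrix container
#'
#' Holds a genes x samples matrix of TPM values together with a flag
#' recording whether TMM scaling has been applied.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param normalized logical; `FALSE` for raw TPM.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match identifier lists")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ", sample_ids[duplicated(sample_ids)][1L])
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative or non-finite value for gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "TMM-normalized" else "raw TPM"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# SampleTable -----------------------------------------------------------------

#' Construct a sample metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param cancer_type categorical cancer-type label per sample.
#' @param tissue_class one of `TISSUE_CLASSES` per sample.
#' @param extra_labels optional named list of additional per-sample
#'   label vectors.
#' @return A `data.frame` of class `SampleTable`.
#' @export
sample_table <- function(sample_id, cancer_type,
                         tissue_class = "tumor", extra_labels = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  n <- length(sample_id)
  cancer_type <- rep_len(as.character(cancer_type), n)
  tissue_class <- rep_len(as.character(tissue_class), n)
  if (!all(tissue_class %in% TISSUE_CLASSES))
    stop("tissue_class must be one of: ",
         paste(TISSUE_CLASSES, collapse = ", "))
  out <- data.frame(sample_id = sample_id, cancer_type = cancer_type,
                    tissue_class = tissue_class, stringsAsFactors = FALSE)
  if (!is.null(extra_labels)) {
    stopifnot(is.list(extra_labels), !is.null(names(extra_labels)))
    for (nm in names(extra_labels)) out[[nm]] <- rep_len(extra_labels[[nm]], n)
  }
  class(out) <- c("SampleTable", "data.frame")
  out
}

# GeneAnnotation --------------------------------------------------------------

#' Construct a gene annotation table
#'
#' Coordinates are 1-based inclusive (GTF convention) and are never
#' converted implicitly. Category flags come from a closed vocabulary;
#' short-H2A paralogue genes additionally carry the paralogue name.
#'
#' @param gene_id,symbol character vectors.
#' @param chromosome chromosome labels (e.g. "chrX").
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand "+" or "-".
#' @param categories list of character vectors, one per gene, drawn from
#'   `sH2A_paralogue`, `CTA`, `canonical_histone_H2A`,
#'   `canonical_histone_H2B`, `coding`, `marker_panel:<name>`.
#' @param paralogue for sH2A genes, the paralogue name (one of
#'   `SH2A_PARALOGUES`); `NA` otherwise.
#' @return A `data.frame` of class `GeneAnnotation` with a list-column
#'   `categories`.
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, chromosome,
                            start, end, strand = "+",
                            categories = vector("list", length(gene_id)),
                            paralogue = NA_character_) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  n <- length(gene_id)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("start > end for gene ",
                             gene_id[which(start > end)[1L]])
  if (any(start < 1L)) stop("coordinates are 1-based; start must be >= 1")
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.list(categories) || length(categories) != n)
    stop("'categories' must be a list with one entry per gene")
  allcat <- unlist(categories)
  if (length(allcat) && !all(.valid_category(allcat)))
    stop("unknown category: ", allcat[!.valid_category(allcat)][1L])
  paralogue <- rep_len(as.character(paralogue), n)
  is_sh2a <- vapply(categories, function(cc) "sH2A_paralogue" %in% cc, logical(1))
  if (any(is_sh2a & (is.na(paralogue) | !paralogue %in% SH2A_PARALOGUES)))
    stop("sH2A_paralogue genes must carry a paralogue name from: ",
         paste(SH2A_PARALOGUES, collapse = ", "))
  out <- data.frame(gene_id = gene_id, symbol = rep_len(as.character(symbol), n),
                    chromosome = rep_len(as.character(chromosome), n),
                    start = start, end = rep_len(end, n),
                    strand = strand, paralogue = paralogue,
                    stringsAsFactors = FALSE)
  out$categories <- categories
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

#' Select gene ids carrying a category flag
#'
#' @param annotation a `GeneAnnotation`.
#' @param category a single category label (e.g. `"CTA"`, `"coding"`,
#'   `"marker_panel:histone_chaperone"`).
#' @return Character vector of gene ids.
#' @export
genes_with_category <- function(annotation, category) {
  keep <- vapply(annotation$categories, function(cc) category %in% cc,
                 logical(1))
  annotation$gene_id[keep]
}

# PsiTable --------------------------------------------------------------------

#' Construct a percent-spliced-in (Psi) table
#'
#' One row per splicing event; Psi values per sample lie in `[0, 1]`
#' with `NA` for missing (an empty field is missing, never zero -- zero
#' is a valid biological value).
#'
#' @param event_id character vector of unique event identifiers.
#' @param event_class one of `EVENT_CLASSES` per event.
#' @param psi numeric matrix of Psi values, events x samples, with
#'   sample ids as column names.
#' @return An object of class `PsiTable`.
#' @export
psi_table <- function(event_id, event_class, psi) {
  event_id <- as.character(event_id)
  if (anyDuplicated(event_id))
    stop("duplicate event_id: ", event_id[duplicated(event_id)][1L])
  event_class <- as.character(event_class)
  if (!all(event_class %in% EVENT_CLASSES))
    stop("unknown event_class: ",
         event_class[!event_class %in% EVENT_CLASSES][1L])
  if (!is.matrix(psi) || !is.numeric(psi)) stop("'psi' must be a numeric matrix")
  if (nrow(psi) != length(event_id)) stop("psi rows must match event_id")
  if (is.null(colnames(psi))) stop("psi must carry sample ids as column names")
  bad <- which(!is.na(psi) & (psi < 0 | psi > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("Psi out of [0,1] for event '%s', sample '%s'",
                 event_id[bad[1L, 1L]], colnames(psi)[bad[1L, 2L]]))
  rownames(psi) <- event_id
  structure(list(event_id = event_id, event_class = event_class, psi = psi),
            class = "PsiTable")
}

#' @export
print.PsiTable <- function(x, ...) {
  cat(sprintf("PsiTable: %d events x %d samples; classes: %s\n",
              length(x$event_id), ncol(x$psi),
              paste(names(table(x$event_class)), collapse = ", ")))
  invisible(x)
}

# MutationTable ---------------------------------------------------------------

.PROT_CHANGE_RE <- "^([A-Z])([0-9]+)([A-Z*])$"

parse_protein_change <- function(protein_change) {
  ok <- grepl(.PROT_CHANGE_RE, protein_change)
  if (!all(ok))
    stop("unparseable protein_change at row ", which(!ok)[1L], ": '",
         protein_change[!ok][1L], "'")
  data.frame(
    ref_aa = sub(.PROT_CHANGE_RE, "\\1", protein_change),
    position = as.integer(sub(.PROT_CHANGE_RE, "\\2", protein_change)),
    alt_aa = sub(.PROT_CHANGE_RE, "\\3", protein_change),
    stringsAsFactors = FALSE)
}

#' Construct a somatic mutation table
#'
#' Minimal MAF dialect: sample, gene symbol, short-form protein change
#' (`E121Q`: reference residue, 1-based canonical position, alternate
#' residue), and cancer type.
#'
#' @param sample_id,gene_symbol,protein_change,cancer_type character
#'   vectors of equal length.
#' @return A `data.frame` of class `MutationTable` with the parsed
#'   `ref_aa`, `position`, `alt_aa` columns appended.
#' @export
mutation_table <- function(sample_id, gene_symbol, protein_change,
                           cancer_type) {
  n <- length(sample_id)
  stopifnot(length(gene_symbol) == n, length(protein_change) == n,
            length(cancer_type) == n)
  parsed <- if (n) parse_protein_change(as.character(protein_change)) else
    data.frame(ref_aa = character(), position = integer(),
               alt_aa = character())
  if (n && any(parsed$position < 1L)) stop("protein position must be >= 1")
  out <- data.frame(sample_id = as.character(sample_id),
                    gene_symbol = as.character(gene_symbol),
                    protein_change = as.character(protein_change),
                    cancer_type = as.character(cancer_type),
                    stringsAsFactors = FALSE)
  out <- cbind(out, parsed)
  class(out) <- c("MutationTable", "data.frame")
  out
}

# ProteinAlignment ------------------------------------------------------------

#' Construct a gapped protein multiple alignment
#'
#' @param sequences named character vector of equal-length gapped
#'   sequences over the 20 amino acids plus `-`.
#' @param canonical_name name of the record used as the ungapped
#'   coordinate reference.
#' @return An object of class `ProteinAlignment`.
#' @export
protein_alignment <- function(sequences, canonical_name) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all alignment records must be named")
  if (anyDuplicated(names(sequences))) stop("duplicate record names")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(widths), collapse = ", "), ")")
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(.AA_ALPHABET, "-"))
  if (length(bad)) stop("invalid alignment character(s): ",
                        paste(bad, collapse = ""))
  if (!canonical_name %in% names(sequences))
    stop("canonical record '", canonical_name, "' not present in alignment")
  structure(list(sequences = sequences, canonical_name = canonical_name,
                 width = unname(widths[1L])),
            class = "ProteinAlignment")
}

#' @export
print.ProteinAlignment <- function(x, ...) {
  cat(sprintf("ProteinAlignment: %d records, width %d, canonical '%s'\n",
              length(x$sequences), x$width, x$canonical_name))
  invisible(x)
}
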