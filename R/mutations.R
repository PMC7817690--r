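# Somatic histone-mutation collation and alignment-based mapping of
# recurrent oncohistone substitutions onto variant sequences.
#
# Protein positions are 1-based on the ungapped canonical sequence
# (standard histone numbering: E121, R29 on core H2A).

#' Load a gene-class catalogue from TSV
#'
#' Two columns: `class_name`, `gene_symbol`. The packaged default
#' (`inst/extdata/gene_classes.tsv`) seeds the canonical H2A and H2B
#' replication-coupled histone gene sets plus placeholder
#' lymphoma-subtype panels; panels are data, meant to be edited.
#'
#' @param path TSV path; default: the packaged catalogue.
#' @return Named list of character vectors of class `GeneClassCatalogue`.
#' @export
read_gene_classes <- function(path = system.file("extdata", "gene_classes.tsv",
                                                 package = "sh2ascan")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("class_name", "gene_symbol") %in% colnames(dt)))
    stop("catalogue TSV needs columns class_name, gene_symbol")
  gene_class_catalogue(split(dt$gene_symbol, dt$class_name))
}

#' Construct a gene-class catalogue
#'
#' @param classes named list mapping class names to non-empty character
#'   vectors of gene symbols (unique within a class).
#' @return The validated list with class `GeneClassCatalogue`.
#' @export
gene_class_catalogue <- function(classes) {
  stopifnot(is.list(classes), !is.null(names(classes)))
  for (nm in names(classes)) {
    if (length(classes[[nm]]) == 0L) stop("empty gene class: ", nm)
    if (anyDuplicated(classes[[nm]]))
      stop("duplicate symbol in class ", nm)
  }
  structure(classes, class = "GeneClassCatalogue")
}

#' Collate recurrent protein changes within gene classes
#'
#' Counts each protein change pooled across cancer types and across all
#' genes of a class (so e.g. E121Q events in different canonical H2A
#' genes accumulate into one count). A change is recurrent iff its
#' pooled count reaches `min_count`.
#'
#' @param muts a `MutationTable`.
#' @param catalogue a `GeneClassCatalogue`.
#' @param min_count recurrence threshold (default 5).
#' @return `data.frame` with `class_name`, `protein_change`, `count`,
#'   `recurrent`, sorted by class then descending count.
#' @export
collate_recurrent_mutations <- function(muts, catalogue, min_count = 5) {
  stopifnot(inherits(muts, "MutationTable"),
            inherits(catalogue, "GeneClassCatalogue"))
  out <- do.call(rbind, lapply(names(catalogue), function(cl) {
    d <- muts[muts$gene_symbol %in% catalogue[[cl]], ]
    if (nrow(d) == 0L) return(NULL)
    tab <- table(d$protein_change)
    data.frame(class_name = cl, protein_change = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(class_name = character(), protein_change = character(),
                      count = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE))
  out$recurrent <- out$count >= min_count
  out <- out[order(out$class_name, -out$count, out$protein_change), ]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate panel mutations against reactivation status
#'
#' Flags each sample for carrying at least one mutation in any gene of
#' each panel, joins the any-paralogue-positive reactivation flag, and
#' cross-tabulates. Panel genes absent from the mutation table simply
#' yield FALSE flags.
#'
#' @param muts a `MutationTable`.
#' @param gene_panels a `GeneClassCatalogue` of panels.
#' @param statuses output of [classify_sh2a_status()].
#' @return List with `flags` (sample x panel logical data.frame
#'   including `sh2a_positive`) and `crosstab` (per panel, counts of
#'   mutated x positive).
#' @export
subtype_cooccurrence <- function(muts, gene_panels, statuses) {
  stopifnot(inherits(muts, "MutationTable"),
            inherits(gene_panels, "GeneClassCatalogue"))
  sids <- unique(statuses$sample_id)
  pos <- any_paralogue_positive(statuses)
  flags <- data.frame(sample_id = sids, stringsAsFactors = FALSE)
  for (nm in names(gene_panels)) {
    mutated <- unique(muts$sample_id[muts$gene_symbol %in% gene_panels[[nm]]])
    flags[[nm]] <- sids %in% mutated
  }
  flags$sh2a_positive <- unname(pos[sids])
  crosstab <- do.call(rbind, lapply(names(gene_panels), function(nm) {
    data.frame(panel = nm,
               n_mutated = sum(flags[[nm]]),
               n_mutated_positive = sum(flags[[nm]] & flags$sh2a_positive),
               n_mutated_negative = sum(flags[[nm]] & !flags$sh2a_positive),
               n_unmutated_positive = sum(!flags[[nm]] & flags$sh2a_positive),
               n_unmutated_negative = sum(!flags[[nm]] & !flags$sh2a_positive),
               stringsAsFactors = FALSE)
  }))
  list(flags = flags, crosstab = crosstab)
}

# Map between ungapped canonical positions and alignment columns.
# Returns an integer vector: column index of each ungapped position.
ungapped_to_gapped <- function(gapped_seq) {
  chars <- strsplit(gapped_seq, "")[[1]]
  which(chars != "-")
}

gapped_to_ungapped <- function(gapped_seq) {
  chars <- strsplit(gapped_seq, "")[[1]]
  out <- cumsum(chars != "-")
  out[chars == "-"] <- NA_integer_
  out
}

#' Map oncohistone mutation sites onto a variant sequence
#'
#' For each recurrent canonical mutation (short form, e.g. `"R29Q"`),
#' locates the alignment column of the canonical position and reports
#' the variant's residue there. `matches_oncomutation` is TRUE iff the
#' variant's wild-type residue equals the oncomutation's alternate
#' residue — i.e. the variant constitutively carries the cancer
#' substitution. If the variant has only gaps from that column through
#' the C-terminal end of the alignment, the feature is reported as
#' `TRUNCATED` (an internal deletion is reported as a gap, not a
#' truncation). The canonical record must carry the stated reference
#' residue at each position, which catches mis-numbered catalogues.
#'
#' @param aln a `ProteinAlignment`.
#' @param variant_name record to interrogate.
#' @param oncomutations character vector of protein changes on the
#'   canonical sequence (`<ref><pos><alt>`).
#' @return `data.frame` with `oncomutation`, `canonical_position`,
#'   `canonical_aa`, `variant_name`, `variant_aa` (residue, `"-"` for an
#'   internal gap, or `"TRUNCATED"`), `matches_oncomutation`.
#' @export
map_oncohistone_features <- function(aln, variant_name, oncomutations) {
  stopifnot(inherits(aln, "ProteinAlignment"))
  if (!variant_name %in% names(aln$sequences))
    stop("variant record '", variant_name, "' not in alignment")
  canon <- aln$sequences[[aln$canonical_name]]
  var <- aln$sequences[[variant_name]]
  cmap <- ungapped_to_gapped(canon)
  canon_chars <- strsplit(canon, "")[[1]]
  var_chars <- strsplit(var, "")[[1]]
  # columns after which the variant has no residue at all
  last_res <- max(c(0L, which(var_chars != "-")))
  feats <- parse_protein_change(oncomutations)
  out <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    pos <- feats$position[i]
    if (pos > length(cmap))
      stop("canonical position ", pos, " beyond canonical length ",
           length(cmap))
    col <- cmap[pos]
    if (canon_chars[col] != feats$ref_aa[i])
      stop(sprintf(
        "canonical residue mismatch at position %d: expected %s, found %s",
        pos, feats$ref_aa[i], canon_chars[col]))
    truncated <- col > last_res
    vaa <- if (truncated) "TRUNCATED" else var_chars[col]
    data.frame(oncomutation = oncomutations[i], canonical_position = pos,
               canonical_aa = feats$ref_aa[i], variant_name = variant_name,
               variant_aa = vaa,
               matches_oncomutation = identical(vaa, feats$alt_aa[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
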