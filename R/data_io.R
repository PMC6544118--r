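#' Read and validate a tabular input
#'
#' Reads one of the pipeline's tab-delimited tables and validates it against
#' the declared schema. Row order is preserved and duplicate keys are
#' rejected rather than aggregated, so that any aggregation policy stays an
#' explicit, visible analysis step.
#'
#' Schemas and their required columns (a few aliases from common export
#' dialects are accepted and renamed on read):
#' \describe{
#'   \item{protein_quant}{`protein_id`, `gene_name`, `intensity`,
#'     `n_unique_peptides`, `min_peptide_length`, `strain`, `replicate`.}
#'   \item{reference_abundance}{`gene_name`, `copies_iBAQ`, `copies_emPAI`,
#'     `copies_APEX` — per-gene copies per cell on three label-free scales.}
#'   \item{value_table}{`key`, `value` and optionally `value_kind`
#'     (one of intensity, copies, rpkM, half_life_h, read_count).}
#'   \item{kinetics}{`enzyme_gene`, `k_cat`, `K_M`, optionally
#'     `k_cat_organism`, `K_M_organism`, `homology_pct`; every row must carry
#'     at least one of `k_cat`, `K_M`.}
#' }
#'
#' @param path Path to a TSV file (plain or gzip-compressed).
#' @param schema One of `"protein_quant"`, `"reference_abundance"`,
#'   `"value_table"`, `"kinetics"`.
#' @return A validated `data.frame` in file row order.
#' @examples
#' path <- system.file("extdata", "table1_kinetics.tsv", package = "opstoich")
#' kin <- read_quant_table(path, "kinetics")
#' kin[kin$enzyme_gene == "ArgB", c("k_cat", "K_M")]
#' @export
read_quant_table <- function(path,
                             schema = c("protein_quant", "reference_abundance",
                                        "value_table", "kinetics")) {
  schema <- match.arg(schema)
  x <- .read_tsv(path)

  aliases <- list(
    protein_quant = c(unique_peptides = "n_unique_peptides",
                      peptide_length = "min_peptide_length",
                      gene = "gene_name"),
    reference_abundance = c(gene = "gene_name"),
    value_table = c(gene = "key", gene_id = "key"),
    kinetics = c(kcat = "k_cat", km = "K_M", KM = "K_M")
  )[[schema]]
  for (from in names(aliases))
    if (from %in% names(x) && !(aliases[[from]] %in% names(x)))
      names(x)[names(x) == from] <- aliases[[from]]

  required <- list(
    protein_quant = c("protein_id", "gene_name", "intensity",
                      "n_unique_peptides", "min_peptide_length",
                      "strain", "replicate"),
    reference_abundance = c("gene_name", "copies_iBAQ", "copies_emPAI",
                            "copies_APEX"),
    value_table = c("key", "value"),
    kinetics = c("enzyme_gene", "k_cat", "K_M")
  )[[schema]]
  missing <- setdiff(required, names(x))
  if (length(missing))
    .stopf("schema '%s': missing required column(s): %s", schema,
           paste(missing, collapse = ", "))

  nonneg <- list(
    protein_quant = c("intensity", "n_unique_peptides", "min_peptide_length"),
    reference_abundance = c("copies_iBAQ", "copies_emPAI", "copies_APEX"),
    value_table = "value",
    kinetics = c("k_cat", "K_M")
  )[[schema]]
  for (col in nonneg) {
    v <- x[[col]]
    if (!is.numeric(v))
      .stopf("column '%s' must be numeric", col)
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      .stopf("column '%s' has a negative value at row %d", col, bad[1L])
  }

  keycol <- switch(schema, protein_quant = NULL, reference_abundance = "gene_name",
                   value_table = "key", kinetics = "enzyme_gene")
  if (schema == "protein_quant") {
    key <- paste(x$protein_id, x$strain, x$replicate, sep = "\r")
    if (anyDuplicated(key))
      .stopf("duplicate protein_id within a strain/replicate: %s",
             x$protein_id[duplicated(key)][1L])
    if (any(!nzchar(x$protein_id)) || any(!nzchar(x$gene_name)))
      .stopf("empty identifiers in protein_quant table")
  } else if (anyDuplicated(x[[keycol]])) {
    .stopf("duplicate key in %s table: %s", schema,
           x[[keycol]][duplicated(x[[keycol]])][1L])
  }

  if (schema == "kinetics") {
    bad <- which(is.na(x$k_cat) & is.na(x$K_M))
    if (length(bad))
      .stopf("kinetics row %d (%s) has neither k_cat nor K_M", bad[1L],
             x$enzyme_gene[bad[1L]])
    if (!"k_cat_organism" %in% names(x)) x$k_cat_organism <- NA_character_
    if (!"K_M_organism" %in% names(x)) x$K_M_organism <- NA_character_
    if (!"homology_pct" %in% names(x)) x$homology_pct <- NA_real_
  }
  if (schema == "value_table") {
    if (!"value_kind" %in% names(x)) x$value_kind <- "intensity"
    if (any(!nzchar(x$key))) .stopf("empty key in value table")
  }
  x
}

#' Write a validated table back to TSV
#'
#' Inverse of [read_quant_table()]; writing then reading reproduces the
#' records field-for-field (up to numeric print precision).
#'
#' @param x A data.frame as returned by [read_quant_table()].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) .write_tsv(x, path)

#' Build a value table from named values
#'
#' Convenience constructor for the generic key/value substrate used by the
#' calibration and CV stages.
#'
#' @param values Named numeric vector (names are gene/protein keys).
#' @param value_kind One of intensity, copies, rpkM, half_life_h, read_count.
#' @return A `data.frame` with columns key, value, value_kind.
#' @export
value_table <- function(values, value_kind = "intensity") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    .stopf("'values' must be a fully named vector")
  if (anyDuplicated(names(values)))
    .stopf("duplicate keys in value table: %s",
           names(values)[duplicated(names(values))][1L])
  if (any(values < 0, na.rm = TRUE)) .stopf("values must be non-negative")
  kinds <- c("intensity", "copies", "rpkM", "half_life_h", "read_count")
  value_kind <- match.arg(value_kind, kinds)
  data.frame(key = names(values), value = as.numeric(values),
             value_kind = value_kind, stringsAsFactors = FALSE,
             row.names = NULL)
}

.as_named_values <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("key", "value") %in% names(x)))
    stats::setNames(x$value, x$key)
  } else if (is.numeric(x) && !is.null(names(x))) x
  else .stopf("expected a value table (data.frame key/value) or named vector")
}

#' Read operon membership and gene annotation
#'
#' Reads a DOOR2-style operon table together with a GFF3 gene annotation and
#' returns operons with their genes re-ordered into 5'->3' transcript order
#' (ascending start on the + strand, descending on the - strand). Two operon
#' table dialects are accepted: `operon_id` + `gene_ids` (comma- or
#' semicolon-separated) or long format `operon_id` + `gene_id` (+ optional
#' `rank`).
#'
#' Coordinates are 1-based inclusive on disk (GFF convention); interval
#' arithmetic elsewhere in the package converts to 0-based half-open.
#'
#' @param operon_path Path to the operon TSV.
#' @param gff_path Path to a GFF3 file; CDS features are used (falling back
#'   to gene features when no CDS present), with the `ID` attribute as the
#'   gene identifier.
#' @return A list with `operons` (long data.frame: operon_id, gene_id, rank,
#'   strand, contig) and `annotation` (data.frame: gene_id, contig, start,
#'   end, strand, cds_length_nt, protein_length_aa).
#' @export
read_operon_annotation <- function(operon_path, gff_path) {
  ops <- .read_tsv(operon_path)
  if (all(c("operon_id", "gene_ids") %in% names(ops))) {
    genes <- strsplit(as.character(ops$gene_ids), "[,;] *")
    ops <- data.frame(
      operon_id = rep(as.character(ops$operon_id), lengths(genes)),
      gene_id = unlist(genes), stringsAsFactors = FALSE)
  } else if (all(c("operon_id", "gene_id") %in% names(ops))) {
    if ("rank" %in% names(ops)) ops <- ops[order(ops$operon_id, ops$rank), ]
    ops <- data.frame(operon_id = as.character(ops$operon_id),
                      gene_id = as.character(ops$gene_id),
                      stringsAsFactors = FALSE)
  } else {
    .stopf("operon table needs columns operon_id + gene_ids or operon_id + gene_id")
  }
  dup <- duplicated(paste(ops$operon_id, ops$gene_id, sep = "\r"))
  if (any(dup))
    .stopf("duplicate gene %s in operon %s", ops$gene_id[dup][1L],
           ops$operon_id[dup][1L])

  ann <- read_gene_annotation(gff_path)
  order_operons(ops, ann)
}

#' Read gene annotation from GFF3
#'
#' @param gff_path Path to a GFF3 file (plain or gzipped).
#' @return Annotation data.frame (see [read_operon_annotation()]).
#' @export
read_gene_annotation <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  keep <- if (any(type == "CDS")) type == "CDS" else type == "gene"
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  if (anyNA(ids)) .stopf("GFF3 features lack ID attributes")
  ann <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (any(!ann$strand %in% c("+", "-")))
    .stopf("unstranded feature in annotation: %s",
           ann$gene_id[!ann$strand %in% c("+", "-")][1L])
  ann$cds_length_nt <- ann$end - ann$start + 1L
  ann$protein_length_aa <- ann$cds_length_nt %/% 3L - 1L
  ann
}

#' Re-order operon genes into transcript order
#'
#' Sorts each operon's genes by genomic coordinate according to strand
#' (ascending start for +, descending for -) and validates that all genes of
#' an operon share strand and contig and are annotated. Idempotent.
#'
#' @param operons Long data.frame with operon_id, gene_id.
#' @param annotation Annotation data.frame from [read_gene_annotation()].
#' @return As [read_operon_annotation()].
#' @export
order_operons <- function(operons, annotation) {
  miss <- setdiff(operons$gene_id, annotation$gene_id)
  if (length(miss))
    .stopf("operon table references unannotated gene: %s", miss[1L])
  idx <- match(operons$gene_id, annotation$gene_id)
  operons$start <- annotation$start[idx]
  operons$strand <- annotation$strand[idx]
  operons$contig <- annotation$contig[idx]
  for (op in unique(operons$operon_id)) {
    sel <- operons$operon_id == op
    if (length(unique(operons$strand[sel])) != 1L)
      .stopf("operon %s mixes strands", op)
    if (length(unique(operons$contig[sel])) != 1L)
      .stopf("operon %s spans contigs", op)
  }
  neg <- operons$strand == "-"
  key <- ifelse(neg, -operons$start, operons$start)
  operons <- operons[order(operons$operon_id, key), ]
  rank <- stats::ave(seq_len(nrow(operons)), operons$operon_id,
                     FUN = seq_along)
  out <- data.frame(operon_id = operons$operon_id, gene_id = operons$gene_id,
                    rank = as.integer(rank), strand = operons$strand,
                    contig = operons$contig, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(operons = out, annotation = annotation)
}

#' Apply identification-confidence filters
#'
#' Keeps protein quantification records passing the peptide-evidence
#' thresholds: relaxed requires at least one unique peptide of length >= 6
#' aa, stringent at least two unique peptides and length >= 7 aa.
#'
#' @param quant A protein_quant data.frame (see [read_quant_table()]).
#' @param mode `"relaxed"` or `"stringent"`.
#' @return The filtered data.frame; the number of removed records is attached
#'   as attribute `n_removed` and reported via `message()`.
#' @export
filter_confident <- function(quant, mode = c("relaxed", "stringent")) {
  mode <- match.arg(mode)
  stopifnot(all(c("n_unique_peptides", "min_peptide_length") %in% names(quant)))
  th <- if (mode == "relaxed") c(1L, 6L) else c(2L, 7L)
  keep <- quant$n_unique_peptides >= th[1L] & quant$min_peptide_length >= th[2L]
  keep[is.na(keep)] <- FALSE
  out <- quant[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  message(sprintf("filter_confident(%s): kept %d, removed %d records",
                  mode, sum(keep), sum(!keep)))
  out
}

#' Amino-acid sequence coverage by identified peptides
#'
#' Fraction of residue positions of `protein_seq` covered by at least one
#' exact occurrence of any peptide; all match positions of each peptide are
#' marked, overlaps counted once.
#'
#' @param peptides Character vector of peptide sequences.
#' @param protein_seq Protein sequence (single string).
#' @return Coverage fraction in `[0, 1]`.
#' @examples
#' sequence_coverage(c("ABC", "CDE"), "ABCDEF")  # 5/6
#' @export
sequence_coverage <- function(peptides, protein_seq) {
  .assert_string(protein_seq, "protein_seq")
  L <- nchar(protein_seq)
  if (length(peptides) == 0L) return(0)
  if (any(!nzchar(peptides))) .stopf("empty peptide string")
  covered <- logical(L)
  for (p in peptides) {
    w <- nchar(p)
    if (w > L) {
      warning(sprintf("peptide longer than protein (%d > %d): ignored", w, L))
      next
    }
    hits <- gregexpr(p, protein_seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (h in hits) covered[h:(h + w - 1L)] <- TRUE
  }
  sum(covered) / L
}
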