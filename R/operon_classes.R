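#' Classify one operon as Complex or Pathway
#'
#' An operon is labelled "Complex" when at least 90% of its annotated genes
#' encode subunits of one and the same protein complex; otherwise it is
#' labelled "Pathway". The fraction is taken over the single best-covered
#' complex (not a union of complexes) and over the operon's annotated gene
#' count, so classification is a genome property independent of detection.
#'
#' @param genes Character vector of the operon's gene ids.
#' @param membership Complex membership: data.frame with columns `gene_id`,
#'   `complex_id` (a gene may belong to several complexes), or a named list
#'   gene -> character vector of complex ids.
#' @param threshold Complex-fraction cut, default 0.9, boundary inclusive.
#' @return List with `label`, `complex_fraction`, `dominant_complex`.
#' @export
classify_operon <- function(genes, membership, threshold = 0.9) {
  if (length(genes) < 1L) .stopf("empty operon")
  if (is.data.frame(membership)) {
    stopifnot(all(c("gene_id", "complex_id") %in% names(membership)))
    mem <- membership[membership$gene_id %in% genes, , drop = FALSE]
    mem <- unique(mem[, c("gene_id", "complex_id")])
    tab <- if (nrow(mem)) table(mem$complex_id) else integer()
  } else {
    cx <- unlist(membership[intersect(names(membership), genes)],
                 use.names = FALSE)
    tab <- if (length(cx)) table(cx) else integer()
  }
  if (length(tab) == 0L) {
    return(list(label = "Pathway", complex_fraction = 0,
                dominant_complex = NA_character_))
  }
  best <- which.max(tab)
  frac <- as.numeric(tab[best]) / length(genes)
  list(label = if (frac >= threshold) "Complex" else "Pathway",
       complex_fraction = frac,
       dominant_complex = names(tab)[best])
}

#' Classify all operons in a set
#'
#' @param operons Long operon data.frame (operon_id, gene_id, ...).
#' @param membership See [classify_operon()].
#' @param threshold See [classify_operon()].
#' @return data.frame: operon_id, label, complex_fraction, dominant_complex.
#' @export
classify_operons <- function(operons, membership, threshold = 0.9) {
  ids <- unique(operons$operon_id)
  res <- lapply(ids, function(op)
    classify_operon(operons$gene_id[operons$operon_id == op], membership,
                    threshold))
  data.frame(operon_id = ids,
             label = vapply(res, `[[`, "", "label"),
             complex_fraction = vapply(res, `[[`, 0, "complex_fraction"),
             dominant_complex = vapply(res, `[[`, "", "dominant_complex"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split real CV records at the randomized null median
#'
#' Within each operon size group, operons whose CV lies below the median of
#' the randomized null CVs of that group are labelled `L<g>` (tightly
#' controlled) and those at or above the median `H<g>` (ties go high). The
#' suffix is 2, 3, 4 or 5 (the ">= 5 genes" bucket).
#'
#' @param real_cvs `operon_cv_records` with `source = "real"`.
#' @param null_cvs `operon_cv_records` with `source = "randomized"` (the
#'   pooled permutation null).
#' @return `real_cvs` with added columns `null_median` and `subgroup`;
#'   per-group medians in attribute `null_medians`. Size groups absent from
#'   the null are skipped with a warning (subgroup `NA`).
#' @export
split_by_null_median <- function(real_cvs, null_cvs) {
  med <- tapply(null_cvs$cv_percent, null_cvs$size_group, stats::median)
  suffix <- sub("plus$", "", real_cvs$size_group)
  real_cvs$null_median <- as.numeric(med[real_cvs$size_group])
  missing_groups <- setdiff(unique(real_cvs$size_group), names(med))
  if (length(missing_groups))
    warning(sprintf("no null CVs for size group(s) %s; subgroup left NA",
                    paste(missing_groups, collapse = ", ")))
  real_cvs$subgroup <- ifelse(is.na(real_cvs$null_median), NA_character_,
                              paste0(ifelse(real_cvs$cv_percent <
                                              real_cvs$null_median, "L", "H"),
                                     suffix))
  attr(real_cvs, "null_medians") <- med
  real_cvs
}

#' Fisher-exact overrepresentation of functional terms
#'
#' For each term, tests whether the subset contains more term genes than
#' expected from the background using the one-sided (overrepresentation)
#' Fisher exact test, i.e. the upper hypergeometric tail of the 2x2 table.
#' No multiple-testing correction is applied by default, mirroring raw
#' threshold use; Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param subset Character vector of genes of interest; must be contained in
#'   `background`.
#' @param background Character vector: the background gene universe.
#' @param annotation Term annotation: data.frame with columns `term_id`,
#'   `gene_id`, or a named list term -> gene vector.
#' @param alpha Significance threshold on the (optionally adjusted) p-value,
#'   default 0.01.
#' @param insignificant_above Report-time mask: terms with p above this are
#'   additionally flagged (`masked` column), default 0.001.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by p: term_id, k_in_subset, n_subset,
#'   K_in_background, N_background, p_value, significant, masked.
#' @export
fisher_enrichment <- function(subset, background, annotation, alpha = 0.01,
                              insignificant_above = 0.001,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  subset <- unique(subset); background <- unique(background)
  if (length(setdiff(subset, background)))
    .stopf("subset contains genes absent from the background: %s",
           setdiff(subset, background)[1L])
  if (is.data.frame(annotation)) {
    stopifnot(all(c("term_id", "gene_id") %in% names(annotation)))
    annotation <- split(annotation$gene_id, annotation$term_id)
  }
  N <- length(background); n <- length(subset)
  res <- lapply(names(annotation), function(term) {
    term_genes <- intersect(unique(annotation[[term]]), background)
    K <- length(term_genes)
    k <- length(intersect(term_genes, subset))
    # one-sided overrepresentation: P(X >= k), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k_in_subset = k, n_subset = n,
               K_in_background = K, N_background = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value <= alpha
  out$masked <- out$p_value > insignificant_above
  out[order(out$p_value), , drop = FALSE]
}
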