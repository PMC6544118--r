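#' Gene intervals between adjacent cistrons
#'
#' The gene interval is the number of nucleotides strictly between the CDS
#' end (past the stop codon) of a cistron and the CDS start of the next
#' cistron downstream on the same transcript: 0 for back-to-back genes,
#' negative for overlapping ORFs. On-disk coordinates are 1-based inclusive
#' (GFF); the computation converts to 0-based half-open, so for a + strand
#' pair the interval is `start0(next) - end0(prev)` and the mirrored form is
#' used on the - strand. The convention (stop codon inside the upstream CDS,
#' 0 = abutting) matters: +/-3 nt offsets are common across tools.
#'
#' @param operons Long operon data.frame in transcript order (rank column),
#'   as produced by [read_operon_annotation()] / [order_operons()].
#' @param annotation Gene annotation data.frame (1-based inclusive start/end).
#' @return data.frame: operon_id, upstream_gene, downstream_gene,
#'   interval_nt.
#' @export
gene_intervals <- function(operons, annotation) {
  miss <- setdiff(operons$gene_id, annotation$gene_id)
  if (length(miss)) .stopf("missing coordinates for gene: %s", miss[1L])
  idx <- match(operons$gene_id, annotation$gene_id)
  start0 <- annotation$start[idx] - 1L
  end0 <- annotation$end[idx]
  strand <- annotation$strand[idx]
  ord <- order(operons$operon_id, operons$rank)
  op <- operons$operon_id[ord]; g <- operons$gene_id[ord]
  start0 <- start0[ord]; end0 <- end0[ord]; strand <- strand[ord]
  n <- length(g)
  if (n < 2L)
    return(data.frame(operon_id = character(), upstream_gene = character(),
                      downstream_gene = character(), interval_nt = integer(),
                      stringsAsFactors = FALSE))
  i <- which(op[-1L] == op[-n])          # adjacent pairs within an operon
  up <- i; dn <- i + 1L
  interval <- ifelse(strand[up] == "+",
                     start0[dn] - end0[up],
                     start0[up] - end0[dn])
  data.frame(operon_id = op[up], upstream_gene = g[up],
             downstream_gene = g[dn], interval_nt = as.integer(interval),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify an intergenic interval by the 70S-scanning footprint
#'
#' A terminating 70S ribosome covers about 40 nt of mRNA; when the next
#' initiation site lies nearer than the footprint, termination and
#' downstream initiation cannot be independent and translation proceeds by
#' 70S scanning, which couples the cistrons' expression. Coupled if
#' `interval_nt < footprint_nt` (strict); overlapping ORFs (negative
#' intervals) are maximally proximal and hence coupled.
#'
#' @param interval_nt Integer vector of gene intervals.
#' @param footprint_nt Ribosome footprint in nucleotides, default 40.
#' @return Character vector: `"coupled_70S_scanning"` or
#'   `"independent_initiation"`.
#' @export
scanning_class <- function(interval_nt, footprint_nt = 40L) {
  ifelse(interval_nt < footprint_nt,
         "coupled_70S_scanning", "independent_initiation")
}

#' Linear regression of operon CV on operon size
#'
#' Ordinary least squares of `cv_percent` on `n_quantified` with the
#' two-sided slope p-value, used to test length dependence of stoichiometry
#' control within an operon class.
#'
#' @param records `operon_cv_records` data.frame.
#' @param labels Optional data.frame operon_id/label (from
#'   [classify_operons()]) when `class_filter` is used.
#' @param class_filter Optional class label (`"Complex"`/`"Pathway"`) to
#'   restrict the records.
#' @return List of class `opstoich_regression`: slope, intercept, p_value,
#'   r_squared, n.
#' @export
cv_vs_size_regression <- function(records, labels = NULL, class_filter = NULL) {
  if (!is.null(class_filter)) {
    if (is.null(labels)) .stopf("class_filter requires operon labels")
    keep <- labels$operon_id[labels$label == class_filter]
    records <- records[records$operon_id %in% keep, , drop = FALSE]
  }
  .ols(records$n_quantified, records$cv_percent)
}

.ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) .stopf("regression requires >= 3 records")
  if (stats::var(x) == 0) .stopf("degenerate predictor: no variation")
  if (stats::var(y) == 0) {          # flat response: no slope, no evidence
    out <- list(slope = 0, intercept = y[1L], p_value = 1, r_squared = 0,
                n = length(x))
    class(out) <- "opstoich_regression"
    return(out)
  }
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # exact fits are legitimate inputs
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              p_value = s$coefficients[2L, 4L],
              r_squared = s$r.squared,
              n = length(x))
  class(out) <- "opstoich_regression"
  out
}

#' @export
print.opstoich_regression <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g (p = %.3g), intercept = %.4g, r^2 = %.4f, n = %d\n",
              x$slope, x$p_value, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' RNA-protein correlation on shared genes
#'
#' Pearson correlation of log10 RNA vs log10 protein abundance on genes with
#' positive values in both tables; the squared correlation is the headline
#' statistic. Values spanning orders of magnitude motivate the log scale;
#' zeros are excluded.
#'
#' @param rna,protein Value tables (data.frame key/value or named vector).
#' @param genes Optional gene subset.
#' @return `opstoich_regression` (slope/intercept of log-protein on
#'   log-RNA, `r_squared`, two-sided p of the slope).
#' @export
rna_protein_correlation <- function(rna, protein, genes = NULL) {
  r <- .as_named_values(rna); p <- .as_named_values(protein)
  shared <- intersect(names(r)[r > 0], names(p)[p > 0])
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3L)
    .stopf("RNA-protein correlation requires >= 3 shared positive genes (got %d)",
           length(shared))
  .ols(log10(r[shared]), log10(p[shared]))
}

#' Pairwise Mann-Whitney matrix across size groups
#'
#' Symmetric matrix of two-sided Mann-Whitney U p-values between every pair
#' of CV groups (e.g. operon size groups within one class). Groups with
#' fewer than 3 values are masked (`NA` row/column) with a warning; the
#' diagonal is `NA`.
#'
#' @param groups Named list of numeric vectors.
#' @return Numeric matrix of p-values with group names on both dimensions.
#' @export
pairwise_mwu_matrix <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  gn <- names(groups)
  ok <- vapply(groups, length, 1L) >= 3L
  if (any(!ok))
    warning(sprintf("group(s) with < 3 values masked: %s",
                    paste(gn[!ok], collapse = ", ")))
  m <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in seq_along(gn)) for (j in seq_along(gn)) {
    if (i < j && ok[i] && ok[j]) {
      p <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                               exact = FALSE)$p.value)
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}
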