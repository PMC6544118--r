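#' Select the calibration set of abundant reference proteins
#'
#' Ranks reference genes by the mean of their three prior copy-number
#' estimates (iBAQ, emPAI, APEX), takes the `top_n` most abundant, and
#' intersects with the genes having a positive measured intensity. The top
#' fraction of the proteome carries most of the protein mass, so these
#' proteins anchor the intensity-to-copies conversion.
#'
#' Genes with a zero or missing value on any scale are excluded (the
#' geometric-mean formula is undefined there); ties in the ranking statistic
#' are broken by gene name.
#'
#' @param reference A reference_abundance data.frame (see
#'   [read_quant_table()]).
#' @param quant A value table of intensities (data.frame key/value or named
#'   vector).
#' @param top_n Number of most abundant reference genes to consider.
#' @return A data.frame with columns gene_name, B, P, A, D (prior copies and
#'   measured intensity), with attributes `n_matched` and `top_n_requested`.
#' @export
select_calibration_set <- function(reference, quant, top_n = 500L) {
  stopifnot(top_n >= 1)
  d <- .as_named_values(quant)
  ref <- reference[stats::complete.cases(
    reference[, c("copies_iBAQ", "copies_emPAI", "copies_APEX")]), ]
  ok <- ref$copies_iBAQ > 0 & ref$copies_emPAI > 0 & ref$copies_APEX > 0
  n_excluded <- sum(!ok)
  if (n_excluded)
    message(sprintf("calibration: excluded %d reference genes with non-positive copies",
                    n_excluded))
  ref <- ref[ok, ]
  score <- (ref$copies_iBAQ + ref$copies_emPAI + ref$copies_APEX) / 3
  ref <- ref[order(-score, ref$gene_name), ]
  ref <- utils::head(ref, top_n)
  d <- d[d > 0 & !is.na(d)]
  sel <- ref$gene_name %in% names(d)
  if (!any(sel)) .stopf("calibration error: no overlap between top-%d reference genes and quantified genes", top_n)
  ref <- ref[sel, ]
  out <- data.frame(gene_name = ref$gene_name,
                    B = ref$copies_iBAQ, P = ref$copies_emPAI,
                    A = ref$copies_APEX, D = as.numeric(d[ref$gene_name]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_matched") <- nrow(out)
  attr(out, "top_n_requested") <- as.integer(top_n)
  out
}

#' Intensity-to-copies conversion coefficient
#'
#' Computes the coefficient `k` converting measured intensities to protein
#' copies per cell as the ratio of geometric means over the matched
#' calibration proteins:
#' \deqn{k = \frac{\mathrm{geo.mean}_i\,(B_i+P_i+A_i)/3}{\mathrm{geo.mean}_i\, D_i}}
#' where \eqn{B_i, P_i, A_i} are a protein's prior copy numbers on the three
#' label-free scales and \eqn{D_i} its measured intensity. Accumulation is
#' done in log space for numerical stability at hundreds of proteins.
#'
#' @param matched Output of [select_calibration_set()] (or any data.frame
#'   with positive columns B, P, A, D).
#' @return An object of class `conversion_coefficient`: list with `k`,
#'   `n_matched`, `top_n_requested`.
#' @examples
#' m <- data.frame(gene_name = c("a", "b"), B = 3, P = 3, A = 3, D = c(1, 4))
#' conversion_coefficient(m)$k  # 1.5
#' @export
conversion_coefficient <- function(matched) {
  stopifnot(all(c("B", "P", "A", "D") %in% names(matched)))
  if (nrow(matched) < 1L) .stopf("calibration error: empty matched set")
  with(matched, {
    if (any(B <= 0 | P <= 0 | A <= 0 | D <= 0))
      .stopf("conversion_coefficient: all of B, P, A, D must be positive")
  })
  num <- mean(log((matched$B + matched$P + matched$A) / 3))
  den <- mean(log(matched$D))
  out <- list(k = exp(num - den),
              n_matched = nrow(matched),
              top_n_requested = attr(matched, "top_n_requested") %||% nrow(matched))
  class(out) <- "conversion_coefficient"
  out
}

#' @export
print.conversion_coefficient <- function(x, ...) {
  cat(sprintf("Intensity-to-copies conversion: k = %.6g (from %d matched of top %d reference proteins)\n",
              x$k, x$n_matched, x$top_n_requested))
  invisible(x)
}

#' Convert intensities to protein copies per cell
#'
#' Applies `copies = k * D` to every entry of an intensity table. All
#' pairwise abundance ratios are preserved exactly.
#'
#' @param k A `conversion_coefficient` object or a positive scalar.
#' @param quant A value table of intensities.
#' @return A value table with `value_kind = "copies"`.
#' @export
to_copy_number <- function(k, quant) {
  if (inherits(k, "conversion_coefficient")) k <- k$k
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    .stopf("'k' must be a positive scalar")
  d <- .as_named_values(quant)
  value_table(d * k, value_kind = "copies")
}

#' Replicate reproducibility of log-scale quantification
#'
#' Pearson correlation of log10 abundances across two replicates on shared
#' keys, overall and within low/mid/high abundance sections split at the
#' given log10 bounds (section membership by the mean log10 abundance of the
#' two replicates). Sections with fewer than 3 points report `NA`.
#'
#' @param rep1,rep2 Value tables (data.frame key/value or named vector).
#' @param bounds_log10 Two increasing log10 cut points, default `c(2, 3.5)`.
#' @return List of class `reproducibility_summary` with `r_all`, `r_low`,
#'   `r_mid`, `r_high`, `section_bounds_log10`, `n_shared`.
#' @export
replicate_reproducibility <- function(rep1, rep2, bounds_log10 = c(2, 3.5)) {
  stopifnot(length(bounds_log10) == 2L, diff(bounds_log10) > 0)
  a <- .as_named_values(rep1); b <- .as_named_values(rep2)
  shared <- intersect(names(a)[a > 0], names(b)[b > 0])
  if (length(shared) < 3L)
    .stopf("reproducibility QC requires >= 3 shared quantified keys (got %d)",
           length(shared))
  la <- log10(a[shared]); lb <- log10(b[shared])
  m <- (la + lb) / 2
  sec <- cut(m, breaks = c(-Inf, bounds_log10, Inf),
             labels = c("low", "mid", "high"))
  r_of <- function(i) if (sum(i) >= 3L) stats::cor(la[i], lb[i]) else NA_real_
  out <- list(r_all = stats::cor(la, lb),
              r_low = r_of(sec == "low"),
              r_mid = r_of(sec == "mid"),
              r_high = r_of(sec == "high"),
              section_bounds_log10 = bounds_log10,
              n_shared = length(shared))
  class(out) <- "reproducibility_summary"
  out
}

#' @export
print.reproducibility_summary <- function(x, ...) {
  cat(sprintf("Replicate reproducibility (n = %d shared): R = %.4f\n",
              x$n_shared, x$r_all))
  cat(sprintf("  sections (log10 bounds %.1f, %.1f): r_low = %.3f, r_mid = %.3f, r_high = %.3f\n",
              x$section_bounds_log10[1], x$section_bounds_log10[2],
              x$r_low, x$r_mid, x$r_high))
  invisible(x)
}
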