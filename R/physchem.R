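# Physicochemical sequence features. The constant tables (Kyte-Doolittle
# hydropathy scale, Bjellqvist-style pKa set with residue-specific terminal
# pKas, Guruprasad dipeptide instability weights) are shipped as TSVs under
# inst/extdata so that tests can apply them independently of this code.

.physchem_env <- new.env(parent = emptyenv())

.physchem_tables <- function() {
  if (is.null(.physchem_env$kd)) {
    kd <- .read_tsv(system.file("extdata", "kyte_doolittle.tsv",
                                package = "opstoich"))
    .physchem_env$kd <- stats::setNames(kd$hydropathy, kd$residue)
    pka <- .read_tsv(system.file("extdata", "pka_set.tsv",
                                 package = "opstoich"))
    .physchem_env$pka <- pka
    w <- .read_tsv(system.file("extdata", "instability_weights.tsv",
                               package = "opstoich"))
    m <- as.matrix(w[, -1L])
    rownames(m) <- w$first
    .physchem_env$diwv <- m
  }
  .physchem_env
}

.canonical_aa <- function(seq, skip_ambiguous = FALSE) {
  if (inherits(seq, "AAString") || inherits(seq, "AAStringSet"))
    seq <- as.character(seq)
  .assert_string(seq, "seq")
  res <- strsplit(toupper(seq), "")[[1L]]
  canon <- names(.physchem_tables()$kd)
  bad <- setdiff(res, canon)
  if (length(bad)) {
    if (skip_ambiguous) res <- res[res %in% canon]
    else .stopf("non-canonical residue(s) in sequence: %s",
                paste(unique(bad), collapse = ","))
  }
  if (length(res) == 0L) .stopf("sequence has no canonical residues")
  res
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a protein sequence;
#' positive values indicate hydrophobic proteins. Bounded by the scale
#' extremes `[-4.5, 4.5]` and invariant to residue order.
#'
#' @param seq Amino-acid sequence (string or `AAString`).
#' @param skip_ambiguous Drop ambiguous residues (B, Z, X, U) from the mean
#'   instead of failing; default `FALSE`.
#' @return GRAVY score.
#' @examples gravy("AG")  # 0.7
#' @export
gravy <- function(seq, skip_ambiguous = FALSE) {
  res <- .canonical_aa(seq, skip_ambiguous)
  mean(.physchem_tables()$kd[res])
}

# net charge of a peptide at a given pH under the tabulated pKa set;
# residue-specific terminal pKas override the generic termini when present
.net_charge <- function(res, pH) {
  pka <- .physchem_tables()$pka
  pk <- stats::setNames(pka$pka, pka$group)
  cnt <- table(res)
  nterm <- pk[paste0("Nterm_", res[1L])]
  if (is.na(nterm)) nterm <- pk[["Nterm"]]
  cterm <- pk[paste0("Cterm_", res[length(res)])]
  if (is.na(cterm)) cterm <- pk[["Cterm"]]
  pos <- 1 / (1 + 10^(pH - nterm))
  for (a in c("K", "R", "H"))
    if (!is.na(cnt[a])) pos <- pos + cnt[[a]] / (1 + 10^(pH - pk[[a]]))
  neg <- 1 / (1 + 10^(cterm - pH))
  for (a in c("D", "E", "C", "Y"))
    if (!is.na(cnt[a])) neg <- neg + cnt[[a]] / (1 + 10^(pk[[a]] - pH))
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which the peptide's net charge (N-terminus, C-terminus and
#' D/E/C/Y/H/K/R side chains under the shipped Bjellqvist-style pKa set,
#' including residue-specific terminal pKas) crosses zero, found by
#' bisection over pH 0-14 to well below 0.01 pH units.
#'
#' @inheritParams gravy
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, skip_ambiguous = FALSE) {
  res <- .canonical_aa(seq, skip_ambiguous)
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.net_charge(res, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' Dipeptide-weight instability score: `(10 / L) * sum` of the tabulated
#' instability weights over the `L - 1` overlapping dipeptides. Values above
#' 40 conventionally indicate an unstable protein. Order-dependent (the
#' weight matrix is asymmetric).
#'
#' @inheritParams gravy
#' @return Instability index.
#' @export
instability_index <- function(seq, skip_ambiguous = FALSE) {
  res <- .canonical_aa(seq, skip_ambiguous)
  L <- length(res)
  if (L < 2L) .stopf("instability index requires length >= 2")
  w <- .physchem_tables()$diwv
  idx <- cbind(match(res[-L], rownames(w)), match(res[-1L], colnames(w)))
  (10 / L) * sum(w[idx])
}

#' Physicochemical feature table for a set of proteins
#'
#' @param seqs Named character vector or `Biostrings::AAStringSet`.
#' @param skip_ambiguous See [gravy()].
#' @return data.frame: protein_id, length_aa, gravy, isoelectric_point,
#'   instability_index.
#' @export
physchem_features <- function(seqs, skip_ambiguous = FALSE) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) .stopf("'seqs' must be named")
  data.frame(
    protein_id = names(seqs),
    length_aa = nchar(seqs),
    gravy = vapply(seqs, gravy, 0, skip_ambiguous = skip_ambiguous),
    isoelectric_point = vapply(seqs, isoelectric_point, 0,
                               skip_ambiguous = skip_ambiguous),
    instability_index = vapply(seqs, instability_index, 0,
                               skip_ambiguous = skip_ambiguous),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare feature distributions of two protein sets
#'
#' Two-sided Mann-Whitney U test per feature between e.g. the MS-quantified
#' and translated-but-unquantified protein sets, with the direction of the
#' shift summarised by the median difference (second set minus first).
#'
#' @param quantified,unquantified Feature data.frames from
#'   [physchem_features()] (>= 3 records each).
#' @return data.frame: feature, p_value, median_quantified,
#'   median_unquantified, median_shift.
#' @export
compare_feature_distributions <- function(quantified, unquantified) {
  feats <- c("length_aa", "gravy", "isoelectric_point", "instability_index")
  if (nrow(quantified) < 3L || nrow(unquantified) < 3L)
    .stopf("each set needs >= 3 records")
  res <- lapply(feats, function(f) {
    p <- suppressWarnings(stats::wilcox.test(quantified[[f]],
                                             unquantified[[f]],
                                             exact = FALSE)$p.value)
    if (is.nan(p)) p <- 1     # fully tied samples carry no evidence
    mq <- stats::median(quantified[[f]]); mu <- stats::median(unquantified[[f]])
    data.frame(feature = f, p_value = p, median_quantified = mq,
               median_unquantified = mu, median_shift = mu - mq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
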