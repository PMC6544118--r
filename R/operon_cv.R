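#' Within-operon coefficient of variation
#'
#' The dispersion statistic for operon stoichiometry: the sample standard
#' deviation (n - 1 denominator) of the member proteins' abundances divided
#' by their arithmetic mean, expressed in percent. A perfectly
#' stoichiometric operon has CV 0; the statistic is invariant to any
#' positive rescaling of the abundances, so intensities and copies per cell
#' give identical CVs.
#'
#' @param values Numeric vector of non-negative abundances, length >= 2.
#' @return CV in percent.
#' @examples
#' operon_cv(c(1, 2, 3))  # 50
#' operon_cv(c(2, 4))     # 47.1405
#' @export
operon_cv <- function(values) {
  if (length(values) < 2L)
    .stopf("CV is undefined for fewer than 2 values")
  if (any(is.na(values) | values < 0))
    .stopf("CV requires non-negative, non-missing values")
  m <- mean(values)
  if (m <= 0) .stopf("CV undefined: mean is zero")
  100 * stats::sd(values) / m
}

#' Compute within-operon CVs over an abundance table
#'
#' One CV record per operon with at least two quantified member genes.
#' Genes absent from the abundance table are dropped, not zero-filled, and
#' by default the operon's size group follows the number of quantified
#' genes (`group_by = "quantified"`), not the annotated gene count.
#'
#' @param operons Long operon data.frame (operon_id, gene_id, ...) as
#'   returned by [read_operon_annotation()] or [simulate_genome()].
#' @param abundances Value table (data.frame key/value or named vector)
#'   keyed by gene.
#' @param group_by Size-group definition: `"quantified"` (default) or
#'   `"annotated"`.
#' @param source Label stored in the `source` column, default `"real"`.
#' @return data.frame of class `operon_cv_records`: operon_id, n_quantified,
#'   cv_percent, size_group, source; skipped-operon count in attribute
#'   `n_skipped`.
#' @export
compute_operon_cvs <- function(operons, abundances,
                               group_by = c("quantified", "annotated"),
                               source = "real") {
  group_by <- match.arg(group_by)
  vals <- .as_named_values(abundances)
  ops <- operons[operons$gene_id %in% names(vals), , drop = FALSE]
  ops$value <- as.numeric(vals[ops$gene_id])
  cnt <- table(ops$operon_id)
  keep <- names(cnt)[cnt >= 2L]
  n_skipped <- length(unique(operons$operon_id)) - length(keep)
  ops <- ops[ops$operon_id %in% keep, , drop = FALSE]
  if (nrow(ops) == 0L) {
    out <- data.frame(operon_id = character(), n_quantified = integer(),
                      cv_percent = numeric(), size_group = character(),
                      source = character(), stringsAsFactors = FALSE)
  } else {
    f <- factor(ops$operon_id)
    n <- as.integer(tapply(ops$value, f, length))
    mu <- as.numeric(tapply(ops$value, f, mean))
    sdv <- as.numeric(tapply(ops$value, f, stats::sd))
    if (any(mu <= 0)) {
      drop <- mu <= 0
      message(sprintf("compute_operon_cvs: dropped %d operon(s) with zero mean abundance",
                      sum(drop)))
      n <- n[!drop]; mu <- mu[!drop]; sdv <- sdv[!drop]
      lev <- levels(f)[!drop]
    } else lev <- levels(f)
    size_n <- if (group_by == "quantified") n else {
      ann_cnt <- table(operons$operon_id)
      as.integer(ann_cnt[lev])
    }
    out <- data.frame(operon_id = lev, n_quantified = n,
                      cv_percent = 100 * sdv / mu,
                      size_group = .size_group(size_n),
                      source = source, stringsAsFactors = FALSE,
                      row.names = NULL)
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("operon_cv_records", "data.frame")
  out
}

#' Permutation null for within-operon CVs
#'
#' Builds the randomized negative control by reshuffling the quantified
#' protein abundances of all polycistronic operons (annotated size >= 2)
#' jointly over those same gene slots, then recomputing per-operon CVs for
#' each permutation. The quantified/unquantified pattern is preserved: only
#' slots that carried a value receive one, so the null has exactly the same
#' operon sizes as the real data, and each permutation preserves the
#' multiset of values exactly.
#'
#' @param operons Long operon data.frame.
#' @param abundances Value table keyed by gene.
#' @param n_permutations Number of reshuffles (default 1000).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @param group_by Passed through to size-group assignment (see
#'   [compute_operon_cvs()]).
#' @return `operon_cv_records` data.frame with `source = "randomized"` and a
#'   `permutation_index` column; the seed is stored as attribute `seed`.
#' @export
randomize_null <- function(operons, abundances, n_permutations = 1000L,
                           seed = 1L, group_by = c("quantified", "annotated")) {
  group_by <- match.arg(group_by)
  if (!is.numeric(n_permutations) || n_permutations < 1L)
    .stopf("'n_permutations' must be >= 1")
  n_permutations <- as.integer(n_permutations)
  vals <- .as_named_values(abundances)

  ann_cnt <- table(operons$operon_id)
  poly <- names(ann_cnt)[ann_cnt >= 2L]
  slots <- operons[operons$operon_id %in% poly &
                     operons$gene_id %in% names(vals), , drop = FALSE]
  if (nrow(slots) < 2L)
    .stopf("no quantified genes in polycistronic operons to reshuffle")
  v <- as.numeric(vals[slots$gene_id])
  f <- factor(slots$operon_id)
  nper <- as.integer(table(f))
  keep <- nper >= 2L            # operons contributing CV records
  lev <- levels(f)[keep]
  nk <- nper[keep]
  size_n <- if (group_by == "quantified") nk else as.integer(ann_cnt[lev])
  sg <- .size_group(size_n)

  m <- length(v)
  res <- .with_seed(seed, {
    lapply(seq_len(n_permutations), function(p) {
      vp <- v[sample.int(m)]
      s1 <- rowsum(vp, f)[, 1L]
      s2 <- rowsum(vp * vp, f)[, 1L]
      s1 <- s1[keep]; s2 <- s2[keep]
      mu <- s1 / nk
      varv <- pmax(0, (s2 - s1 * s1 / nk) / (nk - 1L))
      data.frame(operon_id = lev, n_quantified = nk,
                 cv_percent = 100 * sqrt(varv) / mu,
                 size_group = sg, source = "randomized",
                 permutation_index = p, stringsAsFactors = FALSE,
                 row.names = NULL)
    })
  })
  out <- do.call(rbind, res)
  ok <- is.finite(out$cv_percent)
  out <- out[ok, , drop = FALSE]
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("operon_cv_records", "data.frame")
  out
}

#' Two-sample (or k-sample) distribution comparison
#'
#' Thin, uniform wrapper over the two-sided Mann-Whitney U,
#' Kolmogorov-Smirnov and Kruskal-Wallis tests used throughout the
#' analysis.
#'
#' @param a Numeric sample; for `"kruskal_wallis"` may be a list of >= 2
#'   samples (then `b` is ignored).
#' @param b Second numeric sample.
#' @param test One of `"mann_whitney_u"`, `"kolmogorov_smirnov"`,
#'   `"kruskal_wallis"`.
#' @return List of class `distribution_comparison`: test, statistic,
#'   p_value, n_a, n_b, sidedness.
#' @export
compare_distributions <- function(a, b = NULL,
                                  test = c("mann_whitney_u",
                                           "kolmogorov_smirnov",
                                           "kruskal_wallis")) {
  test <- match.arg(test)
  if (test == "kruskal_wallis" && is.list(a)) {
    groups <- a
  } else {
    if (is.null(b)) .stopf("two samples required for %s", test)
    groups <- list(a, b)
  }
  if (any(vapply(groups, length, 1L) < 3L))
    .stopf("each sample needs >= 3 observations")
  res <- switch(test,
    mann_whitney_u = {
      h <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]],
                                               alternative = "two.sided",
                                               exact = FALSE))
      list(stat = unname(h$statistic), p = h$p.value)
    },
    kolmogorov_smirnov = {
      h <- suppressWarnings(stats::ks.test(groups[[1L]], groups[[2L]],
                                           alternative = "two.sided"))
      list(stat = unname(h$statistic), p = h$p.value)
    },
    kruskal_wallis = {
      h <- stats::kruskal.test(groups)
      list(stat = unname(h$statistic), p = h$p.value)
    })
  out <- list(test = test, statistic = res$stat, p_value = res$p,
              n_a = length(groups[[1L]]),
              n_b = if (length(groups) > 1L) length(groups[[2L]]) else NA_integer_,
              sidedness = "two_sided")
  class(out) <- "distribution_comparison"
  out
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("%s (two-sided): statistic = %.4g, p = %.4g (n = %s, %s)\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
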