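#' Fit the operon stoichiometry analysis
#'
#' The package's central entry point: runs the full analysis on a dataset
#' and returns a fitted `opstoich` object. Stages: identification-confidence
#' filtering; replicate-reproducibility QC; calibration of intensities to
#' copies per cell against the prior abundance scales; within-operon CVs and
#' the reshuffled permutation null; Complex/Pathway classification and the
#' null-median split; class and size comparisons (Mann-Whitney,
#' Kolmogorov-Smirnov); gene intervals with 70S-scanning classification;
#' CV-vs-size regressions; RNA-protein correlation; branch-free enzyme
#' kinetics concordance; physicochemical comparison of quantified vs
#' unquantified proteins; coverage summary. Optional inputs (`rna`,
#' `kinetics`/`graph`, `proteins`, `terms`) switch their stages on.
#'
#' @param data A list (e.g. from [simulate_operon_dataset()]) with
#'   components `quant` (protein_quant data.frame), `operons`, `annotation`,
#'   `reference`, and optionally `membership`, `rna`, `kinetics`, `graph`,
#'   `proteins`, `terms`.
#' @param top_n Calibration set size, default 500.
#' @param n_permutations Permutations for the null, default 1000.
#' @param seed Seed for the permutation null, default 1.
#' @param filter_mode Identification filter, `"stringent"` (default) or
#'   `"relaxed"`.
#' @param footprint_nt Ribosome footprint for interval classification,
#'   default 40.
#' @param alpha Enrichment significance threshold, default 0.01.
#' @param group_by Size-group definition, see [compute_operon_cvs()].
#' @param verbose Emit per-stage messages, default TRUE.
#' @return Object of class `opstoich`; see [print.opstoich()],
#'   [summary.opstoich()], [coef.opstoich()], [plot.opstoich()].
#' @examples
#' \donttest{
#' cfg <- simulation_config(seed = 7, n_operons = 60)
#' fit <- operon_stoichiometry(simulate_operon_dataset(cfg),
#'                             n_permutations = 50, verbose = FALSE)
#' fit
#' }
#' @export
operon_stoichiometry <- function(data, top_n = 500L, n_permutations = 1000L,
                                 seed = 1L,
                                 filter_mode = c("stringent", "relaxed"),
                                 footprint_nt = 40L, alpha = 0.01,
                                 group_by = c("quantified", "annotated"),
                                 verbose = TRUE) {
  filter_mode <- match.arg(filter_mode)
  group_by <- match.arg(group_by)
  for (need in c("quant", "operons", "annotation", "reference"))
    if (is.null(data[[need]])) .stopf("data lacks required component '%s'", need)
  say <- if (verbose) message else function(...) invisible()
  quiet <- function(expr) withCallingHandlers(expr,
    message = function(m) { if (!verbose) invokeRestart("muffleMessage") })

  fit <- list(call = match.call(), seed = as.integer(seed),
              n_permutations = as.integer(n_permutations),
              filter_mode = filter_mode)

  # -- identification filter and replicate aggregation
  quant <- quiet(filter_confident(data$quant, filter_mode))
  fit$n_quantified_records <- nrow(quant)
  reps <- split(quant, quant$replicate)
  rep_tables <- lapply(reps, function(q)
    stats::setNames(q$intensity, q$gene_name))
  if (length(rep_tables) >= 2L) {
    fit$reproducibility <- tryCatch(
      replicate_reproducibility(rep_tables[[1L]], rep_tables[[2L]]),
      error = function(e) NULL)
  }
  agg <- tapply(quant$intensity, quant$gene_name, mean)
  intensities <- value_table(stats::setNames(as.numeric(agg), names(agg)))
  say(sprintf("quantified genes after %s filter: %d", filter_mode,
              nrow(intensities)))

  # -- calibration to copies per cell
  matched <- quiet(select_calibration_set(data$reference, intensities, top_n))
  fit$k <- conversion_coefficient(matched)
  fit$copies <- to_copy_number(fit$k, intensities)
  say(sprintf("calibration: k = %.4g from %d matched proteins",
              fit$k$k, fit$k$n_matched))

  # -- within-operon CVs and the permutation null
  fit$cv_real <- quiet(compute_operon_cvs(data$operons, fit$copies,
                                          group_by = group_by))
  fit$cv_null <- randomize_null(data$operons, fit$copies,
                                n_permutations = n_permutations, seed = seed,
                                group_by = group_by)
  fit$test_real_vs_null <- list(
    mann_whitney_u = compare_distributions(fit$cv_real$cv_percent,
                                           fit$cv_null$cv_percent,
                                           "mann_whitney_u"),
    kolmogorov_smirnov = compare_distributions(fit$cv_real$cv_percent,
                                               fit$cv_null$cv_percent,
                                               "kolmogorov_smirnov"))
  say(sprintf("CV: %d operons, mean real %.1f%% vs null %.1f%% (MWU p = %.3g)",
              nrow(fit$cv_real), mean(fit$cv_real$cv_percent),
              mean(fit$cv_null$cv_percent),
              fit$test_real_vs_null$mann_whitney_u$p_value))

  # -- classification and the null-median split
  if (!is.null(data$membership)) {
    poly <- names(which(table(data$operons$operon_id) >= 2L))
    fit$labels <- classify_operons(
      data$operons[data$operons$operon_id %in% poly, ], data$membership)
    lab <- stats::setNames(fit$labels$label, fit$labels$operon_id)
    cvl <- fit$cv_real[fit$cv_real$operon_id %in% names(lab), ]
    cvl$label <- lab[cvl$operon_id]
    fit$test_complex_vs_pathway <- tryCatch(
      compare_distributions(cvl$cv_percent[cvl$label == "Complex"],
                            cvl$cv_percent[cvl$label == "Pathway"],
                            "mann_whitney_u"),
      error = function(e) NULL)
    fit$regression <- lapply(
      stats::setNames(nm = c("Complex", "Pathway")),
      function(cl) tryCatch(cv_vs_size_regression(fit$cv_real, fit$labels, cl),
                            error = function(e) NULL))
    fit$mwu_matrix <- lapply(
      stats::setNames(nm = c("Complex", "Pathway")),
      function(cl) {
        r <- cvl[cvl$label == cl, ]
        g <- split(r$cv_percent, factor(r$size_group, .size_group_levels))
        suppressWarnings(pairwise_mwu_matrix(g))
      })
  }
  fit$split <- suppressWarnings(split_by_null_median(fit$cv_real, fit$cv_null))

  # -- functional enrichment of the low-CV subgroups
  if (!is.null(data$terms) && !is.null(fit$labels)) {
    background <- fit$copies$key
    low_ops <- fit$split$operon_id[!is.na(fit$split$subgroup) &
                                     startsWith(fit$split$subgroup, "L")]
    low_genes <- intersect(
      data$operons$gene_id[data$operons$operon_id %in% low_ops], background)
    fit$enrichment <- fisher_enrichment(low_genes, background, data$terms,
                                        alpha = alpha)
  }

  # -- gene intervals and scanning classification
  fit$intervals <- gene_intervals(data$operons, data$annotation)
  fit$intervals$scanning <- scanning_class(fit$intervals$interval_nt,
                                           footprint_nt)
  if (!is.null(fit$labels)) {
    ilab <- stats::setNames(fit$labels$label, fit$labels$operon_id)
    fit$intervals$label <- ilab[fit$intervals$operon_id]
    fit$test_intervals <- tryCatch(
      compare_distributions(
        fit$intervals$interval_nt[fit$intervals$label == "Complex"],
        fit$intervals$interval_nt[fit$intervals$label == "Pathway"],
        "kolmogorov_smirnov"),
      error = function(e) NULL)
  }

  # -- RNA-protein correlation
  if (!is.null(data$rna)) {
    fit$rna_protein <- list(
      all = tryCatch(rna_protein_correlation(data$rna, fit$copies),
                     error = function(e) NULL))
    if (!is.null(fit$labels)) {
      for (cl in c("Complex", "Pathway")) {
        ops_cl <- fit$labels$operon_id[fit$labels$label == cl]
        genes_cl <- data$operons$gene_id[data$operons$operon_id %in% ops_cl]
        fit$rna_protein[[cl]] <- tryCatch(
          rna_protein_correlation(data$rna, fit$copies, genes_cl),
          error = function(e) NULL)
      }
    }
  }

  # -- enzyme kinetics concordance on branch-free candidates
  if (!is.null(data$graph) && !is.null(data$kinetics)) {
    cand <- branch_free_candidates(data$operons, fit$copies, data$graph,
                                   data$kinetics)
    fit$candidates <- cand
    fit$concordance <- concordance_verdicts(cand, data$operons, fit$copies,
                                            data$rna, data$kinetics)
    say(sprintf("enzymes: %d branch-free candidate operons, %d concordant",
                length(cand), sum(fit$concordance$km_abundance_concordant)))
  }

  # -- physicochemical comparison of quantified vs unquantified proteins
  if (!is.null(data$proteins)) {
    seqs <- data$proteins
    if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
    qset <- intersect(names(seqs), fit$copies$key)
    uset <- setdiff(names(seqs), qset)
    if (length(qset) >= 3L && length(uset) >= 3L) {
      fq <- physchem_features(seqs[qset])
      fu <- physchem_features(seqs[uset])
      fit$physchem <- compare_feature_distributions(fq, fu)
    }
  }

  # -- coverage
  fit$coverage <- coverage_summary(fit$copies$key,
                                   data$annotation$gene_id,
                                   operons = data$operons)
  class(fit) <- "opstoich"
  fit
}

#' Quantification coverage summary
#'
#' Fraction of translating genes quantified, overall and restricted to
#' cytosolic proteins when a localization table is supplied, plus the
#' fraction of polycistronic operons with at least one and at least two
#' quantified proteins.
#'
#' @param quant_genes Character vector of quantified gene ids.
#' @param translatome Character vector of translating gene ids.
#' @param localization Optional data.frame gene_id/localization; the
#'   cytosolic fraction is computed over genes with localization
#'   `"cytosolic"`.
#' @param operons Optional long operon data.frame for operon-level coverage.
#' @return List: fraction_quantified, fraction_cytosolic_quantified,
#'   fraction_operons_ge1, fraction_operons_ge2, n_translatome.
#' @export
coverage_summary <- function(quant_genes, translatome, localization = NULL,
                             operons = NULL) {
  translatome <- unique(translatome)
  if (length(translatome) == 0L) .stopf("empty translatome")
  out <- list(fraction_quantified = mean(translatome %in% quant_genes),
              fraction_cytosolic_quantified = NA_real_,
              fraction_operons_ge1 = NA_real_,
              fraction_operons_ge2 = NA_real_,
              n_translatome = length(translatome))
  if (!is.null(localization)) {
    cyt <- intersect(translatome,
                     localization$gene_id[localization$localization == "cytosolic"])
    if (length(cyt)) out$fraction_cytosolic_quantified <- mean(cyt %in% quant_genes)
  }
  if (!is.null(operons)) {
    cnt <- table(operons$operon_id)
    poly <- names(cnt)[cnt >= 2L]
    po <- operons[operons$operon_id %in% poly &
                    operons$operon_id %in%
                    operons$operon_id[operons$gene_id %in% translatome], ]
    qn <- tapply(po$gene_id %in% quant_genes, po$operon_id, sum)
    out$fraction_operons_ge1 <- mean(qn >= 1)
    out$fraction_operons_ge2 <- mean(qn >= 2)
  }
  out
}

#' @export
print.opstoich <- function(x, ...) {
  cat("Operon stoichiometry analysis\n")
  cat(sprintf("  conversion: k = %.4g (%d calibration proteins); %d genes quantified\n",
              x$k$k, x$k$n_matched, nrow(x$copies)))
  cat(sprintf("  within-operon CV: %d operons, mean %.1f%% (null mean %.1f%%, %d permutations)\n",
              nrow(x$cv_real), mean(x$cv_real$cv_percent),
              mean(x$cv_null$cv_percent), x$n_permutations))
  cat(sprintf("  real vs null: MWU p = %.3g, KS p = %.3g\n",
              x$test_real_vs_null$mann_whitney_u$p_value,
              x$test_real_vs_null$kolmogorov_smirnov$p_value))
  if (!is.null(x$test_complex_vs_pathway))
    cat(sprintf("  Complex vs Pathway CV: MWU p = %.3g\n",
                x$test_complex_vs_pathway$p_value))
  if (!is.null(x$test_intervals))
    cat(sprintf("  Complex vs Pathway gene intervals: KS p = %.3g\n",
                x$test_intervals$p_value))
  if (!is.null(x$concordance))
    cat(sprintf("  kinetics concordance: %d/%d candidate operons concordant\n",
                sum(x$concordance$km_abundance_concordant),
                nrow(x$concordance)))
  invisible(x)
}

#' @export
summary.opstoich <- function(object, ...) {
  print(object)
  cat("\nCV by size group (real | null medians):\n")
  for (g in .size_group_levels) {
    r <- object$cv_real$cv_percent[object$cv_real$size_group == g]
    n <- object$cv_null$cv_percent[object$cv_null$size_group == g]
    if (length(r))
      cat(sprintf("  %-5s n = %3d: %7.2f%% | %7.2f%%\n", g, length(r),
                  stats::median(r), stats::median(n)))
  }
  if (!is.null(object$regression)) {
    cat("\nCV vs operon size regressions:\n")
    for (cl in names(object$regression)) {
      r <- object$regression[[cl]]
      if (!is.null(r))
        cat(sprintf("  %-8s slope = %.3f (p = %.3g, n = %d)\n", cl,
                    r$slope, r$p_value, r$n))
    }
  }
  if (!is.null(object$rna_protein)) {
    cat("\nRNA-protein correlation (r^2):\n")
    for (cl in names(object$rna_protein)) {
      r <- object$rna_protein[[cl]]
      if (!is.null(r)) cat(sprintf("  %-8s %.4f\n", cl, r$r_squared))
    }
  }
  if (!is.null(object$coverage))
    cat(sprintf("\nCoverage: %.1f%% of %d annotated genes quantified; %.1f%% of polycistronic operons with >= 2 quantified proteins\n",
                100 * object$coverage$fraction_quantified,
                object$coverage$n_translatome,
                100 * object$coverage$fraction_operons_ge2))
  invisible(object)
}

#' Extract the fitted conversion coefficient
#'
#' @param object An `opstoich` fit.
#' @param ... Unused.
#' @return Named numeric: `k`.
#' @export
coef.opstoich <- function(object, ...) c(k = object$k$k)

#' Diagnostic plots for an opstoich fit
#'
#' Left: within-operon CV distributions by size group, real against the
#' permutation null. Right: gene-interval distributions of Complex vs
#' Pathway operons with the ribosome-footprint threshold.
#'
#' @param x An `opstoich` fit.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.opstoich <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  d <- rbind(
    data.frame(cv = x$cv_real$cv_percent,
               grp = paste0(x$cv_real$size_group, "\nreal")),
    data.frame(cv = x$cv_null$cv_percent,
               grp = paste0(x$cv_null$size_group, "\nnull")))
  graphics::boxplot(cv ~ grp, data = d, ylab = "within-operon CV (%)",
                    xlab = "", las = 2, ...)
  if (!is.null(x$intervals$label)) {
    ic <- x$intervals$interval_nt[x$intervals$label == "Complex"]
    ip <- x$intervals$interval_nt[x$intervals$label == "Pathway"]
    rng <- range(c(ic, ip), finite = TRUE)
    graphics::hist(ip, breaks = 30, col = grDevices::adjustcolor("tomato", 0.5),
                   xlim = rng, main = "gene intervals",
                   xlab = "interval (nt)")
    graphics::hist(ic, breaks = 30, col = grDevices::adjustcolor("steelblue", 0.5),
                   add = TRUE)
    graphics::abline(v = 40, lty = 2)
    graphics::legend("topright", fill = c("steelblue", "tomato"),
                     legend = c("Complex", "Pathway"), bty = "n")
  }
  invisible(x)
}
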