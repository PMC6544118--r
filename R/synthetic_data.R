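#' Configuration for the synthetic operon proteome generator
#'
#' Defines an E. coli-like study: a single contig carrying multi-gene
#' operons, per-class expression regimes, log-normal measurement noise on
#' three correlated prior abundance scales plus the measured intensities,
#' abundance-dependent detection dropout, class-dependent intergenic
#' intervals and enzyme kinetics tied to protein abundance.
#'
#' Expression regimes: `stoichiometric` draws every cistron from the operon
#' base level with within-operon log-normal noise; `staircase` multiplies the
#' base by `staircase_decay^(rank-1)`, the decaying-expression pattern of
#' pathway operons; `independent` draws each cistron independently from the
#' between-operon distribution.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_operons Number of operons, default 300.
#' @param size_distribution Named probabilities over operon sizes
#'   `c("1", "2", "3", "4", "5plus")`; `"5plus"` samples 5-8 genes.
#' @param fraction_complex Probability a polycistronic operon is a Complex
#'   operon, default 0.4.
#' @param regime_per_class Named map class -> regime, default
#'   `c(Complex = "stoichiometric", Pathway = "staircase")`.
#' @param staircase_decay Per-cistron multiplicative retention in (0, 1],
#'   default 0.5.
#' @param between_operon_log10_sd Log10 sd of operon base abundance,
#'   default 1.0.
#' @param within_noise_log10_sd Within-operon log10 noise, default 0.1.
#' @param measurement_noise_log10_sd Log10 measurement noise applied to the
#'   intensity and prior-scale tables, default 0.05.
#' @param rna_noise_log10_sd Log10 noise of per-gene RNA around the operon
#'   transcript level, default 0.05.
#' @param mean_copies_log10 Mean log10 copies per cell, default 3.
#' @param k_true Planted intensity-to-copies coefficient, default 50.
#' @param interval_params Named list class -> c(mean_nt, sd_nt) of
#'   within-operon intergenic intervals; Complex operons sit nearly
#'   back-to-back, Pathway genes lie further apart.
#' @param interval_floor_nt Truncation floor allowing overlapping ORFs,
#'   default -20.
#' @param detection_dropout Target fraction of genes lost to detection
#'   dropout (logistic in log10 abundance), default 0.
#' @param dropout_steepness Logistic steepness per log10 unit, default 3.
#' @param kinetics_gamma Planted exponent tying K_M to copies
#'   (`K_M ~ copies^gamma`), default 1.
#' @param kinetics_log10_sd Log10 noise on planted kinetics, default 0.2.
#' @param kinetics_flip_fraction Fraction of Pathway operons with the
#'   planted sign inverted as negative controls, default 0.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_operons = 300L,
                              size_distribution = c("1" = 0.3, "2" = 0.3,
                                                    "3" = 0.2, "4" = 0.1,
                                                    "5plus" = 0.1),
                              fraction_complex = 0.4,
                              regime_per_class = c(Complex = "stoichiometric",
                                                   Pathway = "staircase"),
                              staircase_decay = 0.5,
                              between_operon_log10_sd = 1.0,
                              within_noise_log10_sd = 0.1,
                              measurement_noise_log10_sd = 0.05,
                              rna_noise_log10_sd = 0.05,
                              mean_copies_log10 = 3,
                              k_true = 50,
                              interval_params = list(
                                Complex = c(mean_nt = 5, sd_nt = 15),
                                Pathway = c(mean_nt = 80, sd_nt = 40)),
                              interval_floor_nt = -20L,
                              detection_dropout = 0,
                              dropout_steepness = 3,
                              kinetics_gamma = 1,
                              kinetics_log10_sd = 0.2,
                              kinetics_flip_fraction = 0) {
  stopifnot(n_operons >= 1,
            abs(sum(size_distribution) - 1) < 1e-8,
            all(names(size_distribution) %in% c("1", "2", "3", "4", "5plus")),
            fraction_complex >= 0, fraction_complex <= 1,
            staircase_decay > 0, staircase_decay <= 1,
            between_operon_log10_sd > 0,
            within_noise_log10_sd >= 0, measurement_noise_log10_sd >= 0,
            k_true > 0, detection_dropout >= 0, detection_dropout < 1,
            all(regime_per_class %in% c("stoichiometric", "staircase",
                                        "independent")))
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate genome, operon structure and class labels
#'
#' Lays genes on one contig: CDS lengths are multiples of 3 (protein length
#' plus stop codon), within-operon intervals are drawn from the class's
#' interval distribution (truncated at the configured floor, so overlapping
#' ORFs occur), strands are assigned per operon, and minus-strand operon
#' blocks are mirrored so transcript order runs against the contig.
#' Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return List: `annotation` (gene coordinates, 1-based inclusive),
#'   `operons` (long operon table in transcript order), `classes` (operon_id,
#'   class, regime, n_genes), `membership` (complex membership table),
#'   `proteins` (named character vector of random protein sequences).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 101L, {
    sizes_lab <- sample(names(config$size_distribution), config$n_operons,
                        replace = TRUE, prob = config$size_distribution)
    sizes <- ifelse(sizes_lab == "5plus",
                    sample(5:8, config$n_operons, replace = TRUE),
                    suppressWarnings(as.integer(sizes_lab)))
    cls <- ifelse(sizes >= 2,
                  ifelse(stats::runif(config$n_operons) < config$fraction_complex,
                         "Complex", "Pathway"),
                  NA_character_)
    regime <- ifelse(is.na(cls), "independent",
                     unname(config$regime_per_class[cls]))
    strands <- sample(c("+", "-"), config$n_operons, replace = TRUE)

    gene_rows <- list(); op_rows <- list()
    cursor <- 1L
    gidx <- 0L
    for (j in seq_len(config$n_operons)) {
      op <- sprintf("op%04d", j)
      n <- sizes[j]
      aa <- sample(80:500, n, replace = TRUE)
      len <- 3L * (aa + 1L)
      ip <- config$interval_params[[if (is.na(cls[j])) "Pathway" else cls[j]]]
      iv <- if (n > 1)
        pmax(config$interval_floor_nt,
             round(stats::rnorm(n - 1L, ip[["mean_nt"]], ip[["sd_nt"]])))
      else integer()
      start <- integer(n); end <- integer(n)
      pos <- cursor
      for (i in seq_len(n)) {
        start[i] <- pos; end[i] <- pos + len[i] - 1L
        if (i < n) pos <- end[i] + iv[i] + 1L
      }
      A <- min(start); B <- max(end)
      if (strands[j] == "-") {   # mirror the block; transcript order reversed
        ns <- A + B - end; ne <- A + B - start
        start <- ns; end <- ne
      }
      ids <- sprintf("g%04d", gidx + seq_len(n))
      gidx <- gidx + n
      gene_rows[[j]] <- data.frame(
        gene_id = ids, contig = "chr", start = start, end = end,
        strand = strands[j], cds_length_nt = len,
        protein_length_aa = aa, stringsAsFactors = FALSE)
      op_rows[[j]] <- data.frame(
        operon_id = op, gene_id = ids, rank = seq_len(n),
        strand = strands[j], contig = "chr", stringsAsFactors = FALSE)
      cursor <- B + sample(100:400, 1L)
    }
    annotation <- do.call(rbind, gene_rows)
    operons <- do.call(rbind, op_rows)
    classes <- data.frame(operon_id = sprintf("op%04d", seq_len(config$n_operons)),
                          class = cls, regime = regime, n_genes = sizes,
                          stringsAsFactors = FALSE)
    cx <- classes$operon_id[!is.na(classes$class) & classes$class == "Complex"]
    membership <- operons[operons$operon_id %in% cx, c("operon_id", "gene_id")]
    membership <- data.frame(gene_id = membership$gene_id,
                             complex_id = if (nrow(membership))
                               paste0("cplx_", membership$operon_id)
                             else character(),
                             stringsAsFactors = FALSE)
    aa_letters <- names(.physchem_tables()$kd)
    proteins <- vapply(annotation$protein_length_aa, function(L)
      paste0("M", paste(sample(aa_letters, L - 1L, replace = TRUE),
                        collapse = "")), character(1L))
    names(proteins) <- annotation$gene_id
    list(annotation = annotation, operons = operons, classes = classes,
         membership = membership, proteins = proteins)
  })
}

#' Simulate true protein and RNA abundances
#'
#' Each operon draws a log-normal base level; cistron copies follow the
#' operon's regime (see [simulation_config()]); RNA is the operon transcript
#' level (the base) with small per-gene log-normal noise, reflecting that an
#' operon is transcribed as one mRNA.
#'
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @return Ground-truth data.frame: gene_id, operon_id, rank, class, regime,
#'   true_copies, true_rna.
#' @export
simulate_expression <- function(config, genome) {
  ops <- genome$operons
  cl <- genome$classes
  .with_seed(config$seed + 202L, {
    base_log10 <- stats::rnorm(nrow(cl), config$mean_copies_log10,
                               config$between_operon_log10_sd)
    names(base_log10) <- cl$operon_id
    regime <- stats::setNames(cl$regime, cl$operon_id)
    out <- ops[, c("operon_id", "gene_id", "rank")]
    n <- nrow(out)
    b <- base_log10[out$operon_id]
    reg <- regime[out$operon_id]
    lg <- numeric(n)
    noise <- stats::rnorm(n, 0, config$within_noise_log10_sd)
    indep <- stats::rnorm(n, config$mean_copies_log10,
                          config$between_operon_log10_sd)
    lg[reg == "stoichiometric"] <- (b + noise)[reg == "stoichiometric"]
    st <- reg == "staircase"
    lg[st] <- (b + (out$rank - 1L) * log10(config$staircase_decay) + noise)[st]
    lg[reg == "independent"] <- (indep + noise)[reg == "independent"]
    out$true_copies <- 10^lg
    out$true_rna <- 10^(b + stats::rnorm(n, 0, config$rna_noise_log10_sd))
    out$class <- stats::setNames(cl$class, cl$operon_id)[out$operon_id]
    out$regime <- reg
    rownames(out) <- NULL
    out
  })
}

#' Simulate measured intensities, prior abundance scales and dropout
#'
#' Intensities are `copies / k_true` under multiplicative log-normal
#' measurement noise (two independent replicates); the three prior scales
#' (iBAQ-, emPAI-, APEX-like) are the true copies under independent
#' log-normal noise. Detection dropout removes genes with a logistic
#' probability decreasing in log10 abundance, with midpoint at the
#' `detection_dropout` quantile of the abundance distribution so the
#' realised dropout fraction approximates the configured one; the mask
#' applies to the measured intensity tables only.
#'
#' @param config A [simulation_config()].
#' @param truth Output of [simulate_expression()].
#' @return List: `intensity_rep1`, `intensity_rep2` (value tables with
#'   dropout applied), `reference` (reference_abundance data.frame),
#'   `detected`, `dropped` (gene id vectors).
#' @export
simulate_measurement <- function(config, truth) {
  stopifnot(all(truth$true_copies > 0))
  .with_seed(config$seed + 303L, {
    n <- nrow(truth)
    g <- truth$gene_id
    s <- config$measurement_noise_log10_sd
    d1 <- truth$true_copies / config$k_true * 10^stats::rnorm(n, 0, s)
    d2 <- truth$true_copies / config$k_true * 10^stats::rnorm(n, 0, s)
    ref <- data.frame(
      gene_name = g,
      copies_iBAQ = truth$true_copies * 10^stats::rnorm(n, 0, s),
      copies_emPAI = truth$true_copies * 10^stats::rnorm(n, 0, s),
      copies_APEX = truth$true_copies * 10^stats::rnorm(n, 0, s),
      stringsAsFactors = FALSE)
    if (config$detection_dropout > 0) {
      lg <- log10(truth$true_copies)
      mid <- stats::quantile(lg, config$detection_dropout)
      p_detect <- stats::plogis(config$dropout_steepness * (lg - mid))
      detected <- stats::runif(n) < p_detect
    } else detected <- rep(TRUE, n)
    list(intensity_rep1 = value_table(stats::setNames(d1[detected], g[detected])),
         intensity_rep2 = value_table(stats::setNames(d2[detected], g[detected])),
         reference = ref,
         detected = g[detected], dropped = g[!detected])
  })
}

#' Simulate enzyme kinetics and pathway graphs for Pathway operons
#'
#' Every polycistronic Pathway operon becomes a linear, branch-free reaction
#' chain (metabolite j-1 -> metabolite j catalysed by the operon's j-th
#' gene). Planted kinetics follow the catalytic-efficiency hypothesis:
#' `K_M ~ (copies / operon geometric mean)^gamma` with log-normal noise, so
#' less active enzymes (higher K_M) are more abundant; `k_cat` is inversely
#' related. A configurable fraction of operons has the sign flipped as
#' negative controls.
#'
#' @param config A [simulation_config()].
#' @param genome Output of [simulate_genome()].
#' @param truth Output of [simulate_expression()].
#' @return List: `kinetics` (kinetics data.frame), `graph`
#'   ([pathway_graph()]), `flipped` (operon ids with inverted sign).
#' @export
simulate_kinetics <- function(config, genome, truth) {
  cl <- genome$classes
  pw <- cl$operon_id[!is.na(cl$class) & cl$class == "Pathway" & cl$n_genes >= 2]
  if (length(pw) == 0L) .stopf("no polycistronic Pathway operons to plant kinetics on")
  .with_seed(config$seed + 404L, {
    n_flip <- round(config$kinetics_flip_fraction * length(pw))
    flipped <- if (n_flip > 0) sample(pw, n_flip) else character()
    kin_rows <- list(); rx_rows <- list()
    for (op in pw) {
      sel <- truth$operon_id == op
      genes <- truth$gene_id[sel][order(truth$rank[sel])]
      copies <- truth$true_copies[sel][order(truth$rank[sel])]
      gamma <- if (op %in% flipped) -config$kinetics_gamma else config$kinetics_gamma
      rel <- copies / exp(mean(log(copies)))
      km <- rel^gamma * 10^stats::rnorm(length(genes), 0,
                                        config$kinetics_log10_sd)
      kcat <- 1 / rel^gamma * 10^stats::rnorm(length(genes), 0,
                                              config$kinetics_log10_sd)
      kin_rows[[op]] <- data.frame(
        enzyme_gene = genes, k_cat = kcat, K_M = km,
        k_cat_organism = "Escherichia coli",
        K_M_organism = "Escherichia coli",
        homology_pct = NA_real_, stringsAsFactors = FALSE)
      mets <- paste0("m_", op, "_", seq(0L, length(genes)))
      rx_rows[[op]] <- data.frame(
        substrate = mets[-length(mets)], product = mets[-1L],
        enzyme_gene = genes, stringsAsFactors = FALSE)
    }
    list(kinetics = do.call(rbind, c(kin_rows, list(make.row.names = FALSE))),
         graph = pathway_graph(do.call(rbind, c(rx_rows,
                                                list(make.row.names = FALSE)))),
         flipped = flipped)
  })
}

#' Generate a complete synthetic operon proteome dataset
#'
#' Runs all generator stages and assembles every input the analysis
#' pipeline consumes, together with the ground truth.
#'
#' @param config A [simulation_config()] (default configuration if omitted).
#' @return List of class `opstoich_dataset`: `config`, `annotation`,
#'   `operons`, `classes`, `membership`, `proteins`, `truth`, `quant`
#'   (protein_quant data.frame, two replicates), `intensity_rep1/2`,
#'   `reference`, `rna` (value table of true RNA), `rna_counts` (read-count
#'   table), `kinetics`, `graph`, `flipped`, `dropped`.
#' @export
simulate_operon_dataset <- function(config = simulation_config()) {
  genome <- simulate_genome(config)
  truth <- simulate_expression(config, genome)
  meas <- simulate_measurement(config, truth)
  kin <- simulate_kinetics(config, genome, truth)
  quant <- .with_seed(config$seed + 505L, {
    mk <- function(vt, rep) {
      data.frame(protein_id = vt$key, gene_name = vt$key,
                 intensity = vt$value,
                 n_unique_peptides = 2L + stats::rpois(nrow(vt), 8),
                 min_peptide_length = 7L,
                 strain = "SIM", replicate = rep, stringsAsFactors = FALSE)
    }
    rbind(mk(meas$intensity_rep1, "rep1"), mk(meas$intensity_rep2, "rep2"))
  })
  rna_counts <- .with_seed(config$seed + 606L, {
    lambda <- truth$true_rna * truth$true_copies^0 *
      genome$annotation$cds_length_nt[match(truth$gene_id,
                                            genome$annotation$gene_id)] / 1000
    data.frame(gene_id = truth$gene_id,
               read_count = stats::rpois(nrow(truth), lambda),
               cds_length_nt = genome$annotation$cds_length_nt[
                 match(truth$gene_id, genome$annotation$gene_id)],
               stringsAsFactors = FALSE)
  })
  out <- c(list(config = config), genome,
           list(truth = truth, quant = quant,
                intensity_rep1 = meas$intensity_rep1,
                intensity_rep2 = meas$intensity_rep2,
                reference = meas$reference,
                dropped = meas$dropped,
                rna = value_table(stats::setNames(truth$true_rna,
                                                  truth$gene_id), "copies"),
                rna_counts = rna_counts,
                kinetics = kin$kinetics, graph = kin$graph,
                flipped = kin$flipped))
  class(out) <- c("opstoich_dataset", "list")
  out
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits GFF3 (gene annotation), TSVs (operons, protein quantification,
#' reference abundances, RNA counts, kinetics, complex membership), a
#' protein FASTA and a ground-truth JSON into a directory, so that the file
#' readers and the pipeline can be exercised end to end.
#'
#' @param dataset Output of [simulate_operon_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- dataset$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = "CDS", phase = 0L, ID = ann$gene_id)
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  .write_tsv(dataset$operons[, c("operon_id", "gene_id", "rank")],
             file.path(dir, "operons.tsv"))
  .write_tsv(dataset$quant, file.path(dir, "protein_quant.tsv"))
  .write_tsv(dataset$reference, file.path(dir, "reference_abundance.tsv"))
  .write_tsv(dataset$rna_counts, file.path(dir, "rna_counts.tsv"))
  .write_tsv(dataset$kinetics, file.path(dir, "kinetics.tsv"))
  .write_tsv(dataset$membership, file.path(dir, "complex_membership.tsv"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(dataset$proteins),
                              file.path(dir, "proteins.fasta"))
  truth <- list(seed = dataset$config$seed,
                k_true = dataset$config$k_true,
                classes = dataset$classes,
                truth = dataset$truth,
                flipped = dataset$flipped,
                dropped = dataset$dropped)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
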