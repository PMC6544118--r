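test_that("generation is fully deterministic under the config seed", {
  cfg <- simulation_config(seed = 5, n_operons = 40)
  d1 <- simulate_operon_dataset(cfg)
  d2 <- simulate_operon_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$quant, d2$quant)
  expect_identical(d1$kinetics, d2$kinetics)
  d3 <- simulate_operon_dataset(simulation_config(seed = 6, n_operons = 40))
  expect_false(identical(d1$truth$true_copies, d3$truth$true_copies))
})

test_that("genome layout respects class structure and interval distributions", {
  cfg <- simulation_config(seed = 8, n_operons = 150, fraction_complex = 1,
                           size_distribution = c("2" = 0.5, "3" = 0.5))
  g <- simulate_genome(cfg)
  expect_true(all(g$classes$class == "Complex"))
  expect_true(all(g$annotation$cds_length_nt %% 3 == 0))
  expect_equal(g$annotation$protein_length_aa,
               g$annotation$cds_length_nt / 3 - 1)

  # planted short Complex vs long Pathway intervals are distinguishable
  cfg2 <- simulation_config(seed = 9, n_operons = 120, fraction_complex = 0.5,
                            size_distribution = c("2" = 0.4, "3" = 0.6))
  g2 <- simulate_genome(cfg2)
  iv <- gene_intervals(g2$operons, g2$annotation)
  cls <- setNames(g2$classes$class, g2$classes$operon_id)
  ivc <- iv$interval_nt[cls[iv$operon_id] == "Complex"]
  ivp <- iv$interval_nt[cls[iv$operon_id] == "Pathway"]
  expect_gt(length(ivc), 50); expect_gt(length(ivp), 50)
  ks <- compare_distributions(ivc, ivp, "kolmogorov_smirnov")
  expect_lt(ks$p_value, 0.01)
  expect_lt(median(ivc), median(ivp))
})

test_that("noise-free regimes produce their exact CV signatures", {
  cfg <- simulation_config(seed = 10, n_operons = 30,
                           within_noise_log10_sd = 0,
                           regime_per_class = c(Complex = "stoichiometric",
                                                Pathway = "staircase"),
                           staircase_decay = 0.5,
                           size_distribution = c("3" = 1))
  g <- simulate_genome(cfg)
  tr <- simulate_expression(cfg, g)
  cv <- compute_operon_cvs(g$operons, setNames(tr$true_copies, tr$gene_id))
  cls <- setNames(g$classes$class, g$classes$operon_id)
  cv_complex <- cv$cv_percent[cls[cv$operon_id] == "Complex"]
  cv_pathway <- cv$cv_percent[cls[cv$operon_id] == "Pathway"]
  expect_equal(cv_complex, rep(0, length(cv_complex)))
  # decay 1:0.5:0.25 is the 4:2:1 staircase: CV = 100*sqrt(7/3)/(7/3)
  expect_equal(cv_pathway, rep(100 * sqrt(7 / 3) / (7 / 3),
                               length(cv_pathway)),
               tolerance = 1e-9)
  expect_equal(cv_pathway[1], 65.465, tolerance = 1e-3)
  # RNA tracks the operon transcript level
  expect_true(all(tr$true_rna > 0))
})

test_that("noiseless measurement recovers the planted conversion exactly", {
  cfg <- simulation_config(seed = 12, n_operons = 60,
                           measurement_noise_log10_sd = 0, k_true = 321.5)
  g <- simulate_genome(cfg)
  tr <- simulate_expression(cfg, g)
  me <- simulate_measurement(cfg, tr)
  m <- select_calibration_set(me$reference, me$intensity_rep1, top_n = 500)
  expect_equal(conversion_coefficient(m)$k, 321.5, tolerance = 1e-10)
})

test_that("detection dropout is abundance-biased at roughly the target rate", {
  cfg <- simulation_config(seed = 13, n_operons = 400,
                           detection_dropout = 0.3)
  g <- simulate_genome(cfg)
  tr <- simulate_expression(cfg, g)
  me <- simulate_measurement(cfg, tr)
  frac <- length(me$dropped) / nrow(tr)
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
  lg <- setNames(log10(tr$true_copies), tr$gene_id)
  cmp <- compare_distributions(lg[me$detected], lg[me$dropped],
                               "mann_whitney_u")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(median(lg[me$detected]), median(lg[me$dropped]))
})

test_that("planted kinetics drive concordance, with flipped negative controls", {
  cfg <- simulation_config(seed = 14, n_operons = 80, fraction_complex = 0.2,
                           kinetics_log10_sd = 0,
                           kinetics_flip_fraction = 0.25,
                           size_distribution = c("2" = 0.3, "3" = 0.7))
  ds <- simulate_operon_dataset(cfg)
  copies <- setNames(ds$truth$true_copies, ds$truth$gene_id)
  cand <- branch_free_candidates(ds$operons, copies, ds$graph, ds$kinetics)
  expect_gt(length(cand), 10)
  v <- concordance_verdicts(cand, ds$operons, copies, kinetics = ds$kinetics)
  flipped <- v$operon_id %in% ds$flipped
  expect_true(any(flipped))
  expect_true(all(v$km_abundance_concordant[!flipped]))   # sigma = 0
  expect_false(any(v$km_abundance_concordant[flipped]))
})

test_that("datasets round-trip through standard file formats", {
  ds <- small_dataset(seed = 15, n_operons = 12)
  dir <- tempfile("synthds")
  write_dataset(ds, dir)
  res <- read_operon_annotation(file.path(dir, "operons.tsv"),
                                file.path(dir, "annotation.gff3"))
  expect_equal(res$operons$gene_id, ds$operons$gene_id)  # transcript order kept
  ann <- res$annotation[match(ds$annotation$gene_id, res$annotation$gene_id), ]
  expect_equal(ann$start, ds$annotation$start)
  expect_equal(ann$strand, ds$annotation$strand)

  q <- read_quant_table(file.path(dir, "protein_quant.tsv"), "protein_quant")
  expect_equal(q$gene_name, ds$quant$gene_name)
  kin <- read_quant_table(file.path(dir, "kinetics.tsv"), "kinetics")
  expect_equal(kin$enzyme_gene, ds$kinetics$enzyme_gene)
  fa <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  expect_equal(as.character(fa), ds$proteins)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$k_true, ds$config$k_true)
})
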