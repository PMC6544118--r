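# shared fixture builders; everything is generated in code

# minimal GFF3 written as plain text (independent of the package's writer)
write_tiny_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  # genes: data.frame gene_id, start, end, strand (contig "chr")
  lines <- c("##gff-version 3",
             sprintf("chr\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$start, genes$end, genes$strand, genes$gene_id))
  writeLines(lines, path)
  path
}

write_operon_tsv <- function(operons, path = tempfile(fileext = ".tsv")) {
  # operons: named list operon_id -> gene id vector
  df <- data.frame(operon_id = names(operons),
                   gene_ids = vapply(operons, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_quant_df <- function(genes, intensity, strain = "S", replicate = "rep1",
                          unique_peptides = 3L, peplen = 8L) {
  data.frame(protein_id = genes, gene_name = genes, intensity = intensity,
             n_unique_peptides = unique_peptides,
             min_peptide_length = peplen, strain = strain,
             replicate = replicate, stringsAsFactors = FALSE)
}

# one-sided overrepresentation tail by explicit combinatorial enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(k, min(n, K))
  if (length(js) == 0L || k > min(n, K)) return(if (k <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

table1_path <- function() {
  system.file("extdata", "table1_kinetics.tsv", package = "opstoich")
}

# small complete dataset for pipeline-level tests
small_dataset <- function(seed = 42, n_operons = 80, ...) {
  simulate_operon_dataset(simulation_config(seed = seed,
                                            n_operons = n_operons, ...))
}

dataset_inputs <- function(ds) {
  list(quant = ds$quant, operons = ds$operons, annotation = ds$annotation,
       reference = ds$reference, membership = ds$membership, rna = ds$rna,
       kinetics = ds$kinetics, graph = ds$graph, proteins = ds$proteins)
}
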