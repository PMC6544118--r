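# opstoich

Do bacterial operons keep their gene products at stoichiometric levels?
More than half of the protein-coding genes in a typical bacterium sit in
polycistronic operons and are transcribed as one mRNA, yet the proteins of
an operon often accumulate at very different levels. `opstoich` implements
a complete, testable analysis of operon stoichiometry from label-free
quantitative proteomics, for proteomics and systems-biology researchers who
have per-protein intensities (e.g. from a DIA/SWATH protein pivot report)
plus operon and genome annotation, or who want to study the statistics
themselves on synthetic data with known ground truth.

## The model

**Copies per cell.** Measured intensities `D_i` are converted to protein
copies per cell with a single coefficient calibrated on the most abundant
proteins against three prior label-free copy-number scales (iBAQ, emPAI,
APEX: `B_i`, `P_i`, `A_i`):

    k = geomean_i[(B_i + P_i + A_i) / 3] / geomean_i[D_i]
    copies_i = k * D_i

**Within-operon dispersion.** Each operon with at least two quantified
proteins is scored by the coefficient of variation of its members'
abundances,

    CV = 100% * sd(x_1..x_n) / mean(x_1..x_n)      (n - 1 denominator)

and compared against a permutation null built by reshuffling the quantified
abundances of all polycistronic operons over the same gene slots, which
preserves operon sizes and the value multiset exactly.

**Operon classes and structure.** Operons with >= 90% of their genes in one
protein complex are labelled *Complex*, the rest *Pathway*. The analysis
contrasts the two classes in CV, in CV-vs-length regression, in RNA-protein
correlation, and in intergenic distance, where intervals shorter than the
~40 nt ribosome footprint indicate coupled 70S-scanning reinitiation.
For Pathway operons lying on branch-free reaction chains with known
kinetics, the package tests whether less active enzymes (higher Michaelis
constant K_M) are more abundant — the catalytic-efficiency explanation of
non-stoichiometric expression.

## Worked example

```r
library(opstoich)

cfg <- simulation_config(seed = 42, n_operons = 150, detection_dropout = 0.1)
ds  <- simulate_operon_dataset(cfg)
fit <- operon_stoichiometry(
  list(quant = ds$quant, operons = ds$operons, annotation = ds$annotation,
       reference = ds$reference, membership = ds$membership, rna = ds$rna,
       kinetics = ds$kinetics, graph = ds$graph, proteins = ds$proteins),
  n_permutations = 500, seed = 1, verbose = FALSE)
summary(fit)
```

```
Operon stoichiometry analysis
  conversion: k = 50.15 (346 calibration proteins); 346 genes quantified
  within-operon CV: 97 operons, mean 45.0% (null mean 119.5%, 500 permutations)
  real vs null: MWU p = 2.89e-42, KS p = 0
  Complex vs Pathway CV: MWU p = 1.77e-11
  Complex vs Pathway gene intervals: KS p = 0
  kinetics concordance: 50/55 candidate operons concordant

CV by size group (real | null medians):
  2     n =  43:   28.41% |  115.71%
  3     n =  24:   54.94% |  127.90%
  4     n =  21:   32.75% |  138.66%
  5plus n =   9:   31.95% |  159.35%

CV vs operon size regressions:
  Complex  slope = 2.450 (p = 0.0129, n = 42)
  Pathway  slope = 17.807 (p = 3.61e-11, n = 55)

RNA-protein correlation (r^2):
  all      0.6253
  Complex  0.9877
  Pathway  0.8140

Coverage: 88.7% of 390 annotated genes quantified; 90.7% of polycistronic operons with >= 2 quantified proteins
```

Reading the output: the planted conversion coefficient (50) is recovered as
`k = 50.15`; real within-operon CVs sit far below the reshuffled null
(operons unify expression); Complex operons are tighter than Pathway
operons and only the Pathway class grows markedly noisier with operon
length; RNA-protein correlation is near-perfect for Complex operons; and
50 of 55 branch-free Pathway operons show the higher-K_M ⇒ higher-abundance
relationship planted by the generator (`kinetics_log10_sd = 0.2` noise
accounts for the rest).

Individual stages are exported (`conversion_coefficient()`, `operon_cv()`,
`randomize_null()`, `classify_operon()`, `fisher_enrichment()`,
`gene_intervals()`, `branch_free_candidates()`, `gravy()`,
`isoelectric_point()`, `rpkm()`, ...), and a curated enzyme kinetics table
ships with the package:

```r
kin <- read_quant_table(system.file("extdata", "table1_kinetics.tsv",
                                    package = "opstoich"), "kinetics")
kinetic_ratio(kin, "ArgB", "ArgC", "K_M")$ratio
#> [1] 3.25
```

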