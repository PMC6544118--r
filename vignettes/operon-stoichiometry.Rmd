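---
title: "Methods: quantifying stoichiometry control in bacterial operons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stoichiometry control in bacterial operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the estimator

A polycistronic operon is transcribed as one mRNA, so to first order its
genes share a transcriptional program. Whether the *proteins* of an operon
are kept at stoichiometric (equimolar) levels is a different question:
translation efficiency and turnover act per cistron. `opstoich` treats this
as an estimation problem with three ingredients.

**1. Absolute scale.** Label-free MS intensities are proportional to
abundance within a run but carry no absolute unit. Assuming the most
abundant proteins dominate total protein mass and are well estimated by
earlier label-free scales (iBAQ, emPAI, APEX copies per cell), a single
conversion coefficient

$$k = \frac{\prod_i \left[(B_i+P_i+A_i)/3\right]^{1/n}}{\prod_i D_i^{1/n}}$$

is fitted on the matched top-`top_n` reference proteins and applied as
`copies = k * D`. The geometric mean is the right average for
multiplicative measurement error; we accumulate in log space so that
hundreds of factors spanning many orders of magnitude neither overflow nor
lose precision. Because `k` is a global scalar, every downstream ratio and
every CV is identical whether computed on intensities or on copies; the
calibration matters only when absolute copy numbers are read off.

The reference ranking statistic ("most abundant") is the arithmetic mean of
the three prior copy estimates, with lexicographic gene-name tie-breaks —
a deterministic choice among several defensible ones. Genes with a zero or
missing value on any scale are excluded (the product is undefined there),
and the exclusion count is reported. When two replicates are present the
pipeline calibrates on the per-gene mean intensity; this is a documented
default, not the only option — both replicates are also exposed for QC,
where Pearson correlations of log10 abundance are reported overall and in
low/mid/high sections split at log10 = 2.0 and 3.5.

**2. Dispersion statistic.** Each operon with `n >= 2` quantified proteins
gets

$$\mathrm{CV} = \frac{\sqrt{\tfrac{1}{n-1}\sum_i (x_i-\bar x)^2}}{\bar x}\times 100\%$$

on linear-scale abundances (the statistic is defined on quantities, not
logs). Unquantified genes are dropped, never zero-filled: a missing MS
value mostly reflects detectability, and imputing zeros would
manufacture dispersion. The operon's size group (2, 3, 4, 5plus) follows
the number of *quantified* genes by default, mirroring the "protein numbers
>= 2" convention; `group_by = "annotated"` switches to the genomic gene
count.

**3. Permutation null.** Observed CVs are compared with a negative control
in which the quantified abundances of all polycistronic operons are
reshuffled jointly over those same gene slots and per-operon CVs are
recomputed. The joint reshuffle-then-extract design (rather than shuffling
within size groups) matches the idea of a single genome-wide null pool;
because the quantified/unquantified pattern is held fixed, the null
preserves operon sizes exactly, and each permutation preserves the value
multiset exactly. The default is 1000 permutations with all null CVs
pooled; the per-size-group medians of this pool define the low/high (L/H)
split of real operons, with ties going high. Pooling stabilises the median
against permutation-to-permutation jitter. Distribution comparisons use
two-sided Mann-Whitney U, Kolmogorov-Smirnov and Kruskal-Wallis tests
throughout; sidedness is not varied per comparison.

# Classification and structure

An operon is *Complex* when at least 90% of its annotated genes encode
subunits of one and the same protein complex (boundary inclusive: 9 of 10
qualifies). The fraction uses the single best-covered complex, not a union,
and the denominator is the annotated gene count — classification is a
genome property, independent of what the MS run detected. Everything else
is *Pathway*.

Functional overrepresentation of gene sets (e.g. the low-CV subgroups) is
a one-sided Fisher exact test — the upper hypergeometric tail of the 2x2
table against a user-supplied background, with terms taken as flat sets.
Raw p-values are thresholded at `alpha = 0.01` by default and a stricter
0.001 display mask is also reported; Benjamini-Hochberg adjustment is
available but off by default so that the raw-threshold convention is the
visible behaviour.

**Gene intervals.** The interval between adjacent cistrons is the number of
nucleotides strictly between the upstream CDS end (past its stop codon) and
the downstream CDS start: 0 means back-to-back, negative means overlapping
ORFs. On-disk coordinates are 1-based inclusive (GFF); internally
everything is 0-based half-open, so the + strand interval is
`start0(next) - end0(prev)` with the mirrored form on the - strand. We
state this convention prominently because ±3 nt offsets (stop codon in or
out) are endemic across tools; whichever convention another pipeline uses,
the *differences* between classes are unaffected. Intervals below the
ribosome footprint (`footprint_nt = 40`, strict inequality "nearer than
40 nt") are classified as coupled 70S-scanning reinitiation; negative
intervals are maximally proximal and hence coupled. Overlapping ORFs are
kept, not clipped.

**Enzyme kinetics.** Pathway operons qualify for the kinetics comparison
when (a) at least two quantified proteins act in the same pathway, (b) the
spanned segment is branch-free — every internal metabolite between
consecutive quantified enzymes has exactly one producing and one consuming
reaction — and (c) kinetic parameters exist for all of them with at least
one value measured in the reference organism (default *Escherichia coli*;
cross-organism values are used as-is but carry their homology annotation,
and `require_reference = FALSE` relaxes the clause). Concordance is a
positive Spearman correlation between K_M and protein copies; K_M is the
primary activity proxy (k_cat is reported alongside when present), and with
two enzymes the statistic reduces to a pairwise order check. "Inverse RNA
vs protein expression" is formalised as a negative Spearman correlation of
within-operon ranks; the aggregate across candidate operons is reported as
a per-operon verdict table rather than a single test, since no standard
statistic exists for "all operons validate without exception". A curated
kinetics table (`inst/extdata/table1_kinetics.tsv`) ships with the package;
rows measured in other organisms carry the organism and percent homology.

**Physicochemical features.** GRAVY is the mean Kyte-Doolittle hydropathy;
the isoelectric point is the zero of the net-charge curve under a
Bjellqvist-style pKa set (including residue-specific terminal pKas), found
by bisection over pH 0-14 to far below 0.01 pH; the instability index is
the standard dipeptide-weight sum scaled by 10/L. All three constant tables
are shipped as TSVs under `inst/extdata/` so tests can apply them naively
and independently of the implementation. Ambiguous residues (B, Z, X, U)
are rejected by default; `skip_ambiguous = TRUE` drops them from the means.
RNA quantification uses rpkM over CDS-mapped reads with the >= 10-read
quantifiability rule.

# The synthetic data model

`simulation_config()` defines the study conditions; the defaults describe
an E. coli-like genome at desk scale: 300 operons on one contig, operon
sizes distributed 30/30/20/10/10% over 1/2/3/4/5+ genes (5+ drawn from
5-8), 40% of polycistronic operons Complex, protein lengths 80-500 aa.
Expression: operon base levels are log-normal with `mean_copies_log10 = 3`
and between-operon sd 1.0 log10; Complex operons are stoichiometric
(within-operon log10 sd 0.1), Pathway operons follow a staircase with
per-cistron retention 0.5; RNA is the operon transcript level with 0.05
log10 per-gene noise. Measurement: intensities are `copies / k_true`
(default `k_true = 50`) under 0.05 log10 multiplicative noise, two
replicates; the three prior scales get independent noise of the same
magnitude. Intervals: Complex operons mean 5 ± 15 nt, Pathway 80 ± 40 nt,
floored at -20 nt so overlapping ORFs occur. Kinetics: for every
polycistronic Pathway operon a linear reaction chain is emitted and
`K_M ∝ (relative copies)^gamma` with `gamma = 1` and 0.2 log10 noise;
`kinetics_flip_fraction` inverts the sign for negative controls. Detection
dropout, off by default, removes genes with a logistic probability in log10
copies whose midpoint sits at the `detection_dropout` quantile of the
abundance distribution, so the realised dropout fraction approximates the
configured value; the mask applies to the intensity tables only, since the
prior scales play the role of external, complete reference datasets.

These choices were made once, before any comparison against expected
outcomes, as a scientist's notion of realistic magnitudes for an
exponential-phase bacterial proteome; they are deliberately not tuned.

What the generator does *not* emulate: peptide-level effects (shared
peptides, missed cleavages, protein inference), intensity-dependent rather
than abundance-dependent noise, correlated dropout between replicates,
operon-internal promoters and terminators, mRNA secondary structure and SD
strength, and protein turnover differences. Passing tests on synthetic data
therefore demonstrate that the *statistics* behave as designed — that the
null is calibrated, the estimators recover planted truth, and the
qualitative contrasts (real below null, Complex tighter than Pathway, short
Complex intervals) are detected when present — not that any particular real
proteome shows these effects.

# Numerical and degenerate-case choices

* Geometric means in log space; `conversion_coefficient()` refuses
  non-positive inputs rather than silently dropping them.
* `operon_cv()` errors on `n < 2` and on zero mean; operons whose
  quantified values are all zero are dropped with a count.
* The permutation engine uses R's default Mersenne-Twister stream, seeded
  per call, and restores the caller's RNG state, so embedding the analysis
  in a larger seeded script does not perturb that script's stream.
* Mann-Whitney and KS tests use the asymptotic (exact = FALSE) forms:
  abundance data are continuous and the null pools are large. Fully tied
  feature comparisons report p = 1 (no evidence) instead of NaN.
* Regressions on a constant response return slope 0 with p = 1 (no
  evidence of a trend) instead of the undefined OLS p-value; a constant
  predictor is an error.
* Enrichment p-values come from `phyper` upper tails; the split-at-median
  rule sends exact ties to the high group and this tie rule is documented
  in `split_by_null_median()`.
* In tests and the acceptance script, simulations use 40-300 operons and
  5-1000 permutations — sizes chosen so the whole validation suite runs in
  about a minute while keeping every comparison far from its decision
  boundary.

# Scope and limitations

The package deliberately stops upstream of raw MS and sequencing data: no
spectra, FDR estimation, spectral libraries or read mapping — inputs are
the tabular exports of those tools. Identifier joining across tables is by
gene name, case-sensitive, with a user-supplied alias table replacing
online conversion services; duplicate gene rows in a quantification table
are an error, not an implicit aggregation. GO term structure is not
propagated (terms are flat sets). The kinetics comparison inherits the
sparsity of curated kinetic constants — criteria (a)-(c) are exactly the
conditions under which the comparison is interpretable, and cross-organism
values remain an acknowledged approximation. Finally, the headline p-values
of any real dataset depend on its depth and noise; the package reproduces
the *procedure* and validates it on planted ground truth, and the
quantities written by `scripts/acceptance.R` are recomputed from those
simulations and the shipped kinetics table at every run.
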