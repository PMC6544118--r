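#' Construct a metabolic pathway graph
#'
#' A minimal reaction network: metabolite nodes and directed
#' substrate -> product reactions, each catalysed by an enzyme gene. This is
#' the substrate for the branch-free test: a pathway segment is branch-free
#' when no internal metabolite is produced or consumed by more than one
#' reaction (no competing branches that could be rate limiting).
#'
#' @param reactions data.frame with columns `substrate`, `product`,
#'   `enzyme_gene`.
#' @return Object of class `pathway_graph`.
#' @export
pathway_graph <- function(reactions) {
  stopifnot(all(c("substrate", "product", "enzyme_gene") %in% names(reactions)))
  if (any(reactions$substrate == reactions$product))
    .stopf("self-loop reaction at enzyme %s",
           reactions$enzyme_gene[reactions$substrate == reactions$product][1L])
  g <- list(metabolites = unique(c(reactions$substrate, reactions$product)),
            reactions = data.frame(substrate = as.character(reactions$substrate),
                                   product = as.character(reactions$product),
                                   enzyme_gene = as.character(reactions$enzyme_gene),
                                   stringsAsFactors = FALSE))
  class(g) <- "pathway_graph"
  g
}

# walk downstream from reaction `r` through branch-free internal metabolites
# until the next reaction catalysed by a target enzyme; NA when the walk hits
# a branch point or leaves the network
.walk_to_next <- function(graph, r, targets) {
  rx <- graph$reactions
  prod_cnt <- table(rx$product)
  sub_cnt <- table(rx$substrate)
  m <- rx$product[r]
  for (step in seq_len(nrow(rx) + 1L)) {
    nprod <- prod_cnt[m]; nsub <- sub_cnt[m]
    if (is.na(nsub) || nsub == 0L) return(NA_character_)   # dead end
    if (nprod != 1L || nsub != 1L) return(NA_character_)   # branch point
    nxt <- which(rx$substrate == m)
    e <- rx$enzyme_gene[nxt]
    if (e %in% targets) return(e)
    m <- rx$product[nxt]
  }
  NA_character_
}

#' Identify branch-free Pathway operon candidates
#'
#' Keeps the operons satisfying the three selection criteria for the
#' kinetics-vs-abundance comparison: (a) at least two quantified proteins
#' acting in the same metabolic pathway; (b) the pathway segment spanned by
#' those enzymes is branch-free, i.e. every internal metabolite between
#' consecutive quantified enzymes has exactly one producing and one
#' consuming reaction; (c) kinetic parameters (k_cat or K_M) available for
#' every quantified enzyme, with at least one value measured in the
#' reference organism.
#'
#' @param operons Long operon data.frame.
#' @param quant Value table of protein abundances (quantified = present with
#'   a positive value).
#' @param graph A [pathway_graph()].
#' @param kinetics Kinetics data.frame (see [read_quant_table()] schema
#'   `kinetics`).
#' @param reference_organism Organism whose measured values satisfy
#'   criterion (c); default `"Escherichia coli"`.
#' @param require_reference Enforce the reference-organism clause of (c),
#'   default `TRUE`.
#' @return Character vector of candidate operon ids; rejection reasons in
#'   attribute `reasons` (data.frame operon_id, reason).
#' @export
branch_free_candidates <- function(operons, quant, graph, kinetics,
                                   reference_organism = "Escherichia coli",
                                   require_reference = TRUE) {
  stopifnot(inherits(graph, "pathway_graph"))
  vals <- .as_named_values(quant)
  quantified <- names(vals)[vals > 0 & !is.na(vals)]
  rx <- graph$reactions
  ids <- unique(operons$operon_id)
  reasons <- list(); keep <- character()
  for (op in ids) {
    genes <- operons$gene_id[operons$operon_id == op]
    qg <- intersect(genes, quantified)
    if (length(qg) < 2L) { reasons[[op]] <- "fewer_than_2_quantified"; next }
    if (!all(qg %in% rx$enzyme_gene)) {
      reasons[[op]] <- sprintf("enzyme_absent_from_graph:%s",
                               setdiff(qg, rx$enzyme_gene)[1L]); next }
    # successor of each quantified enzyme along a branch-free walk
    succ <- vapply(qg, function(e) {
      r <- which(rx$enzyme_gene == e)[1L]
      .walk_to_next(graph, r, setdiff(qg, e))
    }, character(1L))
    linked <- stats::na.omit(succ)
    starts <- setdiff(qg, linked)        # no quantified predecessor
    chain_ok <- length(starts) == 1L && !anyDuplicated(linked)
    if (chain_ok) {                       # walk the chain, must visit all
      seen <- starts; cur <- starts
      while (!is.na(succ[cur])) { cur <- succ[cur]; seen <- c(seen, cur) }
      chain_ok <- length(seen) == length(qg)
    }
    if (!chain_ok) { reasons[[op]] <- "branched_or_disconnected"; next }
    kin <- kinetics[match(qg, kinetics$enzyme_gene), , drop = FALSE]
    if (anyNA(kin$enzyme_gene) ||
        any(is.na(kin$k_cat) & is.na(kin$K_M))) {
      reasons[[op]] <- "kinetics_unavailable"; next }
    if (require_reference) {
      in_ref <- (!is.na(kin$k_cat) & !is.na(kin$k_cat_organism) &
                   kin$k_cat_organism == reference_organism) |
                (!is.na(kin$K_M) & !is.na(kin$K_M_organism) &
                   kin$K_M_organism == reference_organism)
      if (!any(in_ref)) { reasons[[op]] <- "no_reference_organism_value"; next }
    }
    keep <- c(keep, op)
  }
  reasons_df <- data.frame(operon_id = names(reasons),
                           reason = unlist(reasons) %||% character(),
                           stringsAsFactors = FALSE, row.names = NULL)
  attr(keep, "reasons") <- reasons_df
  keep
}

#' Ratio of kinetic parameters between two enzymes
#'
#' @param kinetics Kinetics data.frame.
#' @param e1,e2 Enzyme gene names (numerator, denominator).
#' @param parameter `"K_M"` or `"k_cat"`.
#' @return List with `ratio` and `log10_ratio`.
#' @examples
#' kin <- read_quant_table(system.file("extdata", "table1_kinetics.tsv",
#'                                     package = "opstoich"), "kinetics")
#' kinetic_ratio(kin, "ArgB", "ArgC", "K_M")$ratio  # 3.25
#' @export
kinetic_ratio <- function(kinetics, e1, e2, parameter = c("K_M", "k_cat")) {
  parameter <- match.arg(parameter)
  get1 <- function(e) {
    i <- match(e, kinetics$enzyme_gene)
    if (is.na(i)) .stopf("enzyme %s not in kinetics table", e)
    v <- kinetics[[parameter]][i]
    if (is.na(v)) .stopf("kinetics error: %s has no %s value", e, parameter)
    v
  }
  ratio <- get1(e1) / get1(e2)
  list(ratio = ratio, log10_ratio = log10(ratio))
}

#' Kinetics-abundance concordance for one operon
#'
#' Tests the "less active enzymes are expressed in higher amount"
#' relationship on an operon's quantified enzymes: concordant when the
#' Spearman rank correlation between K_M (substrate affinity proxy; higher
#' K_M = weaker binding = less active) and protein copies is positive. With
#' exactly two enzymes this reduces to a pairwise order check. Also reports
#' whether within-operon RNA and protein ranks run in opposite directions
#' (negative Spearman), the signature of translation-level tuning.
#'
#' @param genes Character vector of the operon's gene ids.
#' @param quant_protein Value table of protein abundances.
#' @param quant_rna Optional value table of RNA abundances.
#' @param kinetics Kinetics data.frame.
#' @return List: n_enzymes, km_abundance_concordant, rna_protein_inverted,
#'   spearman_km_abundance, spearman_rna_protein.
#' @export
concordance <- function(genes, quant_protein, quant_rna = NULL, kinetics) {
  prot <- .as_named_values(quant_protein)
  km <- kinetics$K_M[match(genes, kinetics$enzyme_gene)]
  names(km) <- genes
  use <- genes[!is.na(km) & genes %in% names(prot) & prot[genes] > 0]
  if (length(use) < 2L)
    .stopf("concordance undefined: fewer than 2 enzymes with both K_M and abundance")
  s_km <- stats::cor(km[use], prot[use], method = "spearman")
  out <- list(n_enzymes = length(use),
              km_abundance_concordant = isTRUE(s_km > 0),
              rna_protein_inverted = NA,
              spearman_km_abundance = s_km,
              spearman_rna_protein = NA_real_)
  if (!is.null(quant_rna)) {
    rna <- .as_named_values(quant_rna)
    both <- genes[genes %in% names(rna) & genes %in% names(prot)]
    if (length(both) >= 2L) {
      s_rp <- stats::cor(rank(rna[both]), rank(prot[both]),
                         method = "spearman")
      out$spearman_rna_protein <- s_rp
      out$rna_protein_inverted <- isTRUE(s_rp < 0)
    }
  }
  out
}

#' Concordance verdicts for a set of candidate operons
#'
#' Applies [concordance()] to each operon that passed
#' [branch_free_candidates()].
#'
#' @param candidate_ids Operon ids (from [branch_free_candidates()]).
#' @param operons Long operon data.frame.
#' @param quant_protein,quant_rna,kinetics See [concordance()].
#' @return data.frame: operon_id, n_enzymes, km_abundance_concordant,
#'   rna_protein_inverted, spearman_km_abundance.
#' @export
concordance_verdicts <- function(candidate_ids, operons, quant_protein,
                                 quant_rna = NULL, kinetics) {
  res <- lapply(candidate_ids, function(op) {
    v <- concordance(operons$gene_id[operons$operon_id == op],
                     quant_protein, quant_rna, kinetics)
    data.frame(operon_id = op, n_enzymes = v$n_enzymes,
               km_abundance_concordant = v$km_abundance_concordant,
               rna_protein_inverted = v$rna_protein_inverted,
               spearman_km_abundance = v$spearman_km_abundance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res) %||%
    data.frame(operon_id = character(), n_enzymes = integer(),
               km_abundance_concordant = logical(),
               rna_protein_inverted = logical(),
               spearman_km_abundance = numeric(), stringsAsFactors = FALSE)
}
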