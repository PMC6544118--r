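kin_df <- function(genes, k_cat = NA_real_, K_M = NA_real_,
                   org = "Escherichia coli") {
  data.frame(enzyme_gene = genes, k_cat = k_cat, K_M = K_M,
             k_cat_organism = ifelse(is.na(k_cat), NA, org),
             K_M_organism = ifelse(is.na(K_M), NA, org),
             homology_pct = NA_real_, stringsAsFactors = FALSE)
}

chain_graph <- function(enzymes, prefix = "m") {
  n <- length(enzymes)
  pathway_graph(data.frame(substrate = paste0(prefix, 0:(n - 1)),
                           product = paste0(prefix, 1:n),
                           enzyme_gene = enzymes, stringsAsFactors = FALSE))
}

one_operon <- function(genes) {
  data.frame(operon_id = "op1", gene_id = genes, rank = seq_along(genes),
             stringsAsFactors = FALSE)
}

test_that("branch-free candidate selection applies criteria (a)-(c)", {
  g <- chain_graph(c("E1", "E2"))
  kin <- kin_df(c("E1", "E2"), K_M = c(1, 2))
  quant <- c(E1 = 100, E2 = 500)
  expect_equal(as.character(
    branch_free_candidates(one_operon(c("E1", "E2")), quant, g, kin)), "op1")

  # a third reaction consuming the internal metabolite makes it branched
  gb <- pathway_graph(data.frame(
    substrate = c("m0", "m1", "m1"), product = c("m1", "m2", "x"),
    enzyme_gene = c("E1", "E2", "E3")))
  res <- branch_free_candidates(one_operon(c("E1", "E2")), quant, gb, kin)
  expect_length(res, 0)
  expect_match(attr(res, "reasons")$reason, "branched")

  # an unquantified relay enzyme between the quantified ones is fine
  g3 <- chain_graph(c("E1", "Emid", "E2"))
  expect_equal(as.character(
    branch_free_candidates(one_operon(c("E1", "E2")), quant, g3, kin)), "op1")

  # (c): kinetics missing for one enzyme
  kin_miss <- kin_df(c("E1", "E2"), K_M = c(1, NA))
  res_c <- branch_free_candidates(one_operon(c("E1", "E2")), quant, g, kin_miss)
  expect_length(res_c, 0)
  expect_match(attr(res_c, "reasons")$reason, "kinetics")

  # (c): at least one value must come from the reference organism
  kin_yeast <- kin_df(c("E1", "E2"), K_M = c(1, 2),
                      org = "Saccharomyces cerevisiae")
  expect_length(branch_free_candidates(one_operon(c("E1", "E2")), quant, g,
                                       kin_yeast), 0)
  expect_equal(as.character(
    branch_free_candidates(one_operon(c("E1", "E2")), quant, g,
                           kin_yeast, require_reference = FALSE)), "op1")

  # quantified gene absent from the graph
  res_g <- branch_free_candidates(one_operon(c("E1", "EZ")),
                                  c(E1 = 1, EZ = 1), g, kin)
  expect_length(res_g, 0)
  expect_match(attr(res_g, "reasons")$reason, "absent_from_graph")

  expect_error(pathway_graph(data.frame(substrate = "a", product = "a",
                                        enzyme_gene = "E")), "self-loop")
})

# independent oracle: exhaustive path enumeration over enzyme orderings
oracle_branch_free <- function(rx, quantified) {
  if (!all(quantified %in% rx$enzyme_gene)) return(FALSE)
  prod_cnt <- table(rx$product); sub_cnt <- table(rx$substrate)
  # all directed reaction paths r1 -> ... -> rm (DFS, cycle-safe)
  linked <- function(e1, e2) {
    start <- which(rx$enzyme_gene == e1); target <- which(rx$enzyme_gene == e2)
    ok <- FALSE
    dfs <- function(r, internal) {
      m <- rx$product[r]
      if (m %in% internal) return(invisible())    # cycle guard
      internal <- c(internal, m)
      for (r2 in which(rx$substrate == m)) {
        if (r2 == target) {
          if (all(prod_cnt[internal] == 1) && all(sub_cnt[internal] == 1))
            ok <<- TRUE
        } else if (!(rx$enzyme_gene[r2] %in% quantified)) {
          dfs(r2, internal)
        }
      }
    }
    dfs(start, character())
    ok
  }
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (ord in perms(quantified)) {
    pairs_ok <- all(vapply(seq_len(length(ord) - 1),
                           function(i) linked(ord[i], ord[i + 1]), TRUE))
    if (pairs_ok) return(TRUE)
  }
  FALSE
}

test_that("branch-free detection agrees with path-enumeration on random graphs", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(3:6, 1)                     # chain of n reactions
    enz <- sprintf("E%d", 1:n)
    rx <- data.frame(substrate = sprintf("m%d", 0:(n - 1)),
                     product = sprintf("m%d", 1:n),
                     enzyme_gene = enz, stringsAsFactors = FALSE)
    for (b in seq_len(sample(0:2, 1))) {    # random branches off the chain
      m <- sample(sprintf("m%d", 1:(n - 1)), 1)
      if (runif(1) < 0.5)
        rx <- rbind(rx, data.frame(substrate = m, product = sprintf("x%d", b),
                                   enzyme_gene = sprintf("B%d", b)))
      else
        rx <- rbind(rx, data.frame(substrate = sprintf("x%d", b), product = m,
                                   enzyme_gene = sprintf("B%d", b)))
    }
    q <- sample(enz, sample(2:3, 1))
    quant <- setNames(rep(1, length(q)), q)
    kin <- kin_df(q, K_M = seq_along(q))
    got <- length(branch_free_candidates(one_operon(q), quant,
                                         pathway_graph(rx), kin)) == 1
    expect_equal(got, oracle_branch_free(rx, q),
                 info = paste("graph", i, paste(q, collapse = ",")))
  }
})

test_that("kinetic ratios from the shipped fixture match the printed values", {
  kin <- read_quant_table(table1_path(), "kinetics")
  expect_equal(kinetic_ratio(kin, "ArgB", "ArgC", "K_M")$ratio, 3.25)
  expect_equal(kinetic_ratio(kin, "BioC", "BioF", "k_cat")$log10_ratio,
               3.2274, tolerance = 1e-4)
  r <- kinetic_ratio(kin, "ArgB", "ArgB", "K_M")
  expect_equal(r$ratio, 1)
  expect_equal(r$log10_ratio, 0)
  # reciprocal ratios multiply to exactly 1
  expect_equal(kinetic_ratio(kin, "GuaB", "GuaA", "k_cat")$ratio *
                 kinetic_ratio(kin, "GuaA", "GuaB", "k_cat")$ratio, 1)
  expect_error(kinetic_ratio(kin, "AceB", "AceA", "k_cat"), "AceB.*k_cat")
})

test_that("concordance verdicts follow Spearman rank agreement", {
  kin <- kin_df(c("ArgB", "ArgC"), K_M = c(1.3, 0.4))
  v <- concordance(c("ArgB", "ArgC"), c(ArgB = 1000, ArgC = 200),
                   kinetics = kin)
  expect_true(v$km_abundance_concordant)   # higher K_M, higher abundance
  expect_equal(v$spearman_km_abundance, 1)

  kin3 <- kin_df(c("a", "b", "c"), K_M = c(1, 2, 3))
  up <- concordance(c("a", "b", "c"), c(a = 10, b = 20, c = 30),
                    kinetics = kin3)
  expect_equal(up$spearman_km_abundance, 1)
  down <- concordance(c("a", "b", "c"), c(a = 30, b = 20, c = 10),
                      kinetics = kin3)
  expect_equal(down$spearman_km_abundance, -1)
  expect_false(down$km_abundance_concordant)

  # RNA flat but protein differential: inverted rank relation detected
  vr <- concordance(c("a", "b", "c"), c(a = 10, b = 100, c = 1000),
                    quant_rna = c(a = 3, b = 2, c = 1), kinetics = kin3)
  expect_true(vr$rna_protein_inverted)

  expect_error(concordance("a", c(a = 1), kinetics = kin3), "fewer than 2")
})
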