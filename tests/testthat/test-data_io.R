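test_that("quant tables round-trip through TSV with order and fields intact", {
  q <- make_quant_df(c("gA", "gB", "gC"), c(10, 20, 30))
  p <- tempfile(fileext = ".tsv")
  write_quant_table(q, p)
  back <- read_quant_table(p, "protein_quant")
  expect_equal(back$gene_name, c("gA", "gB", "gC"))
  expect_equal(back$intensity, c(10, 20, 30))
  expect_equal(back, q)

  vt <- value_table(c(a = 1.5, b = 0, c = 2.25), "copies")
  p2 <- tempfile(fileext = ".tsv.gz")   # gzip path exercised too
  write_quant_table(vt, p2)
  expect_equal(read_quant_table(p2, "value_table"), vt)
})

test_that("schema violations are rejected with informative errors", {
  q <- make_quant_df("gA", 10)
  q$intensity <- NULL
  p <- tempfile(fileext = ".tsv")
  write_quant_table(q, p)
  expect_error(read_quant_table(p, "protein_quant"), "intensity")

  q2 <- make_quant_df(c("gA", "gB"), c(5, -1))
  p2 <- tempfile(fileext = ".tsv")
  write_quant_table(q2, p2)
  expect_error(read_quant_table(p2, "protein_quant"), "row 2")

  q3 <- make_quant_df(c("gA", "gA"), c(1, 2))
  p3 <- tempfile(fileext = ".tsv")
  write_quant_table(q3, p3)
  expect_error(read_quant_table(p3, "protein_quant"), "duplicate")
})

test_that("the shipped kinetics fixture parses with both parameters for ArgB", {
  kin <- read_quant_table(table1_path(), "kinetics")
  argb <- kin[kin$enzyme_gene == "ArgB", ]
  expect_equal(argb$K_M, 1.3)
  expect_equal(argb$k_cat, 4.9)
  expect_equal(argb$k_cat_organism, "Saccharomyces cerevisiae")
  # every row has at least one kinetic parameter (table invariant)
  expect_true(all(!is.na(kin$k_cat) | !is.na(kin$K_M)))
})

test_that("operon genes are re-ordered into transcript order by strand", {
  ann <- data.frame(gene_id = c("gA", "gB"), start = c(100, 500),
                    end = c(400, 900), strand = "+")
  gff <- write_tiny_gff(ann)
  ops <- write_operon_tsv(list(op1 = c("gB", "gA")))
  res <- read_operon_annotation(ops, gff)
  expect_equal(res$operons$gene_id, c("gA", "gB"))

  ann$strand <- "-"
  res2 <- read_operon_annotation(write_operon_tsv(list(op1 = c("gA", "gB"))),
                                 write_tiny_gff(ann))
  expect_equal(res2$operons$gene_id, c("gB", "gA"))

  # idempotence: re-ordering an already ordered set changes nothing
  again <- order_operons(res2$operons[, c("operon_id", "gene_id")],
                         res2$annotation)
  expect_equal(again$operons, res2$operons)
})

test_that("cross-reference and strand violations are caught", {
  ann <- data.frame(gene_id = c("gA", "gB"), start = c(1, 500),
                    end = c(300, 900), strand = c("+", "+"))
  gff <- write_tiny_gff(ann)
  expect_error(
    read_operon_annotation(write_operon_tsv(list(op1 = c("gA", "gX"))), gff),
    "gX")
  ann2 <- ann; ann2$strand <- c("+", "-")
  expect_error(
    read_operon_annotation(write_operon_tsv(list(op1 = c("gA", "gB"))),
                           write_tiny_gff(ann2)),
    "strand")
})

test_that("confidence filters apply the peptide-evidence thresholds", {
  q <- make_quant_df(c("g1", "g2", "g3", "g4"), rep(1, 4),
                     unique_peptides = c(1L, 1L, 2L, 0L),
                     peplen = c(6L, 7L, 7L, 10L))
  relaxed <- suppressMessages(filter_confident(q, "relaxed"))
  stringent <- suppressMessages(filter_confident(q, "stringent"))
  expect_equal(relaxed$gene_name, c("g1", "g2", "g3"))   # >=1 peptide, >=6 aa
  expect_equal(stringent$gene_name, "g3")                # >=2 peptides, >=7 aa
  expect_equal(attr(stringent, "n_removed"), 3L)
})

test_that("stringent filter output is a subset of relaxed for random evidence", {
  set.seed(101)
  for (i in 1:5) {
    q <- make_quant_df(sprintf("g%03d", 1:50), runif(50),
                       unique_peptides = sample(0:4, 50, TRUE),
                       peplen = sample(5:10, 50, TRUE))
    r <- suppressMessages(filter_confident(q, "relaxed"))
    s <- suppressMessages(filter_confident(q, "stringent"))
    expect_true(all(s$gene_name %in% r$gene_name))
  }
})

test_that("sequence coverage counts all match positions, overlaps once", {
  expect_equal(sequence_coverage("ABC", "ABCDEF"), 0.5)
  expect_equal(sequence_coverage(c("ABC", "CDE"), "ABCDEF"), 5 / 6)
  expect_equal(sequence_coverage(character(), "ABCDEF"), 0)
  expect_equal(sequence_coverage("AB", "ABXAB"), 4 / 5)     # repeats counted
  expect_warning(out <- sequence_coverage("ABCDEFGH", "ABC"), "longer")
  expect_equal(out, 0)

  # brute-force position-marking oracle on random sequences
  set.seed(7)
  alph <- c("A", "C", "D", "E")
  for (i in 1:10) {
    prot <- paste(sample(alph, 30, TRUE), collapse = "")
    peps <- vapply(1:3, function(j) {
      st <- sample(1:25, 1); substr(prot, st, st + sample(2:5, 1))
    }, "")
    mark <- logical(30)
    for (p in peps) {
      w <- nchar(p)
      for (s in 1:(30 - w + 1))
        if (substr(prot, s, s + w - 1) == p) mark[s:(s + w - 1)] <- TRUE
    }
    expect_equal(sequence_coverage(peps, prot), mean(mark))
  }
})
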