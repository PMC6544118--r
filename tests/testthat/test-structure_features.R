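iv_fixture <- function(starts, ends, strand = "+") {
  n <- length(starts)
  ids <- sprintf("g%d", seq_len(n))
  ord <- if (strand == "+") order(starts) else order(-starts)
  list(operons = data.frame(operon_id = "op1", gene_id = ids[ord],
                            rank = seq_len(n), stringsAsFactors = FALSE),
       annotation = data.frame(gene_id = ids, contig = "chr", start = starts,
                               end = ends, strand = strand,
                               stringsAsFactors = FALSE))
}

test_that("gene intervals follow the stop-exclusive start-inclusive convention", {
  # 1-based inclusive on disk: genes 1-300 and 301-600 abut
  f <- iv_fixture(c(1, 301), c(300, 600))
  expect_equal(gene_intervals(f$operons, f$annotation)$interval_nt, 0L)
  f40 <- iv_fixture(c(1, 341), c(300, 600))
  expect_equal(gene_intervals(f40$operons, f40$annotation)$interval_nt, 40L)
  fov <- iv_fixture(c(1, 297), c(300, 600))
  expect_equal(gene_intervals(fov$operons, fov$annotation)$interval_nt, -4L)

  # minus strand mirror of the 40-nt case
  fm <- iv_fixture(c(1, 341), c(300, 600), strand = "-")
  ivm <- gene_intervals(fm$operons, fm$annotation)
  expect_equal(ivm$interval_nt, 40L)
  expect_equal(ivm$upstream_gene, "g2")   # transcript starts at the right

  bad <- f; bad$operons$gene_id[2] <- "missing"
  expect_error(gene_intervals(bad$operons, bad$annotation), "missing")
})

test_that("intervals are translation- and strand-mirror-invariant", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    len <- sample(90:600, n)
    gaps <- sample(-20:120, n - 1, replace = TRUE)
    starts <- cumsum(c(1, len[-n] + gaps))
    ends <- starts + len - 1
    f <- iv_fixture(starts, ends)
    iv <- gene_intervals(f$operons, f$annotation)$interval_nt
    expect_equal(iv, gaps)

    shift <- sample(1:10000, 1)
    ft <- iv_fixture(starts + shift, ends + shift)
    expect_equal(gene_intervals(ft$operons, ft$annotation)$interval_nt, iv)

    # reflect the contig and flip strand: intervals preserved
    L <- max(ends) + 50
    fr <- iv_fixture(L + 1 - ends, L + 1 - starts, strand = "-")
    expect_equal(gene_intervals(fr$operons, fr$annotation)$interval_nt, iv)

    # sum of intervals equals the span not covered by genes (coordinate oracle)
    expect_equal(sum(iv), (max(ends) - min(starts) + 1) - sum(len))
  }
})

test_that("scanning classification uses a strict 40-nt threshold", {
  expect_equal(scanning_class(39), "coupled_70S_scanning")
  expect_equal(scanning_class(40), "independent_initiation")
  expect_equal(scanning_class(-10), "coupled_70S_scanning")
  expect_equal(scanning_class(c(0, 100), footprint_nt = 50),
               c("coupled_70S_scanning", "independent_initiation"))
})

test_that("CV-vs-size regression matches closed forms", {
  rec <- function(sz, cv) data.frame(operon_id = sprintf("o%d", seq_along(sz)),
                                     n_quantified = sz, cv_percent = cv,
                                     size_group = "2", source = "real")
  flat <- cv_vs_size_regression(rec(c(2, 3, 4, 5), rep(12, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  line <- cv_vs_size_regression(rec(c(2, 3, 4, 5), 10 * c(2, 3, 4, 5)))
  expect_equal(line$slope, 10, tolerance = 1e-10)
  expect_equal(line$r_squared, 1, tolerance = 1e-10)

  # closed form slope = cov(x, y) / var(x)
  set.seed(43)
  x <- sample(2:8, 20, TRUE); y <- runif(20, 10, 80)
  r <- cv_vs_size_regression(rec(x, y))
  expect_equal(r$slope, cov(x, y) / var(x), tolerance = 1e-12)

  expect_error(cv_vs_size_regression(rec(rep(3, 5), runif(5))), "degenerate")
})

test_that("staircase amplitude growing with length gives a positive CV slope", {
  set.seed(44)
  sz <- sample(2:6, 60, TRUE)
  cv <- vapply(sz, function(n)
    operon_cv(0.5^(seq_len(n) - 1) * 10^rnorm(n, 3, 0.05)), 0)
  rec <- data.frame(operon_id = sprintf("o%d", 1:60), n_quantified = sz,
                    cv_percent = cv, size_group = "2", source = "real")
  r <- cv_vs_size_regression(rec)
  expect_gt(r$slope, 0)
  expect_lt(r$p_value, 0.05)
})

test_that("RNA-protein correlation is computed on shared log-scale genes", {
  v <- setNames(10^runif(50, 1, 5), sprintf("g%02d", 1:50))
  expect_equal(rna_protein_correlation(v, v)$r_squared, 1)

  set.seed(45)
  rna <- setNames(10^rnorm(1000, 2, 1), sprintf("g%04d", 1:1000))
  prot <- setNames(10^rnorm(1000, 2, 1), sprintf("g%04d", 1:1000))
  expect_lt(rna_protein_correlation(rna, prot)$r_squared, 0.02)

  expect_error(rna_protein_correlation(c(a = 1), c(a = 2)), ">= 3")
})

test_that("pairwise Mann-Whitney matrix is symmetric with masked small groups", {
  set.seed(46)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30) + 10, tiny = 1:2)
  expect_warning(m <- pairwise_mwu_matrix(g), "tiny")
  expect_true(all(is.na(m["tiny", ])))
  expect_true(is.na(m["a", "a"]))
  expect_equal(m["a", "c"], m["c", "a"])
  expect_lt(m["a", "c"], 0.01)
  expect_lt(m["b", "c"], 0.01)
  expect_gt(m["a", "b"], 0.001)   # identically drawn groups

  m2 <- suppressWarnings(pairwise_mwu_matrix(list(x = 1:10, y = 1:10)))
  expect_gt(m2["x", "y"], 0.9)
})
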