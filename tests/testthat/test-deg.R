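make_labels <- function(n_case, n_control)
  rep(c("case", "control"), c(n_case, n_control))

test_that("probe collapsing keeps the largest-|logFC| probe per gene", {
  labels <- make_labels(2, 2)
  # one probe per gene: identity rekey
  x <- rbind(p1 = c(1, 2, 3, 4), p2 = c(5, 5, 5, 5))
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("GA", "GB"))
  out <- collapse_probes(x, map, labels)
  expect_identical(rownames(out), c("GA", "GB"))
  expect_identical(as.vector(out), as.vector(x))

  # |logFC| 1.2 vs 0.3: the 1.2 probe wins
  x <- rbind(p1 = c(1.2, 1.2, 0, 0), p2 = c(0.3, 0.3, 0, 0))
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("G", "G"))
  out <- collapse_probes(x, map, labels)
  expect_identical(unname(attr(out, "probe")), "p1")

  # exact tie: lexicographically smaller probe id wins
  x <- rbind(pB = c(1, 1, 0, 0), pA = c(0, 0, 1, 1))
  map <- data.frame(probe_id = c("pA", "pB"), gene_id = c("G", "G"))
  out <- collapse_probes(x, map, labels)
  expect_identical(unname(attr(out, "probe")), "pA")

  # unmapped probes are dropped with a message
  x <- rbind(p1 = c(1, 1, 0, 0), px = c(9, 9, 9, 9))
  map <- data.frame(probe_id = "p1", gene_id = "G")
  expect_message(out <- collapse_probes(x, map, labels), "1 unmapped")
  expect_identical(rownames(out), "G")
})

test_that("constant-barcode filtering drops genes constant in any cohort", {
  a <- rbind(g1 = c(1, 1, 1), g2 = c(1, 0, 1), g3 = c(0, 0, 0),
             g4 = c(0, 1, 0), g5 = c(1, 1, 0))
  b <- rbind(g1 = c(1, 0, 1, 0), g2 = c(0, 1, 1, 0), g3 = c(1, 0, 0, 0),
             g4 = c(1, 1, 1, 1), g5 = c(0, 1, 1, 1))
  flt <- filter_constant_barcodes(list(A = a, B = b))
  # g1 all-1 in A, g3 all-0 in A, g4 all-1 in B: 3 genes removed by hand
  expect_identical(flt$retained, c("g2", "g5"))
  expect_setequal(flt$report$gene_id, c("g1", "g3", "g4"))
  expect_identical(flt$report$reason[flt$report$gene_id == "g1"], "all_one")

  rownames(b) <- paste0("x", 1:5)
  expect_error(filter_constant_barcodes(list(a, b)), "no gene identifiers")
})

test_that("contingency tables count expressed/silenced by group", {
  expect_identical(gene_contingency(rep(1, 5), make_labels(3, 2)),
                   c(a = 3L, b = 0L, c = 2L, d = 0L))
  expect_identical(gene_contingency(rep(0, 5), make_labels(3, 2)),
                   c(a = 0L, b = 3L, c = 0L, d = 2L))
  expect_identical(gene_contingency(c(1, 0, 1, 0, 1), make_labels(2, 3)),
                   c(a = 1L, b = 1L, c = 2L, d = 1L))
  expect_error(gene_contingency(c(1, 0), c("case", "case")), "two levels")
})

test_that("fisher_exact matches the enumeration oracle and conventions", {
  # identical proportions: p = 1
  expect_equal(fisher_exact(c(5, 5, 5, 5)), 1.0)
  # hand-enumerable table with margins (4,4)/(4,4)
  expect_equal(fisher_exact(c(3, 1, 1, 3)),
               enumerate_fisher(3, 1, 1, 3), tolerance = 1e-12)
  # the printed-counts overlap table (universe 8392, sets 2114 and 36)
  expect_equal(fisher_exact(c(15, 2099, 21, 6257)),
               enumerate_fisher(15, 2099, 21, 6257), tolerance = 1e-9)
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("fisher_exact is invariant to transposition and label swaps", {
  tb <- c(7, 3, 2, 9)
  # swap rows with columns (transpose)
  expect_equal(fisher_exact(tb), fisher_exact(c(7, 2, 3, 9)))
  # swap both group and barcode labels simultaneously
  expect_equal(fisher_exact(tb), fisher_exact(c(9, 2, 3, 7)))
})

test_that("odds ratios follow the uncorrected zero-cell conventions", {
  expect_equal(odds_ratio(c(2, 2, 2, 2)), 1.0)
  expect_equal(odds_ratio(c(4, 1, 2, 3)), 6.0)
  expect_identical(odds_ratio(c(0, 5, 3, 7)), 0)
  expect_identical(odds_ratio(c(5, 0, 3, 7)), Inf)
  expect_warning(val <- odds_ratio(c(0, 3, 0, 4)), "undefined")
  expect_true(is.na(val))
  # group swap inverts a finite nonzero OR
  expect_equal(odds_ratio(c(4, 1, 2, 3)) * odds_ratio(c(2, 3, 4, 1)), 1.0)
})

test_that("bh_fdr implements the step-up adjustment", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:5) {
    p <- stats::runif(50)
    q <- bh_fdr(p)
    expect_equal(q, step_up_bh(p))
    expect_true(all(q >= p) && all(q <= 1))
  }
  expect_error(bh_fdr(c(0.1, NaN, 0.2)), "indices: 2")
})

test_that("bh_fdr is monotone in its input", {
  set.seed(12)
  p <- sort(stats::runif(30))
  p2 <- pmin(p + 0.05, 1)
  expect_true(all(bh_fdr(p2) >= bh_fdr(p)))
})

test_that("identify_degs calls extreme separation with direction and OR", {
  set.seed(13)
  bc <- rbind(gA = c(rep(1, 30), rep(0, 30)),
              gB = stats::rbinom(60, 1, 0.5),
              gC = stats::rbinom(60, 1, 0.5))
  colnames(bc) <- paste0("s", 1:60)
  degs <- identify_degs(bc, make_labels(30, 30))
  gA <- degs[degs$gene_id == "gA", ]
  expect_true(gA$is_deg)
  expect_identical(gA$direction, "expressed-higher-in-case")
  expect_identical(gA$odds_ratio, Inf)
  expect_true(all(degs$fdr >= degs$p_value))
})

test_that("identify_degs is equivariant under sample permutation", {
  co <- simulate_cohort(simulation_config(40, 20, 20, deg_fraction = 0.2,
                                          p_effect = 0.5, seed = 14))
  d1 <- identify_degs(co$true_barcode, co$labels)
  set.seed(15)
  perm <- sample(ncol(co$true_barcode))
  d2 <- identify_degs(co$true_barcode[, perm], co$labels[perm])
  expect_equal(d1, d2)
})
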