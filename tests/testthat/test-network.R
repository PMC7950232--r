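test_that("spearman_matrix matches rank-then-Pearson, ties included", {
  x <- rbind(gA = c(1, 2, 3, 4, 5, 6),
             gB = c(2, 4, 6, 8, 10, 12),     # monotone with gA
             gC = c(6, 5, 4, 3, 2, 1),       # reversed
             gD = c(1, 1, 2, 5, 4, 3))       # has a tie
  colnames(x) <- paste0("s", 1:6)
  sp <- spearman_matrix(x)
  expect_equal(sp$rho["gA", "gB"], 1)
  expect_equal(sp$rho["gA", "gC"], -1)
  # oracle: product-moment correlation of average ranks
  expect_equal(sp$rho["gA", "gD"],
               stats::cor(rank(x["gA", ]), rank(x["gD", ])))
  # p from the t approximation == Pearson test on the ranks
  ref <- stats::cor.test(rank(x["gA", ]), rank(x["gD", ]))$p.value
  expect_equal(sp$p["gA", "gD"], ref)
  expect_true(isSymmetric(sp$rho))
  expect_true(all(is.na(diag(sp$p))))
})

test_that("rank correlation is invariant under monotone transforms", {
  set.seed(21)
  x <- matrix(rnorm(4 * 12), 4, dimnames = list(paste0("g", 1:4), NULL))
  colnames(x) <- paste0("s", 1:12)
  sp1 <- spearman_matrix(x)
  x2 <- exp(x); x2[2, ] <- x2[2, ]^3
  sp2 <- spearman_matrix(x2)
  expect_equal(sp1$rho, sp2$rho)
})

test_that("constant genes produce missing correlations, excluded from FDR", {
  x <- rbind(gA = c(1, 2, 3, 4, 5), gB = c(2, 2, 2, 2, 2),
             gC = c(5, 3, 4, 1, 2))
  colnames(x) <- paste0("s", 1:5)
  sp <- spearman_matrix(x)
  expect_true(all(is.na(sp$rho["gB", ])))
  net <- build_network(sp$rho, sp$p, rho_cutoff = 0, fdr_cutoff = 1)
  tested <- net$pairs[is.finite(net$pairs$p), ]
  expect_identical(nrow(tested), 1L)   # only gA-gC is testable
})

test_that("edges require both a strict rho and a strict FDR threshold", {
  nm <- paste0("g", 1:3)
  rho <- matrix(c(1, 0.39, 0.5, 0.39, 1, -0.8, 0.5, -0.8, 1), 3,
                dimnames = list(nm, nm))
  p <- matrix(c(NA, 1e-4, 1e-3, 1e-4, NA, 1e-5, 1e-3, 1e-5, NA), 3,
              dimnames = list(nm, nm))
  net <- build_network(rho, p)
  keys <- paste(net$edges$gene1, net$edges$gene2)
  expect_false("g1 g2" %in% keys)       # rho 0.39 not > 0.4
  expect_setequal(keys, c("g1 g3", "g2 g3"))
})

test_that("the network equals a brute-force filter over all pairs", {
  set.seed(22)
  co <- simulate_cohort(simulation_config(5, 8, 7, seed = 23))
  sp <- spearman_matrix(co$expression)
  net <- build_network(sp$rho, sp$p, rho_cutoff = 0.3, fdr_cutoff = 0.2)
  ids <- rownames(sp$rho)
  pairs <- utils::combn(ids, 2)
  pvec <- apply(pairs, 2, function(pr) sp$p[pr[1], pr[2]])
  fdr <- stats::p.adjust(pvec, "BH")
  expected <- apply(pairs, 2, function(pr) sp$rho[pr[1], pr[2]])
  keep <- abs(expected) > 0.3 & fdr < 0.2
  got <- paste(net$edges$gene1, net$edges$gene2)
  want <- paste(pairs[1, keep], pairs[2, keep])
  expect_setequal(got, want)
})

toy_network <- function(nodes, edges_df) {
  structure(list(nodes = nodes, edges = edges_df, pairs = edges_df,
                 rho_cutoff = 0.4, fdr_cutoff = 0.05, group_meta = ""),
            class = "coexpression_network")
}

edge_df <- function(g1, g2) {
  data.frame(gene1 = g1, gene2 = g2, rho = rep(0.5, length(g1)),
             p = rep(1e-4, length(g1)), fdr = rep(1e-3, length(g1)),
             stringsAsFactors = FALSE)
}

test_that("network comparison is plain set arithmetic on edges", {
  nodes <- c("A", "B", "C", "D")
  ref <- toy_network(nodes, edge_df(c("A", "B"), c("B", "C")))
  tgt <- toy_network(nodes, edge_df(c("B", "C"), c("C", "D")))
  d <- compare_networks(ref, tgt)
  expect_identical(paste(d$gained$gene1, d$gained$gene2), "C D")
  expect_identical(paste(d$lost$gene1, d$lost$gene2), "A B")
  expect_identical(paste(d$retained$gene1, d$retained$gene2), "B C")

  same <- compare_networks(ref, ref)
  expect_identical(nrow(same$gained), 0L)
  expect_identical(nrow(same$lost), 0L)
  expect_identical(nrow(same$retained), 2L)

  empty <- toy_network(nodes, edge_df(character(0), character(0)))
  d2 <- compare_networks(ref, empty)
  expect_identical(nrow(d2$lost), 2L)
  expect_identical(nrow(d2$gained) + nrow(d2$retained), 0L)

  expect_error(compare_networks(ref, toy_network(c("A", "B"),
                                                 ref$edges[0, ])), "differ")
})

test_that("diff identities hold on randomized toy networks", {
  nodes <- paste0("g", 1:8)
  all_pairs <- utils::combn(nodes, 2)
  rand_net <- function(seed) {
    set.seed(seed)
    k <- sample(0:ncol(all_pairs), 1)
    sel <- sample(ncol(all_pairs), k)
    toy_network(nodes, edge_df(all_pairs[1, sel], all_pairs[2, sel]))
  }
  for (seed in 1:20) {
    ref <- rand_net(seed); tgt <- rand_net(seed + 100)
    d <- compare_networks(ref, tgt)
    key <- function(df) paste(df$gene1, df$gene2)
    # pairwise disjoint
    expect_length(intersect(key(d$gained), key(d$lost)), 0)
    expect_length(intersect(key(d$gained), key(d$retained)), 0)
    expect_length(intersect(key(d$lost), key(d$retained)), 0)
    # unions reconstruct each side
    expect_setequal(c(key(d$gained), key(d$retained)), key(tgt$edges))
    expect_setequal(c(key(d$lost), key(d$retained)), key(ref$edges))
    # swapping reference and target swaps gained and lost
    d2 <- compare_networks(tgt, ref)
    expect_setequal(key(d2$gained), key(d$lost))
    expect_setequal(key(d2$lost), key(d$gained))
    expect_setequal(key(d2$retained), key(d$retained))
  }
})

test_that("exact permutation p-values are offered for tiny samples", {
  x <- rbind(gA = c(3, 1, 4, 2, 5), gB = c(2, 7, 1, 8, 3))
  colnames(x) <- paste0("s", 1:5)
  sp <- spearman_matrix(x, exact = TRUE)
  ref <- stats::cor.test(x["gA", ], x["gB", ], method = "spearman",
                         exact = TRUE)$p.value
  expect_equal(sp$p["gA", "gB"], ref)
})
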