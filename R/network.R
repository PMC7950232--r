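#' Spearman correlation and p-value matrices for a gene panel
#'
#' Rank-transforms each gene (average ranks on ties) and correlates the
#' ranks (product-moment), giving Spearman's \eqn{\rho}; p-values come
#' from the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' \eqn{n - 2} degrees of freedom, or from the exact permutation
#' distribution when `exact = TRUE` (recommended for n < 10, where the t
#' approximation degrades).  Genes constant within the group have
#' undefined correlations; their entries are `NA` and are excluded from
#' downstream FDR adjustment.
#'
#' @param x log2 expression matrix (genes x samples) already restricted to
#'   the panel and one sample group.
#' @param exact logical; exact permutation p-values (all n! rank orders
#'   via [stats::cor.test]'s exact machinery) instead of the t
#'   approximation.
#' @return List with `rho` and `p` (symmetric gene x gene matrices;
#'   `diag(rho) = 1`, `diag(p) = NA`), and `n` (sample count).
#' @examples
#' cohort <- simulate_cohort(simulation_config(5, 10, 10, seed = 5))
#' sp <- spearman_matrix(cohort$expression)
#' round(sp$rho, 2)
#' @export
spearman_matrix <- function(x, exact = FALSE) {
  stop_if_not_matrix(x, "panel expression")
  if (ncol(x) < 4) stop("need at least 4 samples")
  if (nrow(x) < 2) stop("need at least 2 panel genes")
  n <- ncol(x)
  const <- apply(x, 1, function(r) diff(range(r)) == 0)
  ranks <- t(apply(x, 1, rank))          # average ranks on ties
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  if (exact) {
    p <- matrix(NA_real_, nrow(x), nrow(x), dimnames = dimnames(rho))
    for (i in seq_len(nrow(x) - 1L)) for (j in (i + 1L):nrow(x)) {
      if (!const[i] && !const[j]) {
        p[i, j] <- p[j, i] <- suppressWarnings(
          stats::cor.test(x[i, ], x[j, ], method = "spearman",
                          exact = TRUE)$p.value)
      }
    }
  } else {
    r2 <- pmin(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1] <- 0
  }
  diag(p) <- NA
  dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p, n = n)
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Benjamini-Hochberg adjusts the p-values of all unordered off-diagonal
#' pairs with a defined correlation (one multiple-testing family per
#' panel/group matrix), then connects a pair iff \eqn{|\rho| >}
#' `rho_cutoff` (strict) and FDR < `fdr_cutoff` (strict).
#'
#' @param rho,p symmetric matrices from [spearman_matrix()].
#' @param rho_cutoff absolute-correlation threshold (default 0.4).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param group_meta optional free-text label (cohort/group) carried in
#'   the result.
#' @return An object of class `"coexpression_network"`: `nodes`
#'   (character), `edges` (data.frame `gene1`, `gene2`, `rho`, `p`, `fdr`,
#'   with `gene1 < gene2`), `pairs` (all tested pairs with their FDR),
#'   thresholds and `group_meta`.
#' @export
build_network <- function(rho, p, rho_cutoff = 0.4, fdr_cutoff = 0.05,
                          group_meta = "") {
  stopifnot(is.matrix(rho), is.matrix(p), all(dim(rho) == dim(p)),
            nrow(rho) == ncol(rho))
  if (!isTRUE(all.equal(rho, t(rho), check.attributes = FALSE)))
    stop("rho matrix must be symmetric")
  nodes <- rownames(rho)
  if (is.null(nodes)) nodes <- paste0("g", seq_len(nrow(rho)))
  ut <- upper.tri(rho)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                      rho = rho[ut], p = p[ut], stringsAsFactors = FALSE)
  defined <- is.finite(pairs$p)
  pairs$fdr <- NA_real_
  if (any(defined)) pairs$fdr[defined] <- bh_fdr(pairs$p[defined])
  is_edge <- defined & abs(pairs$rho) > rho_cutoff & pairs$fdr < fdr_cutoff
  edges <- pairs[is_edge, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 rho_cutoff = rho_cutoff, fdr_cutoff = fdr_cutoff,
                 group_meta = group_meta),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "Co-expression network%s: %d nodes, %d edges (|rho| > %g, FDR < %g)\n",
    if (nzchar(x$group_meta)) paste0(" [", x$group_meta, "]") else "",
    length(x$nodes), nrow(x$edges), x$rho_cutoff, x$fdr_cutoff))
  invisible(x)
}

# canonical "gene1|gene2" keys with gene1 < gene2
edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  g1 <- pmin(edges$gene1, edges$gene2)
  g2 <- pmax(edges$gene1, edges$gene2)
  paste(g1, g2, sep = "|")
}

#' Gained, lost and retained edges between two networks
#'
#' Set arithmetic on unordered edges over a common node set: `gained` are
#' edges present in `target` but not `reference`, `lost` the reverse,
#' `retained` the intersection — the vocabulary used to describe
#' connectivity change between disease and control co-expression networks.
#'
#' @param reference,target `"coexpression_network"` objects on the same
#'   node set.
#' @return A list of class `"network_diff"` with data.frames `gained`,
#'   `lost`, `retained` (edge rows carry the rho/fdr of the network they
#'   belong to; `retained` carries the target's).
#' @export
compare_networks <- function(reference, target) {
  stopifnot(inherits(reference, "coexpression_network"),
            inherits(target, "coexpression_network"))
  if (!setequal(reference$nodes, target$nodes))
    stop("node sets differ; symmetric difference: ",
         paste(utils::head(c(setdiff(reference$nodes, target$nodes),
                             setdiff(target$nodes, reference$nodes)), 10),
               collapse = ", "))
  kr <- edge_keys(reference$edges)
  kt <- edge_keys(target$edges)
  structure(list(
    gained = target$edges[!(kt %in% kr), , drop = FALSE],
    lost = reference$edges[!(kr %in% kt), , drop = FALSE],
    retained = target$edges[kt %in% kr, , drop = FALSE]),
    class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf("Network diff: %d gained, %d lost, %d retained\n",
              nrow(x$gained), nrow(x$lost), nrow(x$retained)))
  invisible(x)
}
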