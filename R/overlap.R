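#' Test the overlap of two gene sets against a shared universe
#'
#' Builds the 2x2 partition of the universe by membership in set A and set
#' B — \eqn{(|A \cap B|, |A \setminus B|, |B \setminus A|,
#' |U \setminus (A \cup B)|)} — and applies the two-sided Fisher exact test.
#' The universe should contain only genes that *could* have appeared in
#' either set (here: genes surviving the constant-barcode filter in both
#' cohorts); an inflated universe overstates significance.
#'
#' @param set_a,set_b character vectors of identifiers, subsets of
#'   `universe`.
#' @param universe character vector of all testable identifiers.
#' @return A list of class `"overlap_result"`: `n_a`, `n_b`, `n_overlap`,
#'   `universe` (its size), `table` (named `(a, b, c, d)` counts),
#'   `p_value` (two-sided), `p_one_sided` (enrichment direction),
#'   `odds_ratio`, `shared_ids` (sorted).
#' @examples
#' u <- sprintf("g%04d", 1:200)
#' overlap_test(u[1:30], u[25:40], u)
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("sets must be subsets of the universe; offenders: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  shared <- sort(intersect(set_a, set_b))
  a <- length(shared)
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  tb <- c(a = a, b = b, c = cc, d = d)
  # an empty set (or a set equal to the universe) fixes a zero margin:
  # the conditional distribution is degenerate and the exact p is 1
  degenerate_margin <- a + b == 0 || cc + d == 0 || a + cc == 0 ||
    b + d == 0
  structure(list(
    n_a = length(set_a), n_b = length(set_b), n_overlap = a,
    universe = length(universe), table = tb,
    p_value = if (degenerate_margin) 1 else fisher_exact(tb),
    p_one_sided = if (degenerate_margin) 1 else
      fisher_exact(tb, alternative = "greater"),
    odds_ratio = if (a * d == 0 && b * cc == 0) NA_real_ else odds_ratio(tb),
    shared_ids = shared), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Set overlap: |A| = %d, |B| = %d, shared = %d, universe = %d\n",
    x$n_a, x$n_b, x$n_overlap, x$universe))
  cat(sprintf("  Fisher exact p = %.4g (two-sided), %.4g (one-sided), OR = %.4g\n",
              x$p_value, x$p_one_sided, x$odds_ratio))
  invisible(x)
}

#' Two-set Venn partition counts
#'
#' @param result an [overlap_test()] result.
#' @return Named vector `(a_only, b_only, both)`; the three disjoint
#'   counts sum to \eqn{|A \cup B|}.
#' @examples
#' u <- sprintf("g%04d", 1:100)
#' venn_summary(overlap_test(u[1:20], u[15:30], u))
#' @export
venn_summary <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  c(a_only = unname(result$table["b"]),
    b_only = unname(result$table["c"]),
    both = unname(result$table["a"]))
}
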