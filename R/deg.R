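# Binarized differential expression: contingency tables on barcode calls,
# exact tests, BH control, probe collapsing and the constant-barcode filter.

# Accepts c(a, b, c, d) (case-expressed, case-silenced, control-expressed,
# control-silenced) or a 2x2 matrix with groups in rows; returns the vector.
as_contingency <- function(table) {
  if (is.matrix(table)) {
    stopifnot(nrow(table) == 2L, ncol(table) == 2L)
    table <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  }
  if (length(table) != 4L || any(!is.finite(table)) || any(table < 0) ||
      any(table != round(table)))
    stop("contingency table must be 4 nonnegative counts (a, b, c, d)")
  stats::setNames(as.integer(table), c("a", "b", "c", "d"))
}

#' Collapse probe-level rows to genes by largest fold change
#'
#' When several probes map to the same gene, the probe with the largest
#' absolute log fold change between groups (difference of group means of
#' the log2 values) is retained; ties go to the lexicographically smallest
#' probe identifier.  Probes absent from the map are dropped with a
#' message.
#'
#' @param x probe-level log2 expression matrix (probes in rows).
#' @param probe_map data.frame with columns `probe_id`, `gene_id`.
#' @param labels two-level group vector, one entry per column of `x`.
#' @param case_level optional label value to treat as the case group.
#' @return Gene-level expression matrix keyed by gene identifier, with a
#'   `"probe"` attribute recording the retained probe per gene.
#' @examples
#' x <- rbind(p1 = c(1, 1, 5, 5), p2 = c(2, 2, 3, 3))
#' map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("G", "G"))
#' collapse_probes(x, map, c("case", "case", "control", "control"))
#' @export
collapse_probes <- function(x, probe_map, labels, case_level = NULL) {
  stop_if_not_matrix(x, "probe-level expression")
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  f <- as_group_factor(labels, case_level)
  if (length(f) != ncol(x)) stop("labels length must match sample count")
  mapped <- rownames(x) %in% probe_map$probe_id
  if (!all(mapped))
    message("dropping ", sum(!mapped), " unmapped probe(s)")
  x <- x[mapped, , drop = FALSE]
  if (!nrow(x)) stop("no probes left after mapping")
  gene <- probe_map$gene_id[match(rownames(x), probe_map$probe_id)]
  is_case <- f == case_level_of(f)
  lfc <- rowMeans(x[, is_case, drop = FALSE]) -
    rowMeans(x[, !is_case, drop = FALSE])
  # per gene: max |logFC|, ties to the smallest probe id
  ord <- order(gene, -abs(lfc), rownames(x))
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(match(gene[keep], unique(gene)))]
  out <- x[keep, , drop = FALSE]
  probes <- rownames(out)
  rownames(out) <- gene[keep]
  attr(out, "probe") <- stats::setNames(probes, rownames(out))
  out
}

#' Drop genes with constant barcode in any cohort
#'
#' A gene is informative for proportion-based testing only if its barcode
#' row contains both expressed and silenced calls.  Given one barcode
#' matrix per cohort, a gene is retained iff in *every* cohort its row has
#' both a 0 and a 1; the survivors form the shared testing universe.
#'
#' @param barcodes named list of 0/1 barcode matrices sharing a gene
#'   namespace (rownames).
#' @return A list with `retained` (character vector of gene ids, in the
#'   order of the first matrix) and `report` (data.frame: `gene_id`,
#'   `cohort`, `reason` — `"all_zero"` or `"all_one"` — one row per
#'   removal cause).
#' @export
filter_constant_barcodes <- function(barcodes) {
  if (is.matrix(barcodes)) barcodes <- list(barcodes)
  stopifnot(length(barcodes) >= 1)
  if (is.null(names(barcodes)))
    names(barcodes) <- paste0("cohort", seq_along(barcodes))
  common <- Reduce(intersect, lapply(barcodes, rownames))
  if (!length(common))
    stop("cohorts share no gene identifiers")
  constant <- lapply(names(barcodes), function(nm) {
    b <- barcodes[[nm]][common, , drop = FALSE]
    rs <- rowSums(b)
    data.frame(gene_id = common,
               cohort = nm,
               reason = ifelse(rs == 0, "all_zero",
                               ifelse(rs == ncol(b), "all_one", "ok")),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, constant)
  report <- report[report$reason != "ok", , drop = FALSE]
  rownames(report) <- NULL
  list(retained = setdiff(common, report$gene_id), report = report)
}

#' Expressed/silenced contingency table for one gene
#'
#' @param barcode_row 0/1 vector of barcode calls for one gene.
#' @param labels two-level group vector of the same length.
#' @param case_level optional label value to treat as the case group.
#' @return Named integer vector `(a, b, c, d)` = (case expressed, case
#'   silenced, control expressed, control silenced).
#' @examples
#' gene_contingency(c(1, 0, 1, 0, 1), c("case", "case", "control",
#'                                      "control", "control"))
#' @export
gene_contingency <- function(barcode_row, labels, case_level = NULL) {
  if (length(barcode_row) != length(labels))
    stop("barcode row and labels differ in length")
  if (!all(barcode_row %in% c(0, 1)))
    stop("barcode row must be 0/1")
  f <- as_group_factor(labels, case_level)
  if (any(table(f) == 0)) stop("one group is empty")
  is_case <- f == case_level_of(f)
  c(a = sum(barcode_row == 1 & is_case),
    b = sum(barcode_row == 0 & is_case),
    c = sum(barcode_row == 1 & !is_case),
    d = sum(barcode_row == 0 & !is_case))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional (hypergeometric) p-value; the two-sided p sums the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7 for float ties) — the convention of [stats::fisher.test],
#' which this wraps.
#'
#' @param table counts `(a, b, c, d)` or a 2x2 matrix (groups in rows).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact(c(15, 2099, 21, 6257))  # ~0.033
#' @export
fisher_exact <- function(table,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tb <- as_contingency(table)
  if (tb["a"] + tb["b"] < 1 || tb["c"] + tb["d"] < 1)
    stop("each group must contain at least one observation")
  m <- matrix(tb, nrow = 2, byrow = TRUE)
  # fisher.test can exceed 1 by a few ulps when summing point probabilities
  min(stats::fisher.test(m, alternative = alternative)$p.value, 1)
}

#' Sample odds ratio of a 2x2 table
#'
#' The cross-product ratio \eqn{ad/bc} with the uncorrected zero-cell
#' conventions: 0 when the numerator alone vanishes, `Inf` when the
#' denominator alone vanishes, and `NA` (undefined) when both do.  No
#' Haldane-Anscombe continuity correction is applied, so extreme tables
#' yield the extreme values 0 and `Inf` rather than finite surrogates.
#'
#' @inheritParams fisher_exact
#' @return A number in \eqn{[0, \infty]}, or `NA` if undefined.
#' @examples
#' odds_ratio(c(4, 1, 2, 3))  # 6
#' odds_ratio(c(0, 5, 3, 7))  # 0
#' odds_ratio(c(5, 0, 3, 7))  # Inf
#' @export
odds_ratio <- function(table) {
  tb <- as_contingency(table)
  num <- as.numeric(tb["a"]) * tb["d"]
  den <- as.numeric(tb["b"]) * tb["c"]
  if (num == 0 && den == 0) {
    warning("odds ratio undefined: both cross-products are zero")
    return(NA_real_)
  }
  if (den == 0) return(Inf)
  unname(num / den)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and returned
#' in the input order (via [stats::p.adjust]).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  bad <- which(is.na(p) | !is.finite(p))
  if (length(bad))
    stop("NaN/NA p-values at indices: ", paste(bad, collapse = ", "))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from barcode proportions
#'
#' For each gene (the barcode matrix should already have passed
#' [filter_constant_barcodes()]), builds the expressed/silenced-by-group
#' contingency table, computes the two-sided exact p and the sample odds
#' ratio, adjusts across all tested genes by Benjamini-Hochberg, and calls
#' a gene differentially expressed when its FDR is below `fdr_cutoff`.
#' Direction is classified by the expressed proportions:
#' `expressed-higher-in-case` iff \eqn{a/(a+b) > c/(c+d)}.
#'
#' @param barcode 0/1 matrix, genes x samples.
#' @param labels two-level group vector, one entry per column.
#' @param fdr_cutoff FDR threshold for the DEG call (default 0.05).
#' @param case_level optional label value to treat as the case group.
#' @return A data.frame of class `"deg_result"`: `gene_id`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p_value`, `fdr`, `direction`, `is_deg`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(80, 40, 40, seed = 4,
#'                           deg_fraction = 0.2, p_effect = 0.5))
#' degs <- identify_degs(cohort$true_barcode, cohort$labels)
#' table(degs$is_deg)
#' @export
identify_degs <- function(barcode, labels, fdr_cutoff = 0.05,
                          case_level = NULL) {
  stop_if_not_matrix(barcode, "barcode")
  f <- as_group_factor(labels, case_level)
  if (length(f) != ncol(barcode)) stop("labels length must match sample count")
  if (any(table(f) == 0)) stop("one group is empty")
  is_case <- f == case_level_of(f)
  a <- rowSums(barcode[, is_case, drop = FALSE] == 1)
  b <- sum(is_case) - a
  cc <- rowSums(barcode[, !is_case, drop = FALSE] == 1)
  d <- sum(!is_case) - cc

  # exact p per distinct table (many genes share one), then map back
  key <- paste(a, b, cc, d)
  uniq <- !duplicated(key)
  p_uniq <- mapply(function(a, b, c, d) fisher_exact(c(a, b, c, d)),
                   a[uniq], b[uniq], cc[uniq], d[uniq])
  p <- p_uniq[match(key, key[uniq])]

  or <- mapply(function(a, b, c, d) {
    if (a * d == 0 && b * c == 0) NA_real_ else odds_ratio(c(a, b, c, d))
  }, a, b, cc, d)

  fdr <- bh_fdr(p)
  prop_case <- a / (a + b)
  prop_ctrl <- cc / (cc + d)
  direction <- ifelse(prop_case > prop_ctrl, "expressed-higher-in-case",
                      ifelse(prop_case < prop_ctrl,
                             "silenced-higher-in-case", "none"))
  out <- data.frame(gene_id = rownames(barcode),
                    a = a, b = b, c = cc, d = d,
                    odds_ratio = or, p_value = p, fdr = fdr,
                    direction = direction, is_deg = fdr < fdr_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("deg_result", "data.frame")
  attr(out, "fdr_cutoff") <- fdr_cutoff
  out
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("DEG result: %d genes tested, %d called at FDR < %g\n",
              nrow(x), sum(x$is_deg), attr(x, "fdr_cutoff")))
  if (sum(x$is_deg)) {
    dirs <- table(x$direction[x$is_deg])
    cat("  directions:",
        paste(names(dirs), dirs, sep = " = ", collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
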