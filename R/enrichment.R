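#' Read a GMT gene-set collection
#'
#' GMT format: one set per line, tab-separated — set name, description,
#' then member identifiers.  Duplicate members within a set are counted
#' once; sets left empty are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A list of class `"gene_set_collection"`: named character
#'   vectors of members, with a `"description"` attribute per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need name, description, >=1 member): ",
         paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicated set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(seq_along(fields), function(i) {
    members <- unique(fields[[i]][-(1:2)])
    members <- members[nzchar(members)]
    structure(members, description = fields[[i]][2L])
  })
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty set(s): ", paste(nm[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets a `"gene_set_collection"` or named list of character
#'   vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in a query list
#'
#' For each set, counts the overlap k of the query with the set (both
#' intersected with the universe) and computes the upper-tail
#' hypergeometric probability \eqn{P(X \ge k)} of drawing at least k set
#' members in a query-sized sample from the universe — equivalent to a
#' one-sided Fisher exact test on the 2x2 membership table.  Sets smaller
#' than `min_size` after universe intersection are excluded;
#' Benjamini-Hochberg adjustment runs across the tested sets.
#'
#' @param query character vector of genes of interest (e.g. DEGs), a
#'   subset of `universe`.
#' @param collection a [read_gmt()] collection or named list of character
#'   vectors.
#' @param universe character vector of testable genes.
#' @param min_size minimum set size within the universe (default 5).
#' @return data.frame of class `"enrichment_result"`: `term`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size), `N`
#'   (universe size), `p_value`, `fdr`, `genes` (comma-separated overlap),
#'   sorted by p.
#' @export
hypergeom_enrich <- function(query, collection, universe, min_size = 5L) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  stray <- setdiff(query, universe)
  if (length(stray))
    stop("query genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p_value = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term),
             c("term", "k", "K", "n", "N", "p_value", "fdr", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Terms significantly enriched in both of two cohorts
#'
#' @param results_a,results_b [hypergeom_enrich()] results over the same
#'   collection.
#' @param fdr_cutoff significance threshold applied to both (default
#'   0.05).
#' @return Sorted character vector of shared term names.
#' @export
shared_terms <- function(results_a, results_b, fdr_cutoff = 0.05) {
  sig <- function(r) r$term[!is.na(r$fdr) & r$fdr < fdr_cutoff]
  sort(intersect(sig(results_a), sig(results_b)))
}
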