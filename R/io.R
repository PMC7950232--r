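# Plain-text I/O: TSV matrices, label tables, fit serialization, edge lists.

#' Read a genes x samples matrix from TSV
#'
#' First column = gene identifiers, header = sample identifiers.
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Write a genes x samples matrix as TSV
#'
#' @param x numeric matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stop_if_not_matrix(x, "matrix")
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample group labels from a two-column TSV
#'
#' Columns: sample identifier, group label.
#'
#' @param path TSV file.
#' @return Named character vector (names = sample ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("labels file needs two columns (sample, group)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write sample group labels as a two-column TSV
#'
#' @param labels group vector.
#' @param sample_ids sample identifiers (same length).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, sample_ids, path) {
  stopifnot(length(labels) == length(sample_ids))
  utils::write.table(
    data.frame(sample_id = sample_ids, group = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a barcode mixture fit
#'
#' Writes `genes.tsv` (one row per gene) and `meta.yaml` (hyperparameters,
#' cutoff, sample count, frozen flag) into `dir`.
#'
#' @param fit a [barcode_fit()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_barcode_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "barcode_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    hyper = if (is.null(fit$hyper)) NULL else unclass(fit$hyper),
    cutoff_c = fit$cutoff_c, n_samples = fit$n_samples,
    frozen = fit$frozen), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Deserialize a barcode mixture fit
#'
#' Restores a fit written by [write_barcode_fit()].  The training data
#' matrix is not serialized; methods needing it (residuals, plotting,
#' parameterless `predict`) require the original fit object.
#'
#' @param dir directory written by [write_barcode_fit()].
#' @return A `"barcode_fit"` (without `data`).
#' @export
read_barcode_fit <- function(dir) {
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  hyper <- if (is.null(meta$hyper)) NULL else
    structure(meta$hyper, class = "barcode_hyper")
  structure(list(genes = genes, hyper = hyper, cutoff_c = meta$cutoff_c,
                 n_samples = meta$n_samples, frozen = isTRUE(meta$frozen),
                 data = NULL, call = NULL),
            class = "barcode_fit")
}

#' Write a network edge list (and optionally GraphML)
#'
#' TSV columns: gene1, gene2, rho, p, fdr.  With `graphml = TRUE` (needs
#' the igraph package) an additional `.graphml` file is written for graph
#' viewers.
#'
#' @param network a [build_network()] result.
#' @param path output TSV path.
#' @param graphml also write `<path>.graphml`.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path, graphml = FALSE) {
  stopifnot(inherits(network, "coexpression_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export needs the igraph package")
    g <- igraph::graph_from_data_frame(
      network$edges[, c("gene1", "gene2", "rho", "fdr")],
      directed = FALSE,
      vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  }
  invisible(path)
}

#' Write a network diff as a flagged edge table
#'
#' @param diff a [compare_networks()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_diff <- function(diff, path) {
  stopifnot(inherits(diff, "network_diff"))
  bind <- function(df, status)
    if (nrow(df)) cbind(df, status = status) else NULL
  out <- do.call(rbind, c(list(bind(diff$gained, "gained"),
                               bind(diff$lost, "lost"),
                               bind(diff$retained, "retained"))))
  if (is.null(out))
    out <- data.frame(gene1 = character(0), gene2 = character(0),
                      rho = numeric(0), p = numeric(0), fdr = numeric(0),
                      status = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# DEG table writer: Inf odds ratios serialized as the literal "Inf"
write_deg_table <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
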