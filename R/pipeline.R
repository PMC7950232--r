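# End-to-end orchestration: single-cohort barcoding/DEG runs and the
# two-cohort cross-disease analysis, from an in-memory config or YAML.

# Normalize a config: load YAML if a path, check thresholds and that every
# referenced input file exists (before any compute).
normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$cohorts))
  defaults <- list(cutoff_z = 6.5, deg_fdr = 0.05, rho_cutoff = 0.4,
                   network_fdr = 0.05, min_size = 5L, ridge_penalty = 1e-3,
                   signature_features = "barcode", seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!(config$cutoff_z > 0)) stop("cutoff_z must be positive")
  for (nm in c("deg_fdr", "network_fdr"))
    if (config[[nm]] <= 0 || config[[nm]] >= 1)
      stop(nm, " must lie in (0, 1)")
  if (!config$signature_features %in% c("barcode", "expression"))
    stop("signature_features must be 'barcode' or 'expression'")
  for (cid in names(config$cohorts)) {
    co <- config$cohorts[[cid]]
    for (field in c("expression", "labels", "probe_map", "frozen")) {
      v <- co[[field]]
      if (is.character(v) && length(v) == 1L && !file.exists(v))
        stop("cohort '", cid, "': ", field, " file not found: ", v)
    }
    if (is.null(co$expression) || is.null(co$labels))
      stop("cohort '", cid, "' needs expression and labels")
  }
  if (!is.null(config$gmt) && is.character(config$gmt) &&
      !file.exists(config$gmt))
    stop("gmt file not found: ", config$gmt)
  config
}

load_cohort_inputs <- function(config, cohort_id) {
  co <- config$cohorts[[cohort_id]]
  if (is.null(co)) stop("unknown cohort id: ", cohort_id)
  expr <- if (is.character(co$expression)) read_expression(co$expression)
          else co$expression
  labels <- if (is.character(co$labels)) read_labels(co$labels) else co$labels
  if (!is.null(names(labels)) && !is.null(colnames(expr))) {
    miss <- setdiff(colnames(expr), names(labels))
    if (length(miss)) stop("cohort '", cohort_id, "': samples without labels: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    labels <- labels[colnames(expr)]
  }
  probe_map <- co$probe_map
  if (is.character(probe_map))
    probe_map <- utils::read.delim(probe_map, stringsAsFactors = FALSE)
  frozen <- co$frozen
  if (is.character(frozen))
    frozen <- utils::read.delim(frozen, stringsAsFactors = FALSE)
  list(expression = expr, labels = labels, probe_map = probe_map,
       frozen = frozen, case_level = co$case_level)
}

# Shared stage: probe collapse (optional), mixture fit, binarization.
barcode_stage <- function(config, cohort_id) {
  inp <- load_cohort_inputs(config, cohort_id)
  expr <- inp$expression
  if (!is.null(inp$probe_map))
    expr <- collapse_probes(expr, inp$probe_map, inp$labels, inp$case_level)
  fit <- barcode_fit(expr, cutoff_c = stats::pnorm(-config$cutoff_z),
                     frozen = inp$frozen)
  list(expression = expr, labels = inp$labels, case_level = inp$case_level,
       fit = fit, barcode = binarize(expr, fit))
}

manifest_of <- function(config, extra = list()) {
  c(list(package = "barcodeDE",
         version = as.character(utils::packageVersion("barcodeDE")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = config$seed,
         parameters = list(cutoff_z = config$cutoff_z,
                           deg_fdr = config$deg_fdr,
                           rho_cutoff = config$rho_cutoff,
                           network_fdr = config$network_fdr,
                           min_size = config$min_size,
                           ridge_penalty = config$ridge_penalty,
                           signature_features = config$signature_features)),
    extra)
}

#' Run the single-cohort barcode DEG pipeline
#'
#' Executes the stage chain collapse (optional) -> mixture fit ->
#' binarize -> constant-barcode filter -> exact-test DEG calling ->
#' gene-set enrichment (optional, against the filtered universe).  When
#' `out_dir` is set, every artifact is written as TSV along with a
#' `manifest.yaml` recording versions, seed, parameters and the gene-count
#' funnel, so the report is recomputable from config + seed.
#'
#' @param config list or YAML path with a `cohorts` entry (named list;
#'   each cohort: `expression`, `labels`, optional `probe_map`, `frozen`,
#'   `case_level`) and optional thresholds `cutoff_z` (default 6.5),
#'   `deg_fdr` (0.05), `gmt`, `min_size` (5), `seed`.
#' @param cohort_id which cohort to run (default: the first).
#' @param out_dir optional output directory.
#' @return A list of class `"cohort_report"`: `fit`, `barcode`,
#'   `retained`, `filter_report`, `degs`, `deg_ids`, `enrichment`,
#'   `manifest`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(60, 20, 20, seed = 8))
#' cfg <- list(cohorts = list(sim = list(expression = cohort$expression,
#'                                       labels = cohort$labels)))
#' rep <- run_cohort(cfg)
#' rep$manifest$funnel
#' @export
run_cohort <- function(config, cohort_id = NULL, out_dir = NULL) {
  config <- normalize_config(config)
  if (is.null(cohort_id)) cohort_id <- names(config$cohorts)[1L]
  st <- barcode_stage(config, cohort_id)
  flt <- filter_constant_barcodes(stats::setNames(list(st$barcode), cohort_id))
  if (!length(flt$retained))
    stop("stage filter_constant_barcodes: no gene retained")
  degs <- identify_degs(st$barcode[flt$retained, , drop = FALSE],
                        st$labels, fdr_cutoff = config$deg_fdr,
                        case_level = st$case_level)
  deg_ids <- degs$gene_id[degs$is_deg]
  enr <- NULL
  if (!is.null(config$gmt)) {
    coll <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    enr <- hypergeom_enrich(deg_ids, coll, flt$retained,
                            min_size = config$min_size)
  }
  manifest <- manifest_of(config, list(
    cohort = cohort_id,
    funnel = list(genes_in = nrow(st$expression),
                  genes_after_filter = length(flt$retained),
                  degs = length(deg_ids))))
  report <- structure(list(fit = st$fit, barcode = st$barcode,
                           retained = flt$retained,
                           filter_report = flt$report, degs = degs,
                           deg_ids = deg_ids, enrichment = enr,
                           manifest = manifest), class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_expression(st$barcode, file.path(out_dir, "barcode.tsv"))
    write_barcode_fit(st$fit, file.path(out_dir, "fit"))
    write_deg_table(degs, file.path(out_dir, "degs.tsv"))
    if (!is.null(enr))
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  f <- x$manifest$funnel
  cat(sprintf(
    "Cohort report [%s]: %d genes -> %d after constant filter -> %d DEGs\n",
    x$manifest$cohort, f$genes_in, f$genes_after_filter, f$degs))
  invisible(x)
}

#' Run the cross-disease analysis on two cohorts
#'
#' Computes the shared testing universe first (genes non-constant in both
#' cohorts' barcodes), calls DEGs per cohort over that universe, tests the
#' DEG overlap by Fisher's exact test, builds Spearman co-expression
#' networks on the overlapped gene panel for each (cohort, group), and
#' compares them: case vs control within each cohort and case vs case
#' across diseases.  A ridge logistic signature on the overlapped panel is
#' trained per cohort and validated on the other cohort's independently
#' fitted barcode.  With a GMT collection, per-cohort enrichment and the
#' shared significant terms are added.  When the overlapped panel is
#' empty, network and signature stages are skipped with a notice.
#'
#' @param config as in [run_cohort()], with exactly two cohorts and
#'   optional `rho_cutoff` (0.4), `network_fdr` (0.05), `ridge_penalty`
#'   (1e-3), `signature_features` ("barcode" or "expression").
#' @param out_dir optional output directory.
#' @return A list of class `"cross_disease_report"`: `universe`,
#'   `degs` (per cohort), `overlap`, `venn`, `networks` (per
#'   cohort-group), `network_diffs`, `signatures` (fit + validation AUC
#'   per training cohort), `enrichment`, `shared_terms`, `skipped`,
#'   `manifest`.
#' @export
run_cross_disease <- function(config, out_dir = NULL) {
  config <- normalize_config(config)
  ids <- names(config$cohorts)
  if (length(ids) != 2L)
    stop("cross-disease analysis needs exactly two cohorts, got ",
         length(ids))
  st <- lapply(ids, function(cid) barcode_stage(config, cid))
  names(st) <- ids

  flt <- filter_constant_barcodes(lapply(st, `[[`, "barcode"))
  universe <- flt$retained
  if (!length(universe)) stop("stage filter_constant_barcodes: empty universe")

  degs <- lapply(ids, function(cid)
    identify_degs(st[[cid]]$barcode[universe, , drop = FALSE],
                  st[[cid]]$labels, fdr_cutoff = config$deg_fdr,
                  case_level = st[[cid]]$case_level))
  names(degs) <- ids
  deg_ids <- lapply(degs, function(d) d$gene_id[d$is_deg])

  ov <- overlap_test(deg_ids[[1L]], deg_ids[[2L]], universe)
  panel <- ov$shared_ids
  skipped <- character(0)

  networks <- list(); diffs <- list()
  if (length(panel) >= 2L) {
    for (cid in ids) {
      f <- as_group_factor(st[[cid]]$labels, st[[cid]]$case_level)
      for (grp in levels(f)) {
        sel <- f == grp
        if (sum(sel) < 4L) next
        sp <- spearman_matrix(
          st[[cid]]$expression[panel, sel, drop = FALSE])
        networks[[paste(cid, grp, sep = ".")]] <-
          build_network(sp$rho, sp$p, rho_cutoff = config$rho_cutoff,
                        fdr_cutoff = config$network_fdr,
                        group_meta = paste(cid, grp))
      }
      ctrl <- paste(cid, levels(f)[1L], sep = ".")
      case <- paste(cid, levels(f)[2L], sep = ".")
      if (!is.null(networks[[ctrl]]) && !is.null(networks[[case]]))
        diffs[[cid]] <- compare_networks(networks[[ctrl]], networks[[case]])
    }
    cases <- vapply(ids, function(cid) {
      f <- as_group_factor(st[[cid]]$labels, st[[cid]]$case_level)
      paste(cid, levels(f)[2L], sep = ".")
    }, "")
    if (all(cases %in% names(networks)))
      diffs[["cross_disease"]] <-
        compare_networks(networks[[cases[1L]]], networks[[cases[2L]]])
  } else {
    skipped <- c(skipped,
                 "network: overlapped panel has fewer than 2 genes")
  }

  signatures <- list()
  if (length(panel) >= 1L) {
    feat_of <- function(cid) {
      src <- if (config$signature_features == "barcode")
        st[[cid]]$barcode else st[[cid]]$expression
      t(src[panel, , drop = FALSE])
    }
    for (cid in ids) {
      other <- setdiff(ids, cid)
      model <- fit_signature(feat_of(cid), st[[cid]]$labels,
                             ridge_penalty = config$ridge_penalty,
                             case_level = st[[cid]]$case_level)
      val_scores <- predict(model, feat_of(other))
      signatures[[cid]] <- list(
        model = model,
        training_auc = roc_auc(predict(model, feat_of(cid)),
                               st[[cid]]$labels,
                               st[[cid]]$case_level)$auc,
        validation = roc_auc(val_scores, st[[other]]$labels,
                             st[[other]]$case_level))
    }
  } else {
    skipped <- c(skipped, "signature: overlapped panel empty")
  }

  enr <- NULL; shared <- NULL
  if (!is.null(config$gmt)) {
    coll <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    enr <- lapply(ids, function(cid)
      hypergeom_enrich(deg_ids[[cid]], coll, universe,
                       min_size = config$min_size))
    names(enr) <- ids
    shared <- shared_terms(enr[[1L]], enr[[2L]], config$deg_fdr)
  }

  manifest <- manifest_of(config, list(
    cohorts = ids,
    funnel = list(universe = length(universe),
                  degs = stats::setNames(lapply(deg_ids, length), ids),
                  overlap = ov$n_overlap),
    skipped = as.list(skipped)))

  report <- structure(list(
    universe = universe, filter_report = flt$report, degs = degs,
    overlap = ov, venn = venn_summary(ov), networks = networks,
    network_diffs = diffs, signatures = signatures, enrichment = enr,
    shared_terms = shared, skipped = skipped, manifest = manifest),
    class = "cross_disease_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cid in ids)
      write_deg_table(degs[[cid]],
                      file.path(out_dir, paste0("degs_", cid, ".tsv")))
    utils::write.table(
      data.frame(gene_id = ov$shared_ids),
      file.path(out_dir, "overlap_genes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(networks))
      write_network_edges(networks[[nm]],
                          file.path(out_dir, paste0("network_", nm, ".tsv")))
    for (nm in names(diffs))
      write_network_diff(diffs[[nm]],
                         file.path(out_dir, paste0("diff_", nm, ".tsv")))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  report
}

#' @export
print.cross_disease_report <- function(x, ...) {
  f <- x$manifest$funnel
  cat("Cross-disease report\n")
  cat(sprintf("  shared universe: %d genes\n", f$universe))
  for (cid in x$manifest$cohorts)
    cat(sprintf("  %s: %d DEGs\n", cid, f$degs[[cid]]))
  cat(sprintf("  overlap: %d genes, Fisher p = %.4g\n",
              x$overlap$n_overlap, x$overlap$p_value))
  if (length(x$networks))
    cat(sprintf("  networks: %s\n",
                paste(sprintf("%s (%d edges)", names(x$networks),
                              vapply(x$networks,
                                     function(n) nrow(n$edges), 1L)),
                      collapse = ", ")))
  for (s in x$skipped) cat("  skipped -", s, "\n")
  invisible(x)
}
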