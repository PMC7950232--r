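#' Configuration for a synthetic expression cohort
#'
#' Bundles and validates the parameters of the generative model used by
#' [simulate_cohort()].  Each gene g has a silenced mean
#' \eqn{\mu_g \sim N(\xi, \lambda^2)} and silenced variance
#' \eqn{\tau_g^2 \sim \mathrm{InvGamma}(\alpha, \beta)}; an observation is
#' drawn from the uniform (expressed) component
#' \eqn{U(\mu_g, S_g)} with probability \eqn{p_g} and from
#' \eqn{N(\mu_g, \tau_g^2)} otherwise.  The saturation value is
#' \eqn{S_g = \mu_g + \code{s_offset}}.  True differential expression is
#' encoded as an additive shift \code{p_effect} of \eqn{p_g} in the case
#' group for a seeded random subset of \code{deg_fraction} of the genes.
#'
#' The defaults mimic a log2 microarray scale (silenced means near
#' background intensity ~6, expressed intensities reaching toward
#' saturation ~12) and are stand-ins: real barcoding pipelines estimate
#' these hyperparameters from large chip corpora.
#'
#' @param n_genes,n_case,n_control positive counts.
#' @param xi prior mean of the silenced means (log2 units).
#' @param lambda2 prior variance of the silenced means (> 0).
#' @param alpha,beta inverse-gamma shape and scale for the silenced
#'   variances (both > 0); the prior mean of \eqn{\tau_g^2} is
#'   \eqn{\beta/(\alpha-1)} for \eqn{\alpha > 1}.
#' @param s_offset distance from \eqn{\mu_g} to the saturation value
#'   \eqn{S_g} (> 0, log2 units).
#' @param deg_fraction fraction of genes whose expressed probability
#'   differs between groups, in [0, 1].
#' @param p_control_range length-2 interval in [0, 1]; each gene's control
#'   expressed probability is uniform on it.
#' @param p_effect additive shift of \eqn{p_g} in cases for true DEGs,
#'   in [-1, 1]; the shifted value is clipped to [0, 1].
#' @param seed integer seed making the cohort fully reproducible.
#' @return A list of class `"simulation_config"`.
#' @seealso [simulate_cohort()], [draw_gene_params()]
#' @examples
#' cfg <- simulation_config(n_genes = 100, n_case = 20, n_control = 20,
#'                          deg_fraction = 0.1, p_effect = 0.4, seed = 1)
#' @export
simulation_config <- function(n_genes, n_case, n_control,
                              xi = 6, lambda2 = 1, alpha = 3, beta = 2,
                              s_offset = 6,
                              deg_fraction = 0,
                              p_control_range = c(0.2, 0.8),
                              p_effect = 0,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1)
  if (!(lambda2 >= 0)) stop("lambda2 must be nonnegative")
  if (!(alpha > 0) || !(beta > 0)) stop("alpha and beta must be positive")
  if (!(s_offset > 0))
    stop("s_offset must be strictly positive so the expressed component ",
         "sits above the silenced mean")
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("deg_fraction must lie in [0, 1]")
  if (length(p_control_range) != 2L ||
      any(p_control_range < 0) || any(p_control_range > 1) ||
      p_control_range[1] > p_control_range[2])
    stop("p_control_range must be an ordered interval within [0, 1]")
  if (p_effect < -1 || p_effect > 1) stop("p_effect must lie in [-1, 1]")
  structure(list(
    n_genes = as.integer(n_genes), n_case = as.integer(n_case),
    n_control = as.integer(n_control),
    xi = xi, lambda2 = lambda2, alpha = alpha, beta = beta,
    s_offset = s_offset, deg_fraction = deg_fraction,
    p_control_range = p_control_range, p_effect = p_effect,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Draw per-gene parameters from the hierarchical priors
#'
#' Samples \eqn{\mu_g \sim N(\xi, \lambda^2)},
#' \eqn{\tau_g^2 \sim \mathrm{InvGamma}(\alpha, \beta)} (as the reciprocal
#' of a Gamma(shape = \eqn{\alpha}, rate = \eqn{\beta}) draw), sets
#' \eqn{S_g = \mu_g + \code{s_offset}} and draws control-group expressed
#' probabilities uniformly on `p_control_range`.  A seeded random subset of
#' \code{floor(deg_fraction * n_genes)} genes gets
#' \eqn{p_g^{case} = \mathrm{clip}(p_g^{ctrl} + \code{p_effect}, 0, 1)};
#' the rest have equal probabilities in both groups.
#'
#' @param config a [simulation_config()].
#' @return A data.frame with one row per gene: `gene_id`, `mu`, `tau2`,
#'   `s`, `p_control`, `p_case`, `is_deg`.
#' @export
draw_gene_params <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    mu <- stats::rnorm(G, config$xi, sqrt(config$lambda2))
    tau2 <- 1 / stats::rgamma(G, shape = config$alpha, rate = config$beta)
    p_ctrl <- stats::runif(G, config$p_control_range[1],
                           config$p_control_range[2])
    n_deg <- as.integer(floor(config$deg_fraction * G))
    deg_idx <- if (n_deg > 0) sample.int(G, n_deg) else integer(0)
    p_case <- p_ctrl
    p_case[deg_idx] <- pmin(1, pmax(0, p_ctrl[deg_idx] + config$p_effect))
    params <- data.frame(
      gene_id = sprintf("g%05d", seq_len(G)),
      mu = mu, tau2 = tau2, s = mu + config$s_offset,
      p_control = p_ctrl, p_case = p_case,
      is_deg = seq_len(G) %in% deg_idx & p_case != p_ctrl,
      stringsAsFactors = FALSE)
    if (any(!is.finite(params$mu)) || any(!is.finite(params$tau2)))
      stop("non-finite parameter draws; config: xi=", config$xi,
           " lambda2=", config$lambda2, " alpha=", config$alpha,
           " beta=", config$beta)
    params
  })
}

#' Simulate an expression cohort with known barcode ground truth
#'
#' Generates a log2 expression matrix from the two-component model: for
#' gene g and sample i, a latent expressed indicator
#' \eqn{z_{ig} \sim \mathrm{Bernoulli}(p_g)} (with \eqn{p_g} depending on
#' the sample's group) selects between the silenced normal
#' \eqn{N(\mu_g, \tau_g^2)} and the expressed uniform
#' \eqn{U(\mu_g, S_g)}.  The latent indicators are returned as the true
#' barcode so downstream binarization, DEG calling and signature fitting
#' can be scored against ground truth.
#'
#' @param config a [simulation_config()].
#' @return An object of class `"simulated_cohort"`: a list with
#'   `expression` (genes x samples matrix), `labels` (factor,
#'   control/case), `true_barcode` (0/1 integer matrix, 1 = draw came from
#'   the uniform component), `true_params` (per-gene parameter table from
#'   [draw_gene_params()]), `true_deg_ids` (character), and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(50, 10, 10, seed = 7))
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  params <- draw_gene_params(config)   # consumes the seed deterministically
  G <- config$n_genes
  n <- config$n_case + config$n_control
  labels <- factor(rep(c("case", "control"), c(config$n_case, config$n_control)),
                   levels = c("control", "case"))
  with_seed(config$seed + 1L, {
    p_mat <- cbind(matrix(params$p_case, G, config$n_case),
                   matrix(params$p_control, G, config$n_control))
    z <- matrix(stats::rbinom(G * n, 1L, as.vector(p_mat)), G, n)
    silenced <- matrix(stats::rnorm(G * n, mean = params$mu,
                                    sd = sqrt(params$tau2)), G, n)
    expressed <- matrix(stats::runif(G * n, min = params$mu, max = params$s),
                        G, n)
    y <- ifelse(z == 1L, expressed, silenced)
    sample_ids <- sprintf("s%03d", seq_len(n))
    dimnames(y) <- list(params$gene_id, sample_ids)
    dimnames(z) <- dimnames(y)
    structure(list(
      expression = y, labels = labels,
      true_barcode = z, true_params = params,
      true_deg_ids = params$gene_id[params$is_deg],
      config = config), class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated expression cohort:",
      nrow(x$expression), "genes x", ncol(x$expression), "samples\n")
  cat("  cases:", sum(x$labels == "case"),
      " controls:", sum(x$labels == "control"), "\n")
  cat("  true DEGs:", length(x$true_deg_ids),
      sprintf("(deg_fraction = %.3g, p_effect = %.3g)\n",
              x$config$deg_fraction, x$config$p_effect))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv` (genes x samples), `labels.tsv` (sample, group),
#' `true_barcode.tsv`, `true_params.tsv` and `config.yaml` into `dir`.
#'
#' @param cohort a `"simulated_cohort"`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_labels(cohort$labels, colnames(cohort$expression),
               file.path(dir, "labels.tsv"))
  write_expression(cohort$true_barcode, file.path(dir, "true_barcode.tsv"))
  utils::write.table(cohort$true_params, file.path(dir, "true_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
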