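#' @export
print.barcode_fit <- function(x, ...) {
  cat("Barcode normal-uniform mixture fit\n")
  cat(sprintf("  %d genes x %d samples%s\n", nrow(x$genes), x$n_samples,
              if (x$frozen) " (frozen parameters)" else ""))
  if (!x$frozen) {
    cat(sprintf("  converged: %d/%d genes\n",
                sum(x$genes$converged), nrow(x$genes)))
    if (!is.null(x$hyper)) print(x$hyper)
  }
  cat(sprintf("  binarization cutoff C = %.4g (z = %.3g)\n",
              x$cutoff_c, -stats::qnorm(x$cutoff_c)))
  invisible(x)
}

#' @export
summary.barcode_fit <- function(object, ...) {
  g <- object$genes
  out <- list(
    n_genes = nrow(g), n_samples = object$n_samples,
    frozen = object$frozen,
    n_converged = sum(g$converged, na.rm = TRUE),
    n_flagged = sum(!g$converged, na.rm = TRUE),
    hyper = object$hyper, cutoff_c = object$cutoff_c,
    p_hat_quantiles = stats::quantile(g$p_hat, c(0, .25, .5, .75, 1),
                                      na.rm = TRUE),
    tau2_shrinkage = c(raw = stats::var(g$tau2_raw, na.rm = TRUE),
                       shrunk = stats::var(g$tau2_hat, na.rm = TRUE)))
  class(out) <- "summary.barcode_fit"
  out
}

#' @export
print.summary.barcode_fit <- function(x, ...) {
  cat("Barcode mixture fit summary\n")
  cat(sprintf("  %d genes x %d samples; %d converged, %d flagged\n",
              x$n_genes, x$n_samples, x$n_converged, x$n_flagged))
  if (!is.null(x$hyper)) print(x$hyper)
  cat("  expressed proportion (p_hat) quantiles:\n")
  print(round(x$p_hat_quantiles, 4))
  cat(sprintf("  across-gene variance of tau2: raw %.4g -> shrunk %.4g\n",
              x$tau2_shrinkage["raw"], x$tau2_shrinkage["shrunk"]))
  invisible(x)
}

#' @export
coef.barcode_fit <- function(object, ...) {
  g <- object$genes
  m <- as.matrix(g[, c("mu_hat", "tau2_hat", "p_hat", "s_hat")])
  rownames(m) <- g$gene_id
  m
}

#' Binarize expression against a fitted silenced distribution
#'
#' An intensity is called expressed (1) when it is implausibly large under
#' the gene's silenced normal: entry 1 iff
#' \eqn{\Phi(-(y_{ig} - \hat\mu_g)/\hat\tau_g) < C}, equivalently
#' \eqn{y_{ig} > \hat\mu_g + z_C \hat\tau_g} with
#' \eqn{z_C = \Phi^{-1}(1 - C)}.  The default C stored in the fit is
#' \eqn{\Phi(-6.5)}: a value must sit 6.5 silenced standard deviations
#' above the silenced mean to be called expressed.
#'
#' @param x numeric matrix of log2 expression (genes x samples).  Every
#'   row must be covered by `fit`.
#' @param fit a [barcode_fit()] object.
#' @param cutoff_c cutoff in (0, 0.5); defaults to the value stored in
#'   `fit`.
#' @return Integer 0/1 matrix with the dimnames of `x`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(40, 20, 20, seed = 3))
#' fit <- barcode_fit(cohort$expression)
#' bc <- binarize(cohort$expression, fit)
#' table(bc)
#' @export
binarize <- function(x, fit, cutoff_c = fit$cutoff_c) {
  stop_if_not_matrix(x)
  stopifnot(inherits(fit, "barcode_fit"))
  if (!(cutoff_c > 0 && cutoff_c < 0.5))
    stop("cutoff_c must lie in (0, 0.5)")
  idx <- match(rownames(x), fit$genes$gene_id)
  if (anyNA(idx)) {
    miss <- rownames(x)[is.na(idx)]
    stop("fit does not cover genes: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  }
  mu <- fit$genes$mu_hat[idx]
  tau <- sqrt(fit$genes$tau2_hat[idx])
  bc <- (stats::pnorm(-(x - mu) / tau) < cutoff_c) * 1L
  storage.mode(bc) <- "integer"
  dimnames(bc) <- dimnames(x)
  bc
}

#' Predict method for barcode mixture fits
#'
#' `type = "barcode"` returns the 0/1 expressed calls for `newdata` (or the
#' training matrix), `type = "tail"` the silenced tail probability
#' \eqn{\Phi(-(y - \hat\mu)/\hat\tau)} that is compared against the cutoff,
#' and `type = "posterior"` the model-based posterior probability that a
#' value came from the expressed (uniform) component.
#'
#' @param object a [barcode_fit()].
#' @param newdata optional expression matrix; defaults to the training data.
#' @param type see Details.
#' @param cutoff_c binarization cutoff, used for `type = "barcode"`.
#' @param ... unused.
#' @return A matrix shaped like `newdata`.
#' @export
predict.barcode_fit <- function(object, newdata = NULL,
                                type = c("barcode", "tail", "posterior"),
                                cutoff_c = object$cutoff_c, ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else newdata
  stop_if_not_matrix(x)
  if (type == "barcode") return(binarize(x, object, cutoff_c))
  idx <- match(rownames(x), object$genes$gene_id)
  if (anyNA(idx))
    stop("fit does not cover genes: ",
         paste(utils::head(rownames(x)[is.na(idx)], 5), collapse = ", "))
  g <- object$genes
  mu <- g$mu_hat[idx]; tau <- sqrt(g$tau2_hat[idx])
  if (type == "tail") {
    out <- stats::pnorm(-(x - mu) / tau)
  } else {
    if (object$frozen)
      stop("posterior weights need mixture proportions; unavailable in frozen mode")
    p <- g$p_hat[idx]; s <- g$s_hat[idx]
    fU <- (x >= mu & x <= s) / (s - mu)
    fN <- stats::dnorm(x, mean = mu, sd = tau)
    num <- p * fU
    out <- num / pmax(num + (1 - p) * fN, .Machine$double.xmin)
  }
  dimnames(out) <- dimnames(x)
  out
}

#' @export
residuals.barcode_fit <- function(object, ...) {
  g <- object$genes
  r <- (object$data - g$mu_hat) / sqrt(g$tau2_hat)
  dimnames(r) <- dimnames(object$data)
  r
}

#' Simulate new samples from a fitted barcode mixture
#'
#' Draws `nsim` fresh samples per gene from the fitted two-component model
#' (silenced normal with probability \eqn{1 - \hat p_g}, expressed uniform
#' otherwise), e.g. for posterior-predictive checks of the fit.
#'
#' @param object a non-frozen [barcode_fit()].
#' @param nsim number of samples to draw per gene.
#' @param seed optional integer; RNG state is restored afterwards.
#' @param ... unused.
#' @return A genes x `nsim` matrix.
#' @export
simulate.barcode_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$frozen) stop("cannot simulate from a frozen fit (no p_hat)")
  g <- object$genes
  G <- nrow(g)
  with_seed(seed, {
    z <- matrix(stats::rbinom(G * nsim, 1L, g$p_hat), G, nsim)
    sil <- matrix(stats::rnorm(G * nsim, g$mu_hat, sqrt(g$tau2_hat)), G, nsim)
    exp_ <- matrix(stats::runif(G * nsim, g$mu_hat, g$s_hat), G, nsim)
    y <- ifelse(z == 1L, exp_, sil)
    dimnames(y) <- list(g$gene_id, sprintf("sim%03d", seq_len(nsim)))
    y
  })
}

#' Plot the fitted mixture for one gene
#'
#' Histogram of the gene's log2 intensities overlaid with the fitted
#' silenced normal density, expressed uniform density and the
#' binarization threshold \eqn{\hat\mu_g + z_C \hat\tau_g}.
#'
#' @param x a [barcode_fit()].
#' @param gene gene identifier (rowname) to display.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.barcode_fit <- function(x, gene = x$genes$gene_id[1], ...) {
  i <- match(gene, x$genes$gene_id)
  if (is.na(i)) stop("gene not in fit: ", gene)
  y <- x$data[gene, ]
  g <- x$genes[i, ]
  graphics::hist(y, freq = FALSE, main = paste("Barcode mixture:", gene),
                 xlab = "log2 intensity", col = "grey90", border = "grey60",
                 ...)
  xs <- seq(min(y) - 1, max(y) + 1, length.out = 400)
  graphics::lines(xs, (1 - g$p_hat) *
                    stats::dnorm(xs, g$mu_hat, sqrt(g$tau2_hat)),
                  col = "steelblue", lwd = 2)
  graphics::segments(g$mu_hat, g$p_hat / (g$s_hat - g$mu_hat),
                     g$s_hat, g$p_hat / (g$s_hat - g$mu_hat),
                     col = "firebrick", lwd = 2)
  thr <- g$mu_hat - stats::qnorm(x$cutoff_c) * sqrt(g$tau2_hat)
  graphics::abline(v = thr, lty = 2)
  invisible(x)
}
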