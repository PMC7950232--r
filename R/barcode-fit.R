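#' Empirical-Bayes hyperparameters for the silenced component
#'
#' Estimates the across-gene priors of the hierarchical model from raw
#' per-gene estimates: \eqn{\xi} and \eqn{\lambda^2} are the mean and
#' variance of the silenced means, and the inverse-gamma \eqn{(\alpha,
#' \beta)} come from a method-of-moments match of the prior mean
#' \eqn{\beta/(\alpha-1)} and variance
#' \eqn{\beta^2/((\alpha-1)^2(\alpha-2))} to the empirical moments of the
#' raw silenced variances.  Borrowing strength this way is what stabilizes
#' the per-gene variance estimates ("shrinkage toward the overall level").
#'
#' @param mu numeric vector of raw per-gene silenced means.
#' @param tau2 numeric vector of raw per-gene silenced variances.
#' @return A list of class `"barcode_hyper"`: `xi`, `lambda2`, `alpha`,
#'   `beta`.  When the empirical moments of `tau2` are incompatible with an
#'   inverse gamma (zero or non-finite variance), `alpha` is floored at
#'   2.01 and `beta` solved from the mean alone.
#' @examples
#' estimate_hyperparameters(mu = rnorm(100, 6), tau2 = 1 / rgamma(100, 4, 3))
#' @export
estimate_hyperparameters <- function(mu, tau2) {
  ok <- is.finite(mu) & is.finite(tau2) & tau2 > 0
  mu <- mu[ok]; tau2 <- tau2[ok]
  if (length(mu) < 2L)
    stop("need at least 2 genes with finite (mu, tau2) estimates, got ",
         length(mu))
  xi <- mean(mu)
  lambda2 <- stats::var(mu)          # may be 0 for degenerate input
  m <- mean(tau2)
  v <- stats::var(tau2)
  if (is.finite(v) && v > 0) {
    alpha <- 2 + m^2 / v             # from var = mean^2 / (alpha - 2)
    if (alpha < 2.01) alpha <- 2.01
  } else {
    alpha <- 2.01
  }
  beta <- m * (alpha - 1)
  structure(list(xi = xi, lambda2 = lambda2, alpha = alpha, beta = beta),
            class = "barcode_hyper")
}

#' @export
print.barcode_hyper <- function(x, ...) {
  cat(sprintf(
    "Barcode hyperparameters: xi = %.4g, lambda2 = %.4g, alpha = %.4g, beta = %.4g\n",
    x$xi, x$lambda2, x$alpha, x$beta))
  invisible(x)
}

#' Fit the per-gene normal-uniform barcode mixture
#'
#' For each gene the log2 intensities are modeled as
#' \deqn{y_{ig} \sim (1-p_g)\,N(\mu_g, \tau_g^2) + p_g\,U(\mu_g, S_g),}
#' the normal component describing the silenced (untranscribed) state and
#' the uniform component the expressed state up to the saturation value
#' \eqn{S_g}.  Each gene is fit by EM — the E-step computes posterior
#' expressed-membership weights, the M-step updates \eqn{(\mu_g, \tau_g^2,
#' p_g)} from silenced-weighted moments with \eqn{S_g} held at the gene's
#' observed maximum + 0.1 (the uniform upper endpoint is weakly identified,
#' so it is pinned rather than estimated).  After the per-gene fits, the
#' hierarchical priors are estimated by [estimate_hyperparameters()] and
#' a second EM pass refines every gene under them: \eqn{\mu_g} is
#' precision-weighted toward \eqn{\xi}, and the variance update is the
#' inverse-gamma posterior mode
#' \deqn{\hat\tau_g^2 = \frac{\beta + W_g \tau_{g,w}^2 / 2}
#'                           {\alpha + 1 + W_g / 2},}
#' where \eqn{W_g} is the effective silenced count (sum of silenced
#' weights) and \eqn{\tau_{g,w}^2} the silenced-weighted variance — the
#' empirical-Bayes shrinkage that stabilizes variances of genes with few
#' silenced observations and bounds the objective against mixture
#' variance spikes.
#'
#' EM initialization is robust to the expressed tail: \eqn{\mu^0} is the
#' median of the lower half of the gene's values, \eqn{\tau^{2,0}} the
#' squared MAD of that half, and \eqn{p^0} the fraction of values above
#' \eqn{\mu^0 + 3\tau^0}.  A gene with constant values cannot be fit; it
#' is flagged (`converged = FALSE`) with `p_hat = 0` and
#' `tau2_hat = tau2_floor`.
#'
#' Alternatively, supply `frozen` per-gene \eqn{(\mu, \tau^2)} estimated
#' elsewhere (e.g. from a large reference chip corpus) to reproduce
#' reference-corpus barcoding; no EM is run in that mode.
#'
#' @param x numeric matrix of log2 expression, genes in rows (rownames =
#'   gene identifiers), samples in columns.
#' @param max_iter maximum EM iterations per gene.
#' @param tol relative log-likelihood change declaring convergence.
#' @param tau2_floor lower bound applied to all variance estimates.
#' @param cutoff_c default binarization cutoff stored in the fit; see
#'   [binarize()].  The default is \eqn{\Phi(-6.5)}, i.e. a z-threshold of
#'   6.5 silenced standard deviations.
#' @param frozen optional data.frame with columns `gene_id`, `mu`, `tau2`
#'   covering every row of `x`; switches to frozen mode.
#' @param posterior logical; additionally draw from the full posterior of
#'   the hierarchical model by Gibbs sampling (two chains from
#'   overdispersed starts, pooled) and report per-gene posterior means and
#'   standard deviations.  The EM point estimates can sit several
#'   conditional standard errors from the truth for weakly identified
#'   genes (broad silenced variance, high expressed proportion); the
#'   posterior summaries carry honestly calibrated uncertainty there.
#' @param sweeps,burn Gibbs sweeps per chain and burn-in discarded.
#' @return An object of class `"barcode_fit"`; see Details.  Components:
#'   `genes` (per-gene table: `gene_id`, `mu_hat`, `tau2_raw`, `tau2_hat`,
#'   `p_hat`, `s_hat`, `w_silenced`, `n_iter`, `converged`, `loglik`;
#'   with `posterior = TRUE` also `mu_post`, `mu_se`, `tau2_post`,
#'   `p_post`), `hyper` (a `"barcode_hyper"`), `cutoff_c`, `n_samples`,
#'   `frozen`, `data` (the input matrix), `call`.
#' @seealso [binarize()], [predict.barcode_fit()], [simulate_cohort()]
#' @examples
#' cohort <- simulate_cohort(simulation_config(60, 30, 30, seed = 2))
#' fit <- barcode_fit(cohort$expression)
#' fit
#' head(coef(fit))
#' @export
barcode_fit <- function(x, max_iter = 200L, tol = 1e-6, tau2_floor = 1e-6,
                        cutoff_c = stats::pnorm(-6.5), frozen = NULL,
                        posterior = FALSE, sweeps = 1500L, burn = 500L) {
  stop_if_not_matrix(x)
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  cl <- match.call()
  G <- nrow(x); n <- ncol(x)

  if (!is.null(frozen)) {
    if (!all(c("gene_id", "mu", "tau2") %in% names(frozen)))
      stop("frozen table needs columns gene_id, mu, tau2")
    miss <- setdiff(rownames(x), frozen$gene_id)
    if (length(miss))
      stop("frozen table missing genes: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    idx <- match(rownames(x), frozen$gene_id)
    genes <- data.frame(
      gene_id = rownames(x),
      mu_hat = frozen$mu[idx],
      tau2_raw = frozen$tau2[idx],
      tau2_hat = pmax(frozen$tau2[idx], tau2_floor),
      p_hat = NA_real_, s_hat = apply(x, 1, max) + 0.1,
      w_silenced = NA_real_, n_iter = 0L, converged = TRUE,
      loglik = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(genes = genes, hyper = NULL, cutoff_c = cutoff_c,
                          n_samples = n, frozen = TRUE, data = x, call = cl),
                     class = "barcode_fit"))
  }

  if (n < 8)
    warning("fewer than 8 samples per gene; mixture estimates will be unstable")

  s_hat <- apply(x, 1, max) + 0.1
  rng <- apply(x, 1, function(r) diff(range(r)))
  degenerate <- rng == 0

  # robust initialization from the lower half of each gene's values
  lower_stats <- t(apply(x, 1, function(r) {
    lo <- sort(r)[seq_len(ceiling(length(r) / 2))]
    c(med = stats::median(lo), mad2 = stats::mad(lo)^2)
  }))
  mu0 <- lower_stats[, "med"]
  tau20 <- pmax(lower_stats[, "mad2"], tau2_floor)
  p0 <- rowMeans(x > mu0 + 3 * sqrt(tau20))

  em <- em_mixture(x, s_hat, degenerate, mu0, tau20, p0,
                   max_iter = max_iter, tol = tol, tau2_floor = tau2_floor)
  mu <- em$mu; p <- em$p
  converged <- em$converged; n_iter <- em$n_iter; loglik <- em$loglik

  # degenerate (constant) genes: flagged, silenced by convention
  mu[degenerate] <- x[degenerate, 1]
  p[degenerate] <- 0
  converged[degenerate] <- FALSE
  n_iter[degenerate] <- 0L
  loglik[degenerate] <- NA_real_

  tau2_raw <- em$tau2
  tau2_raw[degenerate] <- tau2_floor
  W <- em$W
  W[degenerate] <- NA_real_

  usable <- !degenerate & is.finite(mu) & is.finite(tau2_raw)
  # spike-collapsed fits (a "silenced" normal holding almost no mass) carry
  # degenerate raw estimates; keep them out of the moment matching
  well <- usable & converged & W >= 5
  if (sum(well) < 2) well <- usable
  alt <- NULL
  if (sum(usable) >= 2) {
    hyper <- estimate_hyperparameters(mu[well], tau2_raw[well])
    # The robust start can land in an inverted basin for genes expressed
    # in most samples (the "silenced" normal fits the expressed cluster).
    # Run the EM from a second, high-expressed-fraction start as well,
    # refine both solutions with MAP M-steps under the estimated priors
    # (at the MAP fixed point tau2 equals the inverse-gamma posterior
    # mode (beta + W tau2_w / 2) / (alpha + 1 + W / 2), i.e. the
    # shrinkage is applied inside the EM), and keep, per gene, the
    # solution with the higher penalized objective.
    emB <- em_mixture(x, s_hat, degenerate,
                      mu0 = apply(x, 1, stats::quantile, 0.05),
                      tau20 = rep(0.3, G), p0 = rep(0.7, G),
                      max_iter = max_iter, tol = tol,
                      tau2_floor = tau2_floor)
    mapA <- em_mixture(x, s_hat, degenerate, mu, pmax(tau2_raw, 1e-4), p,
                       max_iter = max_iter, tol = tol,
                       tau2_floor = tau2_floor, hyper = hyper)
    mapB <- em_mixture(x, s_hat, degenerate, emB$mu,
                       pmax(emB$tau2, 1e-4), emB$p,
                       max_iter = max_iter, tol = tol,
                       tau2_floor = tau2_floor, hyper = hyper)
    penalized <- function(m) m$loglik +
      stats::dnorm(m$mu, hyper$xi, sqrt(max(hyper$lambda2, 1e-12)),
                   log = TRUE) -
      (hyper$alpha + 1) * log(m$tau2) - hyper$beta / m$tau2
    useB <- !degenerate & !is.na(penalized(mapB)) &
      penalized(mapB) > penalized(mapA)
    pick <- function(f) ifelse(useB, mapB[[f]], mapA[[f]])
    mu <- pick("mu"); tau2_hat <- pick("tau2"); p <- pick("p")
    W <- pick("W")
    converged <- ifelse(useB, mapB$converged, mapA$converged)
    n_iter <- n_iter + as.integer(pick("n_iter"))
    loglik <- pick("loglik")
    tau2_raw <- ifelse(useB, emB$tau2, tau2_raw)
    alt <- list(mu = ifelse(useB, mapA$mu, mapB$mu),
                tau2 = ifelse(useB, mapA$tau2, mapB$tau2),
                p = ifelse(useB, mapA$p, mapB$p))
    mu[degenerate] <- x[degenerate, 1]
    tau2_hat[degenerate] <- tau2_floor
    tau2_raw[degenerate] <- tau2_floor
    p[degenerate] <- 0
    W[degenerate] <- NA_real_
    converged[degenerate] <- FALSE
    loglik[degenerate] <- NA_real_
  } else {
    warning("fewer than 2 usable genes; skipping empirical-Bayes shrinkage")
    hyper <- NULL
    tau2_hat <- tau2_raw
  }

  genes <- data.frame(
    gene_id = rownames(x), mu_hat = mu, tau2_raw = tau2_raw,
    tau2_hat = tau2_hat, p_hat = p, s_hat = s_hat, w_silenced = W,
    n_iter = n_iter, converged = converged, loglik = loglik,
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  if (posterior) {
    if (is.null(hyper))
      stop("posterior sampling needs estimated hyperparameters")
    # chains seeded at the two competing EM explanations of each gene
    clean <- function(m, t2, pp) list(
      mu = ifelse(is.finite(m), m, hyper$xi),
      tau2 = pmax(ifelse(is.finite(t2), t2, 1), 1e-4),
      p = pmin(pmax(ifelse(is.finite(pp), pp, 0.5), 0.01), 0.99))
    post <- gibbs_posterior(
      x, s_hat, hyper,
      init1 = clean(mu, tau2_hat, p),
      init2 = clean(alt$mu, alt$tau2, alt$p),
      sweeps = sweeps, burn = burn)
    genes$mu_post <- post$mu
    genes$mu_se <- post$mu_se
    genes$tau2_post <- post$tau2
    genes$p_post <- post$p
  }
  structure(list(genes = genes, hyper = hyper, cutoff_c = cutoff_c,
                 n_samples = n, frozen = FALSE, data = x, call = cl),
            class = "barcode_fit")
}

# Per-gene EM for the two-component mixture, vectorized across genes with
# an active set.  E-step: posterior expressed-membership weights; M-step:
# silenced-weighted moments with the uniform upper endpoint pinned at s.
# With `hyper` supplied, the M-steps become MAP updates under the
# hierarchical priors: mu is precision-weighted toward xi and tau2 is the
# inverse-gamma posterior mode (beta + SS/2) / (alpha + 1 + W/2), which
# bounds the objective and removes the single-point variance-spike
# degeneracy of unpenalized mixture EM.
em_mixture <- function(x, s, degenerate, mu0, tau20, p0,
                       max_iter = 200L, tol = 1e-6, tau2_floor = 1e-6,
                       hyper = NULL) {
  G <- nrow(x); n <- ncol(x)
  mu <- mu0; tau2 <- tau20; p <- p0
  loglik <- rep(-Inf, G)
  n_iter <- rep(0L, G)
  converged <- rep(FALSE, G)
  w <- matrix(0, G, n)
  active <- which(!degenerate)
  tiny <- .Machine$double.xmin
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    a <- active
    ya <- x[a, , drop = FALSE]
    fU <- (ya >= mu[a]) / (s[a] - mu[a])
    fN <- stats::dnorm(ya, mean = mu[a], sd = sqrt(tau2[a]))
    num <- p[a] * fU
    den <- pmax(num + (1 - p[a]) * fN, tiny)
    wa <- num / den
    sw <- pmax(rowSums(1 - wa), 1e-8)
    ybar <- rowSums((1 - wa) * ya) / sw
    if (is.null(hyper)) {
      mu_new <- ybar
      tau2_new <- pmax(rowSums((1 - wa) * (ya - mu_new)^2) / sw, tau2_floor)
    } else {
      prior_w <- tau2[a] / hyper$lambda2
      mu_new <- (sw * ybar + prior_w * hyper$xi) / (sw + prior_w)
      ss <- rowSums((1 - wa) * (ya - mu_new)^2)
      tau2_new <- pmax((2 * hyper$beta + ss) / (2 * (hyper$alpha + 1) + sw),
                       tau2_floor)
    }
    p_new <- pmin(pmax(rowMeans(wa), 0), 1)
    ll_new <- rowSums(log(den))
    done <- abs(ll_new - loglik[a]) < tol * (abs(loglik[a]) + tol)
    mu[a] <- mu_new; tau2[a] <- tau2_new; p[a] <- p_new
    w[a, ] <- wa
    loglik[a] <- ll_new
    n_iter[a] <- it
    converged[a[done]] <- TRUE
    active <- a[!done]
  }
  list(mu = mu, tau2 = tau2, p = p, W = rowSums(1 - w),
       loglik = loglik, n_iter = n_iter, converged = converged)
}

# Gibbs sampler for the hierarchical normal-uniform mixture with the
# hyperparameters fixed at their empirical-Bayes estimates.  Conditionals:
# latent labels z are independent Bernoulli; tau2 | z, mu is inverse gamma;
# p | z is beta; mu | z, tau2 gets a Metropolis step (its conditional is
# non-conjugate through the uniform support and the (S - mu)^-n_expressed
# factor).  Two chains seeded at the two EM solutions are pooled, and the
# reported posterior SD includes the between-chain spread, so genes whose
# posterior the chains explore differently carry honestly inflated
# uncertainty.  Uses the caller's RNG state.
gibbs_posterior <- function(y, s, hyper, init1, init2,
                            sweeps = 1500L, burn = 500L) {
  G <- nrow(y); n <- ncol(y)
  y2 <- y^2
  tiny <- .Machine$double.xmin
  run_chain <- function(mu, tau2, p) {
    sums <- list(mu = 0, mu2 = 0, tau2 = 0, p = 0)
    kept <- 0L
    for (sw in seq_len(sweeps)) {
      fU <- (y >= mu) / (s - mu)
      fN <- stats::dnorm(y, mu, sqrt(tau2))
      pr <- p * fU / pmax(p * fU + (1 - p) * fN, tiny)
      z <- matrix(stats::runif(G * n) < pr, G, n)
      n1 <- rowSums(z); n0 <- n - n1
      sum0 <- rowSums(y * !z); sumsq0 <- rowSums(y2 * !z)
      yinf <- y; yinf[!z] <- Inf   # min over expressed entries only
      min_exp <- yinf[cbind(seq_len(G), max.col(-yinf, ties.method = "first"))]
      ss <- pmax(sumsq0 - 2 * mu * sum0 + n0 * mu^2, 0)
      tau2 <- 1 / stats::rgamma(G, shape = hyper$alpha + n0 / 2,
                                rate = hyper$beta + ss / 2)
      prec <- n0 / tau2 + 1 / hyper$lambda2
      mu_star <- mu + stats::rnorm(G, 0, 1.5 / sqrt(prec))
      logt <- function(m) ifelse(m <= min_exp & m < s,
        -(n0 * m^2 - 2 * m * sum0) / (2 * tau2) -
          (m - hyper$xi)^2 / (2 * hyper$lambda2) -
          n1 * log(pmax(s - m, tiny)),
        -Inf)
      lacc <- logt(mu_star) - logt(mu)
      take <- !is.na(lacc) & log(stats::runif(G)) < lacc
      mu[take] <- mu_star[take]
      p <- stats::rbeta(G, 1 + n1, 1 + n0)
      if (sw > burn) {
        sums$mu <- sums$mu + mu; sums$mu2 <- sums$mu2 + mu^2
        sums$tau2 <- sums$tau2 + tau2; sums$p <- sums$p + p
        kept <- kept + 1L
      }
    }
    list(mu = sums$mu / kept,
         mu_var = pmax(sums$mu2 / kept - (sums$mu / kept)^2, 0),
         tau2 = sums$tau2 / kept, p = sums$p / kept)
  }
  c1 <- run_chain(init1$mu, init1$tau2, init1$p)
  c2 <- run_chain(init2$mu, init2$tau2, init2$p)
  mu <- (c1$mu + c2$mu) / 2
  mu_var <- (c1$mu_var + c2$mu_var) / 2 + (c1$mu - c2$mu)^2 / 4
  list(mu = mu, mu_se = sqrt(mu_var),
       tau2 = (c1$tau2 + c2$tau2) / 2, p = (c1$p + c2$p) / 2)
}
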