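# Shared fixtures: small synthetic cohorts and a well-separated variant.

# Low-noise variance regime (tau2 concentrated near 0.1) in which a z = 6.5
# barcode threshold sits well inside the expressed support.
low_noise_config <- function(n_genes, n_case, n_control, seed, ...) {
  simulation_config(n_genes, n_case, n_control, alpha = 6, beta = 0.5,
                    seed = seed, ...)
}

# Cohort whose expressed draws are pushed at least `k` silenced SDs above
# the silenced mean (re-drawn uniformly on [mu + k*tau, S]), giving
# near-perfectly separable components for barcode-fidelity checks.
separated_cohort <- function(n_genes, n_case, n_control, seed, k = 8,
                             s_offset = 10, tau2 = 0.25, ...) {
  cfg <- simulation_config(n_genes, n_case, n_control, s_offset = s_offset,
                           alpha = 102, beta = tau2 * 101, seed = seed, ...)
  co <- simulate_cohort(cfg)
  tp <- co$true_params
  lo <- tp$mu + k * sqrt(tp$tau2)
  stopifnot(all(lo < tp$s))
  expressed <- which(co$true_barcode == 1L, arr.ind = TRUE)
  set.seed(seed + 1L)
  co$expression[expressed] <- stats::runif(nrow(expressed),
                                           min = lo[expressed[, 1]],
                                           max = tp$s[expressed[, 1]])
  co
}

# Fresh samples from an existing cohort's gene-level truth (external
# validation under the same generative parameters).
resim_cohort <- function(cohort, seed) {
  tp <- cohort$true_params
  G <- nrow(tp)
  n_case <- sum(cohort$labels == "case")
  n_control <- sum(cohort$labels == "control")
  n <- n_case + n_control
  set.seed(seed)
  p_mat <- cbind(matrix(tp$p_case, G, n_case),
                 matrix(tp$p_control, G, n_control))
  z <- matrix(stats::rbinom(G * n, 1L, as.vector(p_mat)), G, n)
  sil <- matrix(stats::rnorm(G * n, tp$mu, sqrt(tp$tau2)), G, n)
  expr <- matrix(stats::runif(G * n, tp$mu, tp$s), G, n)
  y <- ifelse(z == 1L, expr, sil)
  dimnames(y) <- list(tp$gene_id, sprintf("v%03d", seq_len(n)))
  dimnames(z) <- dimnames(y)
  out <- cohort
  out$expression <- y
  out$true_barcode <- z
  out
}

# Enumeration oracle for Fisher's exact test, independent of
# stats::fisher.test: hypergeometric point probabilities from choose().
enumerate_fisher <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- exp(lchoose(c1, support) + lchoose(N - c1, r1 - support) -
                 lchoose(N, r1))
  obs <- probs[support == a]
  if (alternative == "greater") sum(probs[support >= a])
  else sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hand-executed BH step-up definition.
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
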