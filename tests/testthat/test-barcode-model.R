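test_that("hyperparameter moments invert the inverse-gamma relations", {
  # empirical mean 1, variance 0.5 => alpha = 2 + 1/0.5 = 4, beta = 3
  tau2 <- c(1 - sqrt(0.5), 1, 1 + sqrt(0.5))
  hy <- estimate_hyperparameters(mu = c(6, 6, 6), tau2 = tau2)
  expect_equal(hy$xi, 6)
  expect_equal(hy$lambda2, 0)
  expect_equal(hy$alpha, 4)
  expect_equal(hy$beta, 3)

  # degenerate zero-variance tau2: alpha at the floor, beta from the mean
  hy <- estimate_hyperparameters(mu = c(5, 7), tau2 = c(0.3, 0.3))
  expect_equal(hy$alpha, 2.01)
  expect_equal(hy$beta, 0.3 * 1.01)

  expect_error(estimate_hyperparameters(6, 1), "at least 2")
})

test_that("a pure-normal gene is fit with a small expressed proportion", {
  cfg <- simulation_config(20, 250, 250, p_control_range = c(0, 0),
                           deg_fraction = 0, seed = 4)
  co <- simulate_cohort(cfg)
  fit <- barcode_fit(co$expression)
  # with S pinned at max + 0.1, the uniform spans only the observed range
  # and legitimately absorbs the top ~2-4% tail of a pure normal; p_hat
  # must stay far below any real expressed signal but is not zero
  expect_true(all(fit$genes$p_hat < 0.08))
  expect_lt(mean(fit$genes$p_hat), 0.04)
  expect_true(all(fit$genes$converged))
})

test_that("constant genes are flagged and floored, not fit", {
  co <- simulate_cohort(simulation_config(10, 10, 10, seed = 6))
  x <- co$expression
  x[3, ] <- 5
  fit <- expect_warning(barcode_fit(x[, 1:6]), "fewer than 8 samples")
  fit <- barcode_fit(x)
  expect_false(fit$genes$converged[3])
  expect_equal(fit$genes$p_hat[3], 0)
  expect_equal(fit$genes$tau2_hat[3], 1e-6)
  expect_equal(fit$genes$mu_hat[3], 5)
})

test_that("empirical-Bayes shrinkage contracts the variance estimates", {
  co <- simulate_cohort(simulation_config(300, 60, 60, seed = 8))
  fit <- barcode_fit(co$expression)
  expect_lt(stats::var(fit$genes$tau2_hat), stats::var(fit$genes$tau2_raw))
  # shrunk values sit between the raw estimate and the prior mode
  expect_true(all(fit$genes$tau2_hat > 0))
})

test_that("binarization applies the silenced-tail rule around z = 6.5", {
  x <- rbind(g1 = c(0, 6, 6.5, 7, -3))
  colnames(x) <- paste0("s", 1:5)
  fit <- barcode_fit(x, frozen = data.frame(gene_id = "g1", mu = 0, tau2 = 1))
  bc <- binarize(x, fit)   # default C = pnorm(-6.5)
  expect_identical(as.vector(bc), c(0L, 0L, 0L, 1L, 0L))
  # y exactly at mu is silenced for any C < 0.5
  bc2 <- binarize(rbind(g1 = c(0, 0)), fit, cutoff_c = 0.49)
  expect_identical(as.vector(bc2), c(0L, 0L))
})

test_that("binarize validates coverage and cutoff", {
  co <- simulate_cohort(simulation_config(5, 10, 10, seed = 12))
  fit <- barcode_fit(co$expression)
  bad <- co$expression
  rownames(bad)[1] <- "missing_gene"
  expect_error(binarize(bad, fit), "missing_gene")
  expect_error(binarize(co$expression, fit, cutoff_c = 0.7), "cutoff_c")
})

test_that("binarization is monotone in the intensity", {
  co <- simulate_cohort(low_noise_config(50, 20, 20, seed = 14))
  fit <- barcode_fit(co$expression)
  bc1 <- binarize(co$expression, fit)
  bump <- co$expression
  set.seed(1)
  idx <- sample(length(bump), 200)
  bump[idx] <- bump[idx] + abs(stats::rnorm(200))
  bc2 <- binarize(bump, fit)
  expect_true(all(bc2 >= bc1))
})

test_that("the barcode is location-equivariant under refitting", {
  co <- simulate_cohort(low_noise_config(40, 25, 25, seed = 15))
  bc1 <- binarize(co$expression, barcode_fit(co$expression))
  shifted <- co$expression + 2.5
  bc2 <- binarize(shifted, barcode_fit(shifted))
  expect_identical(bc1, bc2)
})

test_that("well-separated components are barcoded at high fidelity", {
  co <- separated_cohort(300, 50, 50, seed = 16)
  fit <- barcode_fit(co$expression)
  bc <- binarize(co$expression, fit)
  expect_gt(mean(bc == co$true_barcode), 0.99)
})

test_that("frozen mode reproduces externally supplied parameters", {
  co <- simulate_cohort(simulation_config(8, 12, 12, seed = 18))
  frozen <- data.frame(gene_id = rownames(co$expression),
                       mu = co$true_params$mu, tau2 = co$true_params$tau2)
  fit <- barcode_fit(co$expression, frozen = frozen)
  expect_true(fit$frozen)
  expect_equal(fit$genes$mu_hat, frozen$mu)
  expect_error(barcode_fit(co$expression,
                           frozen = frozen[-1, , drop = FALSE]),
               "missing genes")
  # predict on the training matrix equals direct binarization
  expect_identical(predict(fit), binarize(co$expression, fit))
})

test_that("posterior summaries are returned and ordered sensibly", {
  co <- simulate_cohort(simulation_config(40, 40, 40, seed = 19))
  set.seed(20)
  fit <- barcode_fit(co$expression, posterior = TRUE,
                     sweeps = 200, burn = 50)
  g <- fit$genes
  expect_true(all(is.finite(g$mu_post)))
  expect_true(all(g$mu_se > 0))
  expect_true(all(g$p_post >= 0 & g$p_post <= 1))
  expect_true(all(g$tau2_post > 0))
})

test_that("fit methods expose coefficients, residuals and simulation", {
  co <- simulate_cohort(simulation_config(15, 15, 15, seed = 22))
  fit <- barcode_fit(co$expression)
  cf <- coef(fit)
  expect_identical(rownames(cf), rownames(co$expression))
  expect_identical(colnames(cf), c("mu_hat", "tau2_hat", "p_hat", "s_hat"))
  r <- residuals(fit)
  expect_identical(dim(r), dim(co$expression))
  sim <- simulate(fit, nsim = 5, seed = 1)
  sim2 <- simulate(fit, nsim = 5, seed = 1)
  expect_identical(sim, sim2)
  expect_identical(dim(sim), c(15L, 5L))
  s <- summary(fit)
  expect_identical(s$n_genes, 15L)
  expect_lte(s$tau2_shrinkage["shrunk"], s$tau2_shrinkage["raw"])
})
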