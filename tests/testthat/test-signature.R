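test_that("a perfectly informative predictor separates the classes", {
  x <- cbind(g1 = c(1, 1, 1, 0, 0, 0))
  labels <- rep(c("case", "control"), each = 3)
  m <- fit_signature(x, labels, ridge_penalty = 1e-4)
  expect_gt(m$coefficients[["g1"]], 0)
  acc <- mean((predict(m, x) > 0.5) == (labels == "case"))
  expect_equal(acc, 1.0)
})

test_that("an overwhelming penalty shrinks to the prevalence intercept", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("g", 1:3)))
  labels <- rep(c("case", "control"), c(10, 30))
  m <- fit_signature(x, labels, ridge_penalty = 1e8)
  expect_true(all(abs(m$coefficients) < 1e-4))
  expect_equal(m$intercept, stats::qlogis(0.25), tolerance = 1e-2)
})

test_that("null features yield small coefficients and chance-level AUC", {
  set.seed(3)
  x <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("g", 1:5)))
  labels <- rep(c("case", "control"), each = 100)
  m <- fit_signature(x, labels)
  expect_true(all(abs(m$coefficients) < 1))
  auc <- roc_auc(predict(m, x), labels)$auc
  expect_gt(auc, 0.4); expect_lt(auc, 0.7)
})

test_that("with a vanishing penalty the fit approaches glm", {
  set.seed(4)
  x <- matrix(rnorm(120 * 2), 120, dimnames = list(NULL, c("gA", "gB")))
  eta <- 0.5 + 0.8 * x[, 1] - 0.6 * x[, 2]
  labels <- ifelse(runif(120) < plogis(eta), "case", "control")
  m <- fit_signature(x, labels, ridge_penalty = 1e-8)
  ref <- stats::glm((labels == "case") ~ x, family = stats::binomial())
  expect_equal(unname(coef(m)), unname(coef(ref)), tolerance = 1e-4)
})

test_that("constant feature columns are retained with a warning", {
  x <- cbind(g1 = c(1, 1, 0, 0), g2 = c(2, 2, 2, 2))
  expect_warning(m <- fit_signature(x, c("case", "case", "control",
                                         "control")),
                 "constant feature")
  expect_identical(m$gene_panel, c("g1", "g2"))
})

test_that("predicted scores are the inverse-logit of the linear predictor", {
  m <- structure(list(gene_panel = c("gA", "gB"), intercept = -0.5,
                      coefficients = c(gA = 1.2, gB = -0.7),
                      ridge_penalty = 0, converged = TRUE, n = 0,
                      case_level = "case"), class = "signature_model")
  x <- rbind(c(0, 0), c(1, 0), c(0.5, 2))
  colnames(x) <- c("gA", "gB")
  expect_equal(predict(m, x),
               stats::plogis(c(-0.5, 0.7, -0.5 + 0.6 - 1.4)))
  # all-zero features give the intercept; raising gA raises the score
  expect_equal(predict(m, x)[1], stats::plogis(-0.5))
  x2 <- x; x2[, "gA"] <- x2[, "gA"] + 1
  expect_true(all(predict(m, x2) > predict(m, x)))
  expect_error(predict(m, x[, 1, drop = FALSE]), "gB")
})

test_that("roc_auc matches the all-pairs Mann-Whitney computation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                       rep(c("case", "control"), each = 3))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("case", "control"), each = 3))$auc, 0.5)

  brute_auc <- function(scores, is_case) {
    pairs <- expand.grid(i = which(is_case), j = which(!is_case))
    mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
  }
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_case) || all(is_case)) next
    scores <- round(runif(n), 1)   # force ties
    labels <- ifelse(is_case, "case", "control")
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, is_case))
    # curve contract: (0,0) to (1,1), nondecreasing, trapezoid = auc
    pts <- r$points
    expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, r$auc)
  }
})

test_that("AUC is invariant to monotone transforms and flips with sign", {
  set.seed(6)
  scores <- rnorm(40)
  labels <- rep(c("case", "control"), each = 20)
  a1 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(stats::plogis(3 * scores + 1), labels)$auc, a1)
  expect_equal(roc_auc(-scores, labels)$auc + a1, 1.0)
})

test_that("roc_auc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- c(rnorm(30, 1), rnorm(25))
  labels <- rep(c("case", "control"), c(30, 25))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels =
    c("control", "case"), direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("a barcode signature transfers across simulated cohorts", {
  tr <- simulate_cohort(low_noise_config(60, 80, 80, seed = 31,
                                         deg_fraction = 0.25,
                                         p_effect = 0.6))
  # fresh samples from the same gene-level generative parameters
  va <- resim_cohort(tr, seed = 32)
  panel <- tr$true_deg_ids
  feats <- function(co) t(co$true_barcode[panel, ])
  m <- fit_signature(feats(tr), tr$labels)
  expect_true(m$converged)
  auc <- roc_auc(predict(m, feats(va)), va$labels)$auc
  expect_gt(auc, 0.9)
})
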