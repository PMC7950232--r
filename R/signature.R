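#' Fit a ridge-penalized logistic gene signature
#'
#' Maximizes the binomial log-likelihood minus a ridge penalty
#' \eqn{\lambda/2 \sum_j \beta_j^2} (intercept unpenalized) by Newton
#' iterations with step-halving.  The penalty makes the fit deterministic
#' and well-defined even under complete separation — which binary barcode
#' predictors readily produce (a gene expressed in every case and no
#' control separates perfectly, the situation an infinite odds ratio
#' signals).  Predictors may be barcode calls (0/1, the default
#' platform-portable choice in the pipeline) or continuous log2 expression.
#'
#' @param features numeric matrix, samples x panel genes (colnames = gene
#'   identifiers).
#' @param labels two-level group vector, one entry per row.
#' @param ridge_penalty nonnegative penalty \eqn{\lambda}; default 1e-3,
#'   just enough to tame quasi-separation.
#' @param case_level optional label value to treat as the case group.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `"signature_model"`: `gene_panel`,
#'   `intercept`, `coefficients` (named by gene), `ridge_penalty`,
#'   `converged`, `n`, `case_level`.
#' @examples
#' x <- cbind(gA = c(1, 1, 1, 0, 0, 0), gB = c(0, 1, 0, 1, 0, 1))
#' m <- fit_signature(x, rep(c("case", "control"), each = 3))
#' coef(m)
#' @export
fit_signature <- function(features, labels, ridge_penalty = 1e-3,
                          case_level = NULL, max_iter = 100L, tol = 1e-10) {
  if (!is.matrix(features) || !is.numeric(features))
    stop("features must be a numeric samples x genes matrix")
  if (is.null(colnames(features)))
    stop("features must have gene identifiers as colnames")
  f <- as_group_factor(labels, case_level)
  if (length(f) != nrow(features))
    stop("labels length must match the number of rows (samples)")
  if (ridge_penalty < 0) stop("ridge_penalty must be nonnegative")
  const <- apply(features, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant feature column(s) retained under the penalty: ",
            paste(colnames(features)[const], collapse = ", "))
  y <- as.numeric(f == case_level_of(f))
  X <- cbind(`(Intercept)` = 1, features)
  k <- ncol(X)
  D <- diag(c(0, rep(1, k - 1L)))
  beta <- c(stats::qlogis(pmin(pmax(mean(y), 1e-3), 1 - 1e-3)),
            rep(0, k - 1L))
  obj <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) +
      ridge_penalty / 2 * sum(b[-1L]^2)
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, mu - y)) + ridge_penalty * (D %*% beta)
    H <- crossprod(X * w, X) + ridge_penalty * D
    if (ridge_penalty == 0) H <- H + diag(1e-12, k)  # numerical guard only
    step <- drop(solve(H, grad))
    # step-halving keeps the penalized objective decreasing
    s <- 1
    repeat {
      beta_new <- beta - s * step
      f_new <- obj(beta_new)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      s <- s / 2
      if (s < 1e-10) { beta_new <- beta; f_new <- f_old; break }
    }
    done <- abs(f_old - f_new) < tol * (abs(f_old) + tol)
    beta <- beta_new; f_old <- f_new
    if (done) { converged <- TRUE; break }
  }
  structure(list(
    gene_panel = colnames(features),
    intercept = unname(beta[1L]),
    coefficients = stats::setNames(beta[-1L], colnames(features)),
    ridge_penalty = ridge_penalty, converged = converged,
    n = nrow(features), case_level = case_level_of(f)),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(
    "Logistic gene signature: %d genes, ridge penalty %g, n = %d\n",
    length(x$gene_panel), x$ridge_penalty, x$n))
  cat(sprintf("  intercept %.4g; |coef| range [%.4g, %.4g]\n", x$intercept,
              min(abs(x$coefficients)), max(abs(x$coefficients))))
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predicted case probabilities from a gene signature
#'
#' Inverse-logit of the linear predictor; strictly order-preserving in it.
#'
#' @param object a [fit_signature()] model.
#' @param newdata samples x genes matrix covering the model's panel.
#' @param ... unused.
#' @return Numeric vector of risk scores in (0, 1), one per row.
#' @export
predict.signature_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata) || is.null(colnames(newdata)))
    stop("newdata must be a samples x genes matrix with colnames")
  miss <- setdiff(object$gene_panel, colnames(newdata))
  if (length(miss))
    stop("newdata missing panel gene(s): ", paste(miss, collapse = ", "))
  X <- newdata[, object$gene_panel, drop = FALSE]
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' ROC curve and AUC of a score vector
#'
#' AUC is computed by the rank (Mann-Whitney) formula, so it equals the
#' probability a random case outscores a random control, ties counted
#' one-half.  The curve is a threshold sweep over the distinct score
#' values, from (0, 0) to (1, 1).
#'
#' @param scores numeric risk scores, larger = more case-like.
#' @param labels two-level group vector.
#' @param case_level optional label value to treat as the case group.
#' @return A list of class `"roc_result"`: `auc`, `points` (data.frame
#'   `fpr`, `tpr`, nondecreasing, trapezoidal area = `auc`), `n_case`,
#'   `n_control`.
#' @examples
#' roc_auc(c(.9, .8, .7, .4, .3, .35),
#'         rep(c("case", "control"), each = 3))
#' @export
roc_auc <- function(scores, labels, case_level = NULL) {
  f <- as_group_factor(labels, case_level)
  if (length(scores) != length(f)) stop("scores and labels differ in length")
  if (any(table(f) == 0)) stop("both classes must be present")
  is_case <- f == case_level_of(f)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep grouped on distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_case[ord]); fp <- cumsum(!is_case[ord])
  keep <- which(c(diff(scores[ord]) != 0, TRUE))  # last index of each tie group
  pts <- rbind(c(0, 0), cbind(fp[keep] / n0, tp[keep] / n1))
  colnames(pts) <- c("fpr", "tpr")
  structure(list(auc = auc,
                 points = as.data.frame(pts),
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cases vs %d controls, %d curve points)\n",
              x$auc, x$n_case, x$n_control, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
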