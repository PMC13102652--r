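# Shrinkage-regularized linear discriminant analysis.
#
# Pooled within-class covariance shrunk toward a scaled identity with an
# analytic (Ledoit-Wolf-type) intensity estimated from the data. This is
# the standard classifier behind filter-bank CSP log-variance features:
# deterministic, well-posed even when features outnumber trials.

slda_fit <- function(X, y, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  classes <- sort(unique(y))
  p <- ncol(X)
  n <- nrow(X)
  means <- t(vapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(p)))
  Xc <- X - means[match(y, classes), , drop = FALSE]

  S <- crossprod(Xc) / (n - length(classes))
  if (is.null(gamma)) {
    # analytic shrinkage toward nu*I, nu = mean diagonal variance
    W2 <- crossprod(Xc^2) / n
    varS <- (n / (n - 1)^2) * (W2 - (crossprod(Xc) / n)^2)
    Tgt <- diag(mean(diag(S)), p)
    denom <- sum((S - Tgt)^2)
    gamma <- if (denom > 0) sum(varS) / denom else 1
    gamma <- min(1, max(0, gamma))
  }
  Sg <- (1 - gamma) * S + gamma * diag(mean(diag(S)), p)
  Sinv <- tryCatch(solve(Sg), error = function(e) {
    warning("singular within-class scatter; falling back to full shrinkage")
    solve(diag(mean(diag(S)), p))
  })
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  structure(list(classes = classes, means = means, Sinv = Sinv,
                 log_priors = log(priors), gamma = gamma),
            class = "slda")
}

slda_predict <- function(fit, X) {
  X <- as.matrix(X)
  M <- fit$means                       # K x p
  A <- fit$Sinv %*% t(M)               # p x K
  scores <- X %*% A                    # n x K
  scores <- sweep(scores, 2, 0.5 * colSums(t(M) * A), "-")
  scores <- sweep(scores, 2, fit$log_priors, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}
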