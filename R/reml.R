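#' REML variance components by Monte-Carlo EM
#'
#' Estimates the additive and residual variances of the animal model
#' `y = 1 mu + u + e`, `u ~ N(0, K sigma2_a)`, `e ~ N(0, I sigma2_e)` by a
#' stochastic (Monte-Carlo) EM algorithm: each iteration performs one Gibbs
#' sweep drawing `(u, mu)` from their full conditionals given the current
#' variances (the E-step sample) and then updates
#' `sigma2_a <- u' K^-1 u / q` and `sigma2_e <- e'e / n` (the M-step). The
#' final estimates are the means of the post-burn-in per-iteration values.
#'
#' The sweep works in the eigenbasis of K, computed once per call: there
#' the full conditional of the rotated breeding values is diagonal, so each
#' E-step is an exact joint draw at O(n^2) cost and no matrix is ever
#' re-factorized inside the chain - the point of the Monte-Carlo EM
#' approach over exact REML.
#'
#' @param y Phenotypes, one record per individual in `K`.
#' @param K A `relationship_matrix` (or plain symmetric matrix) over the
#'   phenotyped individuals.
#' @param n_iter Total EM iterations (default 6000).
#' @param burnin Iterations discarded before averaging (default 1000).
#' @param floor Lower bound keeping variances away from the absorbing state
#'   at zero.
#' @return A `reml_fit`: estimates `sigma2_a`, `sigma2_e`, their naive
#'   Monte-Carlo standard errors, and the full `chain` tibble.
#' @export
mcem_reml <- function(y, K, n_iter = 6000, burnin = 1000, floor = 1e-8) {
  stopifnot(burnin < n_iter)
  V <- if (inherits(K, "relationship_matrix")) K$values else K
  if (length(y) != nrow(V)) {
    abort("length(y) must match the relationship matrix order",
          class = "coansel_invalid_argument")
  }
  n <- length(y)
  if (inherits(K, "relationship_matrix") && K$kind != "A") {
    diag(V) <- diag(V) + 1e-6
  }
  eg <- eigen(V, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-10)
  Q <- eg$vectors
  Qty <- drop(crossprod(Q, y))
  Qt1 <- drop(crossprod(Q, rep(1, n)))

  s2a <- s2e <- max(var(y) / 2, floor)
  mu <- mean(y)
  u <- rep(0, n)
  chain_a <- chain_e <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    # v | mu, variances: diagonal precision in the eigenbasis
    d <- 1 / s2e + 1 / (lam * s2a)
    m <- (Qty - mu * Qt1) / s2e / d
    v <- m + rnorm(n) / sqrt(d)
    u <- drop(Q %*% v)
    # mu | u
    mu <- rnorm(1, mean(y - u), sqrt(s2e / n))
    # M-step from the current draw
    s2a <- max(sum(v^2 / lam) / n, floor)
    s2e <- max(sum((y - mu - u)^2) / n, floor)
    if (!is.finite(s2a) || !is.finite(s2e)) {
      abort("Monte-Carlo EM chain diverged",
            class = "coansel_numerical_failure")
    }
    chain_a[it] <- s2a
    chain_e[it] <- s2e
  }
  keep <- (burnin + 1):n_iter
  structure(
    list(
      sigma2_a = mean(chain_a[keep]),
      sigma2_e = mean(chain_e[keep]),
      mc_se_a = sd(chain_a[keep]) / sqrt(length(keep)),
      mc_se_e = sd(chain_e[keep]) / sqrt(length(keep)),
      n_iter = n_iter, burnin = burnin,
      matrix_kind = if (inherits(K, "relationship_matrix")) K$kind else NA,
      chain = tibble::tibble(iteration = seq_len(n_iter),
                             sigma2_a = chain_a, sigma2_e = chain_e)
    ),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> sigma2_a = ", signif(x$sigma2_a, 4), " (mc se ",
      signif(x$mc_se_a, 2), "), sigma2_e = ", signif(x$sigma2_e, 4),
      " (mc se ", signif(x$mc_se_e, 2), "), ", x$n_iter, " iterations (",
      x$burnin, " burn-in)\n", sep = "")
  invisible(x)
}

#' @rdname mcem_reml
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma2_a", "sigma2_e"),
                 estimate = c(x$sigma2_a, x$sigma2_e),
                 mc_se = c(x$mc_se_a, x$mc_se_e))
}

#' @rdname mcem_reml
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
                 h2 = x$sigma2_a / (x$sigma2_a + x$sigma2_e),
                 n_iter = x$n_iter, burnin = x$burnin,
                 matrix_kind = x$matrix_kind)
}
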