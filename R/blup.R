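#' Solve Henderson's mixed-model equations
#'
#' Animal model with a single overall mean as the only fixed effect and one
#' phenotype record per individual, so `X` is a column of ones and `Z` the
#' identity. The coefficient matrix
#' `[X'X X'Z; Z'X Z'Z + lambda K^-1]` with `lambda = sigma2_e / sigma2_a`
#' is solved exactly (dense symmetric factorization). Any of the four
#' relationship matrices may stand in for K, giving pedigree-based or
#' genomic EBVs.
#'
#' @param y Phenotypes, one per individual in `K`.
#' @param K A `relationship_matrix` over the phenotyped individuals.
#' @param sigma2_a Additive variance (> 0).
#' @param sigma2_e Residual variance.
#' @return An `mme_fit`: `mu_hat`, named `ebv` vector, `matrix_kind`,
#'   `lambda`.
#' @export
solve_mme <- function(y, K, sigma2_a, sigma2_e) {
  stopifnot(sigma2_a > 0, sigma2_e >= 0)
  n <- length(y)
  if (n != nrow(K$values)) {
    abort("length(y) must match the relationship matrix order",
          class = "coansel_invalid_argument")
  }
  lambda <- sigma2_e / sigma2_a
  Kinv <- relationship_inverse(K)
  C <- matrix(0, n + 1, n + 1)
  C[1, 1] <- n
  C[1, -1] <- C[-1, 1] <- 1
  C[-1, -1] <- diag(n) + lambda * Kinv
  rhs <- c(sum(y), y)
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    abort("mixed-model coefficient matrix is singular",
          class = "coansel_numerical_failure")
  })
  structure(
    list(mu_hat = sol[1], ebv = setNames(sol[-1], K$ids),
         matrix_kind = K$kind, lambda = lambda,
         sigma2_a = sigma2_a, sigma2_e = sigma2_e),
    class = "mme_fit"
  )
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("<mme_fit> kind ", x$matrix_kind, ", ", length(x$ebv),
      " EBVs, mu_hat = ", signif(x$mu_hat, 5), ", lambda = ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname solve_mme
#' @param x An `mme_fit`.
#' @param ... Unused.
#' @export
tidy.mme_fit <- function(x, ...) {
  tibble::tibble(id = as.integer(names(x$ebv)), ebv = unname(x$ebv))
}

#' @rdname solve_mme
#' @export
glance.mme_fit <- function(x, ...) {
  tibble::tibble(mu_hat = x$mu_hat, lambda = x$lambda,
                 matrix_kind = x$matrix_kind, n = length(x$ebv))
}
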