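#' Draw additive QTL effects
#'
#' Allele-substitution effects are i.i.d. standard normal.
#'
#' @param n_qtl Number of QTLs.
#' @return Numeric vector of effects.
#' @export
draw_effects <- function(n_qtl) {
  stopifnot(n_qtl >= 1)
  rnorm(n_qtl)
}

#' Trait architecture
#'
#' Bundles the QTL positions and effects with the trait's mean and variance
#' components. The heritability must satisfy
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param qtl_indices Locus indices of the QTLs.
#' @param effects Per-QTL additive effects of allele 1.
#' @param mu Phenotypic mean (default 100; it does not affect EBV ranking).
#' @param sigma2_a Additive-genetic variance (> 0).
#' @param sigma2_e Residual variance (>= 0).
#' @return A `trait_architecture` object.
#' @export
trait_architecture <- function(qtl_indices, effects, mu = 100,
                               sigma2_a, sigma2_e) {
  stopifnot(length(qtl_indices) == length(effects), sigma2_a > 0,
            sigma2_e >= 0)
  structure(
    list(qtl_indices = as.integer(qtl_indices), effects = effects,
         mu = mu, sigma2_a = sigma2_a, sigma2_e = sigma2_e,
         h2 = sigma2_a / (sigma2_a + sigma2_e)),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", length(x$effects), " QTLs, mu = ", x$mu,
      ", sigma2_a = ", signif(x$sigma2_a, 4), ", sigma2_e = ",
      signif(x$sigma2_e, 4), " (h2 = ", signif(x$h2, 3), ")\n", sep = "")
  invisible(x)
}

#' True breeding values
#'
#' `TBV_i = sum_j a_j (x_ij - 1)` where `x_ij` is individual i's count of
#' allele 1 at QTL j, so an all-heterozygous genotype has TBV 0.
#'
#' @param x Genotype dosage matrix (individuals x QTLs) with values in
#'   \{0, 1, 2\}, e.g. from [genotype_counts()] at the QTL indices; a vector
#'   is treated as one individual.
#' @param effects Per-QTL effects.
#' @return Numeric TBV per individual (named by row names if present).
#' @export
compute_tbv <- function(x, effects) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(effects)) {
    abort("number of genotype columns must equal number of effects",
          class = "coansel_invalid_argument")
  }
  drop((x - 1) %*% effects)
}

#' Calibrate variance components to a target heritability
#'
#' The additive variance is the empirical (n-1 denominator) variance of the
#' base population's TBVs; the residual variance is then set so that
#' `sigma2_a / (sigma2_a + sigma2_e)` equals the desired heritability.
#'
#' @param base_tbvs TBVs of the base population (>= 2 values).
#' @param h2 Target heritability in (0, 1).
#' @return A list with `sigma2_a` and `sigma2_e`.
#' @export
calibrate_variances <- function(base_tbvs, h2) {
  if (length(h2) != 1 || is.na(h2) || h2 <= 0 || h2 >= 1) {
    abort("`h2` must lie strictly in (0, 1)",
          class = "coansel_invalid_argument")
  }
  stopifnot(length(base_tbvs) >= 2)
  sigma2_a <- var(base_tbvs)
  list(sigma2_a = sigma2_a, sigma2_e = sigma2_a * (1 - h2) / h2)
}

#' Simulate phenotypes
#'
#' `y_i = mu + TBV_i + e_i` with `e_i ~ N(0, sigma2_e)` i.i.d.
#'
#' @param tbvs True breeding values.
#' @param arch A [trait_architecture()].
#' @return Numeric phenotypes.
#' @export
simulate_phenotypes <- function(tbvs, arch) {
  arch$mu + tbvs + rnorm(length(tbvs), 0, sqrt(arch$sigma2_e))
}
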