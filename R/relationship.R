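#' Relationship matrix container
#'
#' All four relationship matrices in this package are stored on the same
#' scale as the pedigree-based additive relationship: twice the coancestry
#' coefficient, so a non-inbred individual's diagonal entry is 1 under A and
#' the coancestry between two individuals is half the stored entry.
#'
#' @param values Symmetric numeric matrix of relationships (2 x coancestry).
#' @param kind One of `"A"` (pedigree/IBD), `"G"` (IBS), `"R"`
#'   (ROH-segment) or `"V"` (VanRaden).
#' @param ids Individual ids in matrix order.
#' @return A `relationship_matrix`.
#' @export
relationship_matrix <- function(values, kind, ids) {
  kind <- match.arg(kind, c("A", "G", "R", "V"))
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            length(ids) == nrow(values))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, kind = kind, ids = as.integer(ids)),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> kind ", x$kind, ", ", nrow(x$values),
      " individuals (entries are 2 x coancestry)\n", sep = "")
  invisible(x)
}

#' Coancestry coefficients of a relationship matrix
#' @param K A `relationship_matrix`.
#' @return Symmetric matrix of coancestries f = K / 2.
#' @export
coancestry <- function(K) K$values / 2

#' Per-individual inbreeding coefficients of a relationship matrix
#'
#' Uniform rule `F_i = K_ii - 1` on the relationship scale. For A this is
#' the pedigree inbreeding coefficient; for G it is the individual's
#' observed homozygosity mapped so a fully heterozygous individual has
#' F = 0; for R it is the ROH fraction of the individual's own two gametes;
#' for V it is the frequency-centered homozygosity excess (possibly
#' negative).
#'
#' @param K A `relationship_matrix`.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(K) setNames(diag(K$values) - 1, K$ids)

#' Pedigree-based additive relationship matrix (A)
#'
#' Tabular (recursive) method: founders are unrelated and non-inbred
#' (diagonal 1); `a_ii = 1 + a_sd / 2` for parents s, d and
#' `a_ij = (a_js + a_jd) / 2` for an older individual j. Entries are twice
#' the identity-by-descent coancestry.
#'
#' @param pedigree Tibble with columns id, sire, dam (NA or 0 = unknown),
#'   ordered parents before offspring.
#' @return A `relationship_matrix` of kind `"A"`.
#' @export
pedigree_A <- function(pedigree) {
  id <- pedigree$id
  if (anyDuplicated(id)) {
    abort("duplicate ids in pedigree", class = "coansel_invalid_pedigree")
  }
  code <- function(p) {
    p[is.na(p)] <- 0L
    out <- ifelse(p == 0L, 0L, match(p, id))
    if (anyNA(out)) {
      abort("pedigree parent id not found among ids",
            class = "coansel_invalid_pedigree")
    }
    as.integer(out)
  }
  s <- code(pedigree$sire)
  d <- code(pedigree$dam)
  if (any(s >= seq_along(id) & s > 0L) || any(d >= seq_along(id) & d > 0L)) {
    abort("pedigree must list parents before offspring",
          class = "coansel_invalid_pedigree")
  }
  relationship_matrix(cpp_tabular_A(s, d), "A", id)
}

panel_columns <- function(pop, panel) {
  if (is.null(panel)) seq_len(n_loci(pop$map)) else panel$marker_indices
}

#' Identity-by-state (IBS) relationship matrix (G)
#'
#' The IBS coancestry between individuals i and k is, per marker, the
#' fraction of the four ordered gamete pairs (two gametes of i crossed with
#' two of k) carrying identical alleles, averaged over markers. The
#' diagonal uses the individual's own four gamete pairs, so
#' `f_G(i, i) = 1 - H_i / 2` with `H_i` the observed heterozygosity.
#'
#' @param pop A `population`.
#' @param panel Optional [marker_panel()]; default uses all loci.
#' @return A `relationship_matrix` of kind `"G"` (entries 2 x coancestry).
#' @export
ibs_G <- function(pop, panel = NULL) {
  cols <- panel_columns(pop, panel)
  M <- length(cols)
  if (M < 1) abort("need at least one marker",
                   class = "coansel_invalid_argument")
  X <- genotype_counts(pop)[, cols, drop = FALSE]
  # matches among the 4 ordered gamete pairs at a biallelic marker:
  # x_i x_k + (2 - x_i)(2 - x_k)
  f <- (tcrossprod(X) + tcrossprod(2 - X)) / (4 * M)
  relationship_matrix(2 * f, "G", pop$id)
}

#' ROH-segment relationship matrix (R)
#'
#' For each of the four ordered gamete pairs of two individuals, maximal
#' runs of contiguous markers with identical alleles are found (runs never
#' span chromosome boundaries); only runs of at least `min_run` markers
#' contribute, each its marker-count length, and
#' `f_R = contributed length / (4L)` with `L` the total panel marker count.
#' A shared segment between two gametes is a potential run of homozygosity
#' in an offspring, which is what makes this a segment-based coancestry.
#'
#' @param pop A `population`.
#' @param panel Optional [marker_panel()]; default all loci.
#' @param min_run Minimum run length in markers (default 100, held constant
#'   across panel densities).
#' @return A `relationship_matrix` of kind `"R"` (entries 2 x coancestry).
#' @export
roh_R <- function(pop, panel = NULL, min_run = 100) {
  stopifnot(min_run >= 1)
  cols <- panel_columns(pop, panel)
  H <- pop$haplotypes[, cols, drop = FALSE]
  f <- cpp_roh_f(H, pop$map$chr[cols], as.integer(min_run))
  relationship_matrix(2 * f, "R", pop$id)
}

#' Genomic span of the minimum ROH run
#'
#' The genetic distance (in centiMorgans) covered by `min_run` consecutive
#' markers of an evenly spaced panel: with 2525 markers on a 1-Morgan
#' chromosome a 100-marker run spans about 4 cM, with 10,100 markers about
#' 1 cM.
#'
#' @param map A [genome_map()].
#' @param markers_per_chromosome Panel density.
#' @param min_run Run threshold in markers.
#' @return Span in centiMorgans.
#' @export
roh_min_span_cM <- function(map, markers_per_chromosome, min_run = 100) {
  min_run * map$chromosome_length * 100 / markers_per_chromosome
}

#' VanRaden allele-frequency-corrected relationship matrix (V)
#'
#' `f_V(i,k) = (1/M) sum_n (g_in - p)(g_kn - p) / (p(1-p))` with gene
#' frequency `g = copies of allele 1 / 2` (0, 0.5 or 1) and all reference
#' frequencies fixed at `p = 0.5`. (An equivalent coding counts allele 0
#' instead: with p = 0.5 the sign cancels inside the symmetric product.)
#' Entries may be negative, e.g. -2 between opposite homozygotes.
#'
#' @param pop A `population`.
#' @param panel Optional [marker_panel()]; default all loci.
#' @param p Reference allele frequency, fixed at 0.5.
#' @return A `relationship_matrix` of kind `"V"` (entries 2 x coancestry).
#' @export
vanraden_V <- function(pop, panel = NULL, p = 0.5) {
  cols <- panel_columns(pop, panel)
  M <- length(cols)
  if (M < 1) abort("need at least one marker",
                   class = "coansel_invalid_argument")
  g <- genotype_counts(pop)[, cols, drop = FALSE] / 2
  f <- tcrossprod(g - p) / (M * p * (1 - p))
  relationship_matrix(2 * f, "V", pop$id)
}

#' Build any of the four relationship matrices
#'
#' @param kind `"A"`, `"G"`, `"R"` or `"V"`.
#' @param pop A `population` (needed for G, R, V).
#' @param pedigree Pedigree tibble (needed for A); rows must cover exactly
#'   the individuals of interest.
#' @param panel Optional [marker_panel()].
#' @param min_run ROH threshold (used by R only).
#' @return A `relationship_matrix`.
#' @export
build_relationship <- function(kind, pop = NULL, pedigree = NULL,
                               panel = NULL, min_run = 100) {
  kind <- match.arg(kind, c("A", "G", "R", "V"))
  switch(kind,
         A = pedigree_A(pedigree),
         G = ibs_G(pop, panel),
         R = roh_R(pop, panel, min_run),
         V = vanraden_V(pop, panel))
}

subset_relationship <- function(K, idx) {
  relationship_matrix(K$values[idx, idx, drop = FALSE], K$kind, K$ids[idx])
}

# Regularized inverse: genomic matrices over close relatives are
# near-singular, so G, R and V always get a small diagonal ridge; A only
# when its factorization fails. The segment-based matrix is not guaranteed
# positive semidefinite (run thresholding breaks the Gram structure), so if
# the ridged Cholesky still fails the inverse is taken on the nearest
# eigenvalue-floored matrix.
relationship_inverse <- function(K, epsilon = 1e-6) {
  V <- K$values
  if (K$kind != "A") diag(V) <- diag(V) + epsilon
  inv <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(inv)) {
    eg <- eigen(V, symmetric = TRUE)
    lam <- pmax(eg$values, epsilon)
    inv <- eg$vectors %*% (t(eg$vectors) / lam)
  }
  inv
}

#' Summarize a relationship matrix as coancestries
#'
#' Reports the mean and variance of the pairwise (off-diagonal)
#' coancestries, the mean inbreeding coefficient from the diagonal, and a
#' histogram of the pairwise coancestries.
#'
#' @param K A `relationship_matrix`.
#' @param bins Number of histogram bins.
#' @return A list of class `coancestry_summary` with a one-row `summary`
#'   tibble (kind, n, mean_f, var_f, mean_F) and a `histogram` tibble
#'   (bin_mid, bin_width, count).
#' @export
coancestry_summary <- function(K, bins = 30) {
  f <- coancestry(K)
  n <- nrow(f)
  stopifnot(n >= 2)
  off <- f[upper.tri(f)]
  brk <- seq(min(off), max(off), length.out = bins + 1)
  if (brk[1] == brk[bins + 1]) brk <- brk[1] + c(-0.5, 0.5) / bins
  h <- graphics::hist(off, breaks = if (length(brk) > 2) brk else 2,
                      plot = FALSE)
  structure(
    list(
      summary = tibble::tibble(
        kind = K$kind, n = n, mean_f = mean(off), var_f = var(off),
        mean_F = mean(inbreeding(K))),
      histogram = tibble::tibble(
        kind = K$kind, bin_mid = h$mids,
        bin_width = diff(h$breaks), count = h$counts)
    ),
    class = "coancestry_summary"
  )
}

#' @export
print.coancestry_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
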