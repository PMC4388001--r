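#' Genome map
#'
#' Describes a genome of `n_chromosomes` chromosomes, each of genetic length
#' `chromosome_length` Morgans carrying `loci_per_chromosome` biallelic loci
#' at equally spaced genetic positions. Loci are ordered by (chromosome,
#' position) throughout the package.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param loci_per_chromosome Number of biallelic loci on each chromosome.
#' @param chromosome_length Genetic length of each chromosome in Morgans.
#' @return An object of class `genome_map` with per-locus chromosome index
#'   and genetic position (Morgans).
#' @examples
#' gm <- genome_map(n_chromosomes = 2, loci_per_chromosome = 100)
#' n_loci(gm)
#' @export
genome_map <- function(n_chromosomes = 10, loci_per_chromosome = 10100,
                       chromosome_length = 1) {
  stopifnot(n_chromosomes >= 1, loci_per_chromosome >= 1,
            chromosome_length > 0)
  L <- loci_per_chromosome
  pos_one <- (seq_len(L) - 0.5) / L * chromosome_length
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      loci_per_chromosome = as.integer(L),
      chromosome_length = chromosome_length,
      chr = rep(seq_len(n_chromosomes), each = L),
      pos = rep(pos_one, times = n_chromosomes)
    ),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$n_chromosomes, " chromosome(s) x ",
      x$loci_per_chromosome, " loci, ", x$chromosome_length,
      " Morgan(s) each\n", sep = "")
  invisible(x)
}

#' Total number of loci of a genome map
#' @param map A [genome_map()].
#' @return Integer count of loci.
#' @export
n_loci <- function(map) length(map$chr)

new_population <- function(haplotypes, id, sex, generation, map) {
  stopifnot(nrow(haplotypes) == 2L * length(id),
            ncol(haplotypes) == n_loci(map),
            length(sex) == length(id), length(generation) == length(id))
  structure(
    list(haplotypes = haplotypes, id = as.integer(id), sex = sex,
         generation = as.integer(generation), map = map),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", n_ind(x), " individuals (",
      sum(x$sex == "M"), " M / ", sum(x$sex == "F"), " F), ",
      n_loci(x$map), " loci, generation(s) ",
      paste(unique(x$generation), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @return Integer count.
#' @export
n_ind <- function(pop) length(pop$id)

hap_rows <- function(i) as.vector(rbind(2L * i - 1L, 2L * i))

#' Initialize a base population at maximal diversity
#'
#' Creates `n_individuals` diploid individuals (half males, half females)
#' whose alleles are all drawn independently and uniformly from \{0, 1\}, so
#' the expected heterozygosity at every locus is 0.5.
#'
#' @param map A [genome_map()].
#' @param n_individuals Even number of individuals to create.
#' @return A `population`.
#' @examples
#' set.seed(1)
#' pop <- init_base(genome_map(2, 100), 10)
#' heterozygosity(pop)
#' @export
init_base <- function(map, n_individuals) {
  if (length(n_individuals) != 1 || n_individuals < 2 ||
      n_individuals %% 2 != 0) {
    rlang::abort("`n_individuals` must be an even count >= 2",
                 class = "coansel_invalid_argument")
  }
  n <- as.integer(n_individuals)
  L <- n_loci(map)
  H <- matrix(sample(c(0L, 1L), 2L * n * L, replace = TRUE),
              nrow = 2L * n, ncol = L)
  new_population(H, seq_len(n),
                 rep(c("M", "F"), each = n / 2L),
                 rep(0L, n), map)
}

#' Mean observed heterozygosity
#'
#' Fraction of (individual, locus) pairs at which the two allele copies
#' differ, averaged genome-wide over the whole population.
#'
#' @param pop A `population`.
#' @return A fraction in \[0, 1\].
#' @export
heterozygosity <- function(pop) {
  if (n_ind(pop) == 0) {
    rlang::abort("empty population", class = "coansel_invalid_argument")
  }
  n <- n_ind(pop)
  odd <- 2L * seq_len(n) - 1L
  mean(pop$haplotypes[odd, , drop = FALSE] !=
         pop$haplotypes[odd + 1L, , drop = FALSE])
}

mutate_haplotypes <- function(H, mu) {
  len <- length(H)
  n_flip <- stats::rbinom(1L, len, mu)
  if (n_flip > 0) {
    idx <- sample.int(len, n_flip)
    H[idx] <- 1L - H[idx]
  }
  H
}

#' Apply symmetric per-copy mutation
#'
#' Each allele copy (one per haplotype per locus) flips 0 <-> 1 independently
#' with probability `mu` per call (one generation).
#'
#' @param pop A `population`.
#' @param mu Per-position, per-generation mutation rate in \[0, 1\].
#' @return The mutated `population`.
#' @export
mutate_population <- function(pop, mu) {
  if (length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1) {
    rlang::abort("`mu` must be a rate in [0, 1]",
                 class = "coansel_invalid_argument")
  }
  pop$haplotypes <- mutate_haplotypes(pop$haplotypes, mu)
  pop
}

#' Form one gamete by meiosis
#'
#' The number of crossovers per chromosome is Poisson with mean equal to the
#' chromosome's genetic length in Morgans; crossover positions are uniform on
#' the chromosome; the starting parental strand is chosen at random and the
#' gamete alternates strands at each crossover. Chromosomes segregate
#' independently.
#'
#' @param haplotypes A 2-row integer matrix: the parent's two haplotypes.
#' @param map A [genome_map()].
#' @return An integer allele vector of length `n_loci(map)`.
#' @export
make_gamete <- function(haplotypes, map) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2,
            ncol(haplotypes) == n_loci(map))
  cpp_gamete(haplotypes[1L, ], haplotypes[2L, ], map$chr, map$pos,
             map$chromosome_length)
}

breed_offspring <- function(pop, sire_idx, dam_idx) {
  cpp_breed(pop$haplotypes, as.integer(sire_idx), as.integer(dam_idx),
            pop$map$chr, pop$map$pos, pop$map$chromosome_length)
}

#' Evolve a population neutrally
#'
#' Runs non-overlapping generations of random mating under mutation, drift
#' and recombination. Each generation, all parents are first mutated, then
#' `n_ind(pop)` offspring are produced, each from a sire and a dam drawn
#' independently and uniformly with replacement; offspring sexes are half
#' male, half female.
#'
#' @param pop A `population` with at least one individual of each sex.
#' @param n_generations Number of generations to run.
#' @param mu Per-position, per-generation mutation rate.
#' @param track_heterozygosity If `TRUE`, record mean heterozygosity after
#'   each generation in the returned population's `het_history` tibble.
#' @return The evolved `population` (same size); if tracking, with a
#'   `het_history` tibble of columns `generation`, `heterozygosity`.
#' @examples
#' set.seed(1)
#' pop <- init_base(genome_map(2, 50), 20)
#' pop <- evolve_base(pop, 5, mu = 0)
#' @export
evolve_base <- function(pop, n_generations, mu,
                        track_heterozygosity = FALSE) {
  stopifnot(n_generations >= 0)
  males <- which(pop$sex == "M")
  females <- which(pop$sex == "F")
  if (length(males) == 0 || length(females) == 0) {
    rlang::abort("population must contain both sexes",
                 class = "coansel_invalid_state")
  }
  n <- n_ind(pop)
  hist <- if (track_heterozygosity) {
    pop$het_history %||% tibble::tibble(generation = integer(),
                                        heterozygosity = double())
  }
  gen0 <- max(pop$generation)
  for (g in seq_len(n_generations)) {
    pop$haplotypes <- mutate_haplotypes(pop$haplotypes, mu)
    sires <- sample(males, n, replace = TRUE)
    dams <- sample(females, n, replace = TRUE)
    pop$haplotypes <- breed_offspring(pop, sires, dams)
    pop$id <- pop$id[n] + seq_len(n)
    pop$sex <- rep(c("M", "F"), each = n / 2L)
    pop$generation <- rep(gen0 + g, n)
    males <- which(pop$sex == "M")
    females <- which(pop$sex == "F")
    if (track_heterozygosity) {
      hist <- dplyr::bind_rows(hist, tibble::tibble(
        generation = gen0 + g, heterozygosity = heterozygosity(pop)))
    }
  }
  if (track_heterozygosity) pop$het_history <- hist
  pop
}

#' Simulate a mutation-drift-recombination base population
#'
#' Convenience wrapper: initialize at heterozygosity 0.5 and run a burn-in of
#' random-mating generations towards mutation-drift equilibrium.
#'
#' @param map A [genome_map()].
#' @param n_individuals Population size (even; half each sex).
#' @param n_generations Burn-in length in generations.
#' @param mu Per-position, per-generation mutation rate.
#' @param seed Optional integer seed (calls [set.seed()]).
#' @return A `population` carrying a `het_history` tibble.
#' @export
sim_base_population <- function(map, n_individuals, n_generations,
                                mu = 2.5e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- init_base(map, n_individuals)
  evolve_base(pop, n_generations, mu, track_heterozygosity = TRUE)
}

#' Genotype dosage matrix
#'
#' Counts of allele 1 per individual and locus.
#'
#' @param pop A `population`.
#' @param loci Optional locus index subset (e.g. a marker panel's indices).
#' @return An integer matrix (individuals x loci) with values in \{0, 1, 2\};
#'   row names are individual ids.
#' @export
genotype_counts <- function(pop, loci = NULL) {
  n <- n_ind(pop)
  odd <- 2L * seq_len(n) - 1L
  H <- pop$haplotypes
  if (!is.null(loci)) H <- H[, loci, drop = FALSE]
  X <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(X) <- pop$id
  X
}
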