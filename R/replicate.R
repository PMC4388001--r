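#' Sample QTL positions from a base population
#'
#' Draws `n_qtl` distinct loci, uniformly, from those whose allele-1
#' frequency `p_j` in the base population lies strictly inside
#' `(freq_lo, freq_hi)`.
#'
#' @param base A base `population`.
#' @param n_qtl Number of selective loci (QTLs) to draw.
#' @param freq_lo,freq_hi Strict allele-frequency bounds; default (0.05,
#'   0.95) keeps only clearly polymorphic positions.
#' @return Sorted integer vector of locus indices.
#' @export
sample_qtls <- function(base, n_qtl, freq_lo = 0.05, freq_hi = 0.95) {
  p <- colMeans(base$haplotypes)
  eligible <- which(p > freq_lo & p < freq_hi)
  if (length(eligible) < n_qtl) {
    abort(paste0("only ", length(eligible), " loci have allele frequency in (",
                 freq_lo, ", ", freq_hi, "); ", n_qtl, " requested"),
          class = "coansel_invalid_state")
  }
  sort(sample(eligible, n_qtl))
}

new_pedigree <- function(id, sire, dam, sex, generation) {
  tibble::tibble(id = as.integer(id), sire = as.integer(sire),
                 dam = as.integer(dam), sex = sex,
                 generation = as.integer(generation))
}

#' Draw founders from a base population
#'
#' Samples `N` males and `N` females without replacement, relabels them
#' 1..2N and starts a pedigree at generation 0 with unknown parents.
#'
#' @param base A base `population`.
#' @param N Founders per sex.
#' @return A list with elements `population` (the 2N founders) and
#'   `pedigree` (a tibble with columns id, sire, dam, sex, generation;
#'   `NA` parent means unknown).
#' @export
draw_founders <- function(base, N) {
  males <- which(base$sex == "M")
  females <- which(base$sex == "F")
  if (length(males) < N || length(females) < N) {
    abort("base population has fewer than N individuals of a sex",
          class = "coansel_invalid_argument")
  }
  pick <- c(sample(males, N), sample(females, N))
  H <- base$haplotypes[hap_rows(pick), , drop = FALSE]
  pop <- new_population(H, seq_len(2L * N),
                        rep(c("M", "F"), each = N),
                        rep(0L, 2L * N), base$map)
  ped <- new_pedigree(seq_len(2L * N), NA_integer_, NA_integer_,
                      pop$sex, 0L)
  list(population = pop, pedigree = ped)
}

# Append one recorded generation: 2N offspring (first N male, then N female),
# each from a sire and dam drawn independently and uniformly with replacement
# from the given parent ids. Mutation is applied to the newly formed gametes.
append_generation <- function(pop, pedigree, sire_ids, dam_ids, N, mu) {
  sires <- sample(rep(sire_ids, 2L), 2L * N, replace = TRUE)
  dams <- sample(rep(dam_ids, 2L), 2L * N, replace = TRUE)
  H_new <- breed_offspring(pop, match(sires, pop$id), match(dams, pop$id))
  if (mu > 0) H_new <- mutate_haplotypes(H_new, mu)
  gen <- max(pop$generation) + 1L
  new_ids <- max(pop$id) + seq_len(2L * N)
  sex <- rep(c("M", "F"), each = N)
  pop$haplotypes <- rbind(pop$haplotypes, H_new)
  pop$id <- c(pop$id, new_ids)
  pop$sex <- c(pop$sex, sex)
  pop$generation <- c(pop$generation, rep(gen, 2L * N))
  pedigree <- dplyr::bind_rows(
    pedigree, new_pedigree(new_ids, sires, dams, sex, gen))
  list(population = pop, pedigree = pedigree)
}

#' Random-mating generations with genealogy recording
#'
#' Runs `n_gen` non-overlapping generations of random mating among the most
#' recent generation's `N` sires and `N` dams, appending every birth to the
#' pedigree. All individuals (every generation) are retained in the returned
#' population so that genomic relationship matrices can later be built over
#' the whole recorded history.
#'
#' @param pop Accumulated `population` (e.g. from [draw_founders()]).
#' @param pedigree Pedigree tibble consistent with `pop`.
#' @param n_gen Number of generations to run.
#' @param N Sires (= dams) produced per generation.
#' @param mu Per-position, per-generation mutation rate applied to newly
#'   formed gametes.
#' @return A list with updated `population` and `pedigree`.
#' @export
random_mating_generations <- function(pop, pedigree, n_gen, N, mu) {
  stopifnot(n_gen >= 0)
  for (g in seq_len(n_gen)) {
    cur <- pop$generation == max(pop$generation)
    st <- append_generation(pop, pedigree,
                            sire_ids = pop$id[cur & pop$sex == "M"],
                            dam_ids = pop$id[cur & pop$sex == "F"],
                            N = N, mu = mu)
    pop <- st$population
    pedigree <- st$pedigree
  }
  list(population = pop, pedigree = pedigree)
}

#' Marker panel by regular thinning
#'
#' Selects an evenly spaced subset of loci on every chromosome; the full
#' density returns all loci.
#'
#' @param map A [genome_map()].
#' @param markers_per_chromosome Markers to keep per chromosome; must divide
#'   the available loci evenly.
#' @return A `marker_panel`: list with `marker_indices` (global locus
#'   indices) and `markers_per_chromosome`.
#' @export
marker_panel <- function(map, markers_per_chromosome) {
  L <- map$loci_per_chromosome
  m <- as.integer(markers_per_chromosome)
  if (m > L) {
    abort("requested marker density exceeds available loci",
          class = "coansel_invalid_argument")
  }
  if (L %% m != 0) {
    abort("markers_per_chromosome must divide loci_per_chromosome",
          class = "coansel_invalid_argument")
  }
  stride <- L %/% m
  within <- seq_len(m) * stride
  idx <- as.vector(outer(within, (seq_len(map$n_chromosomes) - 1L) * L, "+"))
  structure(list(marker_indices = idx, markers_per_chromosome = m),
            class = "marker_panel")
}

#' Subset a population to given individuals
#' @param pop A `population`.
#' @param idx Positional indices of individuals to keep.
#' @return A `population` with those individuals.
#' @export
subset_population <- function(pop, idx) {
  new_population(pop$haplotypes[hap_rows(idx), , drop = FALSE],
                 pop$id[idx], pop$sex[idx], pop$generation[idx], pop$map)
}
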