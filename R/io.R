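#' Export a pedigree as TSV
#'
#' Five columns (id, sire, dam, sex, generation); unknown parents written
#' as 0.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  out <- pedigree
  out$sire[is.na(out$sire)] <- 0L
  out$dam[is.na(out$dam)] <- 0L
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a pedigree TSV
#' @param path Path written by [write_pedigree_tsv()].
#' @return A pedigree tibble (0 parents restored to `NA`).
#' @export
read_pedigree_tsv <- function(path) {
  ped <- readr::read_tsv(path, col_types = "iiici")
  ped$sire[ped$sire == 0L] <- NA_integer_
  ped$dam[ped$dam == 0L] <- NA_integer_
  ped
}

#' Export genotypes as a flat TSV
#'
#' One row per individual: id, sex, generation, then two allele columns
#' (0/1) per locus.
#'
#' @param pop A `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(pop, path) {
  n <- n_ind(pop)
  odd <- 2L * seq_len(n) - 1L
  L <- n_loci(pop$map)
  alle <- matrix(0L, n, 2L * L)
  alle[, 2L * seq_len(L) - 1L] <- pop$haplotypes[odd, , drop = FALSE]
  alle[, 2L * seq_len(L)] <- pop$haplotypes[odd + 1L, , drop = FALSE]
  colnames(alle) <- paste0("l", rep(seq_len(L), each = 2), "_", 1:2)
  out <- dplyr::bind_cols(
    tibble::tibble(id = pop$id, sex = pop$sex,
                   generation = pop$generation),
    tibble::as_tibble(alle))
  readr::write_tsv(out, path)
  invisible(path)
}

#' PLINK-style .ped/.map export
#'
#' Writes `<basename>.ped` (family, id, sire = 0, dam = 0, sex 1/2,
#' phenotype -9, then two allele columns per locus coded 1/2) and
#' `<basename>.map` (chromosome, locus id, genetic position in cM,
#' base-pair column set to the locus index).
#'
#' @param pop A `population`.
#' @param basename Output path without extension.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ped_map <- function(pop, basename) {
  map <- pop$map
  L <- n_loci(map)
  map_tbl <- tibble::tibble(
    chromosome = map$chr,
    locus = paste0("c", map$chr, "_m",
                   rep(seq_len(map$loci_per_chromosome),
                       map$n_chromosomes)),
    position_cM = map$pos * 100,
    bp = seq_len(L))
  readr::write_tsv(map_tbl, paste0(basename, ".map"), col_names = FALSE)
  n <- n_ind(pop)
  odd <- 2L * seq_len(n) - 1L
  alle <- matrix(0L, n, 2L * L)
  alle[, 2L * seq_len(L) - 1L] <- pop$haplotypes[odd, , drop = FALSE] + 1L
  alle[, 2L * seq_len(L)] <- pop$haplotypes[odd + 1L, , drop = FALSE] + 1L
  ped <- cbind(1L, pop$id, 0L, 0L, ifelse(pop$sex == "M", 1L, 2L), -9L,
               alle)
  utils::write.table(ped, paste0(basename, ".ped"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(paste0(basename, c(".ped", ".map")))
}

#' Read a PLINK-style .ped/.map pair as a population
#'
#' Alleles coded 1/2 are mapped back to 0/1. Positions are taken from the
#' .map genetic-distance column (cM).
#'
#' @param basename Path without extension, as given to [write_ped_map()].
#' @return A `population`.
#' @export
read_ped_map <- function(basename) {
  map_tbl <- utils::read.table(paste0(basename, ".map"), sep = "\t")
  chr <- as.integer(map_tbl[[1]])
  counts <- table(chr)
  if (length(unique(counts)) != 1) {
    abort("chromosomes must carry equal locus counts",
          class = "coansel_invalid_argument")
  }
  pos <- map_tbl[[3]] / 100
  gm <- structure(
    list(n_chromosomes = length(counts),
         loci_per_chromosome = as.integer(counts[1]),
         chromosome_length = max(ceiling(max(pos)), 1),
         chr = chr, pos = pos),
    class = "genome_map")
  ped <- utils::read.table(paste0(basename, ".ped"), sep = "\t")
  n <- nrow(ped)
  L <- n_loci(gm)
  alle <- as.matrix(ped[, -(1:6)])
  H <- matrix(0L, 2L * n, L)
  H[2L * seq_len(n) - 1L, ] <- as.integer(alle[, 2L * seq_len(L) - 1L]) - 1L
  H[2L * seq_len(n), ] <- as.integer(alle[, 2L * seq_len(L)]) - 1L
  new_population(H, as.integer(ped[[2]]),
                 ifelse(ped[[5]] == 1L, "M", "F"),
                 rep(0L, n), gm)
}

#' Write a relationship matrix as TSV
#'
#' Square layout: a `# kind:` metadata line, a header of ids, then the
#' matrix rows. Long layout: columns id_i, id_k, value (upper triangle
#' including the diagonal).
#'
#' @param K A `relationship_matrix`.
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_relationship_tsv <- function(K, path, format = c("square", "long")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", K$kind), con)
  if (format == "square") {
    writeLines(paste(c("id", K$ids), collapse = "\t"), con)
    utils::write.table(cbind(K$ids, K$values), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    ut <- which(upper.tri(K$values, diag = TRUE), arr.ind = TRUE)
    long <- tibble::tibble(id_i = K$ids[ut[, 1]], id_k = K$ids[ut[, 2]],
                           value = K$values[ut])
    writeLines(paste(names(long), collapse = "\t"), con)
    utils::write.table(long, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export estimated breeding values as TSV
#'
#' Four columns: generation, id, ebv, matrix_kind.
#'
#' @param fit An `mme_fit` from [solve_mme()].
#' @param generation Generation index to record with the EBVs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ebv_tsv <- function(fit, generation, path) {
  out <- tidy(fit)
  out <- tibble::tibble(generation = as.integer(generation), id = out$id,
                        ebv = out$ebv, matrix_kind = fit$matrix_kind)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write per-generation metrics as TSV
#' @param metrics A metrics tibble from [run_replicate()] or the
#'   `replicates`/`summary` element of [run_scenario_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}
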