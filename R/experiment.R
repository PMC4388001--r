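#' Scenario configuration
#'
#' Bundles every tunable of a selection experiment. Defaults are the study's
#' default scenario: N = 50 sires and 50 dams per generation, h2 = 0.25,
#' 10,100 markers per chromosome, 1000 QTLs, 6 random-mating generations to
#' record the genealogy, then 15 generations of truncation selection of the
#' best 50% of each sex.
#'
#' @param N Sires (= dams) per generation.
#' @param h2 Trait heritability in (0, 1).
#' @param markers_per_chromosome Marker-panel density (2525, 5050 or 10,100
#'   in the study grid).
#' @param selection_matrix Relationship matrix driving BLUP selection:
#'   `"A"`, `"G"`, `"R"` or `"V"`.
#' @param n_qtl Number of selective loci.
#' @param select_fraction Selected proportion per sex (0.5).
#' @param n_random_generations Recorded random-mating generations before
#'   selection (6).
#' @param n_selection_generations Truncation-selection generations (15).
#' @param n_replicates Replicates of the scenario.
#' @param mutation_rate Per-position, per-generation mutation rate.
#' @param mu_trait Phenotypic mean (100).
#' @param min_run ROH run threshold in markers (100 at every density).
#' @param reml_iter,reml_burnin Monte-Carlo EM REML schedule (6000 / 1000).
#' @param use_true_variances If `TRUE`, skip REML and plug the calibrated
#'   simulation variances into the mixed-model equations.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param label Optional scenario label carried into outputs.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(N = 50, h2 = 0.25, markers_per_chromosome = 10100,
                            selection_matrix = "A", n_qtl = 1000,
                            select_fraction = 0.5,
                            n_random_generations = 6,
                            n_selection_generations = 15,
                            n_replicates = 100, mutation_rate = 2.5e-3,
                            mu_trait = 100, min_run = 100,
                            reml_iter = 6000, reml_burnin = 1000,
                            use_true_variances = FALSE, seed = 1,
                            label = NULL) {
  selection_matrix <- match.arg(selection_matrix, c("A", "G", "R", "V"))
  if (h2 <= 0 || h2 >= 1) {
    abort("config error: `h2` must lie in (0, 1)",
          class = "coansel_config_error")
  }
  if (select_fraction <= 0 || select_fraction > 1) {
    abort("config error: `select_fraction` must lie in (0, 1]",
          class = "coansel_config_error")
  }
  stopifnot(N >= 1, n_qtl >= 1, n_replicates >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            reml_burnin < reml_iter)
  structure(
    list(N = as.integer(N), h2 = h2,
         markers_per_chromosome = as.integer(markers_per_chromosome),
         selection_matrix = selection_matrix, n_qtl = as.integer(n_qtl),
         select_fraction = select_fraction,
         n_random_generations = as.integer(n_random_generations),
         n_selection_generations = as.integer(n_selection_generations),
         n_replicates = as.integer(n_replicates),
         mutation_rate = mutation_rate, mu_trait = mu_trait,
         min_run = as.integer(min_run), reml_iter = as.integer(reml_iter),
         reml_burnin = as.integer(reml_burnin),
         use_true_variances = isTRUE(use_true_variances),
         seed = as.integer(seed),
         label = label %||% paste0("N", N, "_h", h2, "_m",
                                   markers_per_chromosome, "_",
                                   selection_matrix)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$label, ": N = ", x$N, ", h2 = ", x$h2,
      ", ", x$markers_per_chromosome, " markers/chr, selection on ",
      x$selection_matrix, ", ", x$n_selection_generations,
      " selection generations\n", sep = "")
  invisible(x)
}

#' Truncation selection within sex
#'
#' Selects, independently within each sex, the top
#' `floor(fraction x count)` candidates by EBV; ties are broken towards the
#' lower id for determinism.
#'
#' @param ebv Estimated breeding values of the candidates.
#' @param sex Candidate sexes (`"M"` / `"F"`).
#' @param id Candidate ids (default positional).
#' @param fraction Selected proportion per sex, in (0, 1].
#' @return Integer vector of selected ids.
#' @export
truncation_select <- function(ebv, sex, id = seq_along(ebv),
                              fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1]",
          class = "coansel_invalid_argument")
  }
  out <- integer(0)
  for (s in c("M", "F")) {
    i <- which(sex == s)
    if (length(i) == 0) {
      abort(paste0("no candidates of sex ", s),
            class = "coansel_invalid_state")
    }
    k <- max(1L, floor(fraction * length(i)))
    ord <- i[order(-ebv[i], id[i])]
    out <- c(out, id[ord[seq_len(k)]])
  }
  sort(out)
}

#' Mate selected parents
#'
#' Produces the next generation: 2N offspring (N sires, N dams), each from
#' a sire and dam drawn independently and uniformly with replacement from
#' the selected sets, with recombination and mutation as in the
#' base-population simulator, appending every birth to the pedigree.
#'
#' @param pop Accumulated `population`.
#' @param pedigree Pedigree tibble.
#' @param sires,dams Ids of the selected parents.
#' @param N Offspring per sex.
#' @param mu Mutation rate applied to the new gametes.
#' @return A list with updated `population` and `pedigree`.
#' @export
mate_selected <- function(pop, pedigree, sires, dams, N, mu) {
  if (length(sires) == 0 || length(dams) == 0) {
    abort("need at least one selected parent of each sex",
          class = "coansel_invalid_state")
  }
  append_generation(pop, pedigree, sires, dams, N, mu)
}

#' Log-scaled change in coancestry
#'
#' `log((1 - f_t) / (1 - f_baseline))`: 0 when coancestry is unchanged and
#' increasingly negative as coancestry accumulates, so the fastest decay on
#' this scale marks the fastest loss of diversity.
#'
#' @param f_t Coancestry at generation t.
#' @param f_baseline Coancestry right before selection started.
#' @return Natural-log ratio (vectorized).
#' @export
log_ratio_metric <- function(f_t, f_baseline) {
  if (any(f_t >= 1) || any(f_baseline >= 1)) {
    abort("coancestry must be < 1 for the log-ratio metric",
          class = "coansel_undefined_metric")
  }
  log((1 - f_t) / (1 - f_baseline))
}

# Metrics of one cohort: mean TBV, all four pairwise coancestries and
# inbreeding measures (cross-performance bookkeeping), and heterozygosity.
cohort_metrics <- function(pop, pedigree, cohort_gen, panel, min_run, tbv) {
  idx <- which(pop$generation == cohort_gen)
  sub <- subset_population(pop, idx)
  A_full <- pedigree_A(pedigree)
  Ks <- list(
    A = subset_relationship(A_full, idx),
    G = ibs_G(sub, panel),
    R = roh_R(sub, panel, min_run),
    V = vanraden_V(sub, panel)
  )
  mean_f <- vapply(Ks, function(K) {
    f <- coancestry(K); mean(f[upper.tri(f)])
  }, 1)
  mean_F <- vapply(Ks, function(K) mean(inbreeding(K)), 1)
  tibble::tibble(
    generation = cohort_gen, n = length(idx),
    mean_tbv = mean(tbv[idx]),
    mean_f_A = mean_f[["A"]], mean_f_G = mean_f[["G"]],
    mean_f_R = mean_f[["R"]], mean_f_V = mean_f[["V"]],
    mean_F_A = mean_F[["A"]], mean_F_G = mean_F[["G"]],
    mean_F_R = mean_F[["R"]], mean_F_V = mean_F[["V"]],
    heterozygosity = heterozygosity(sub)
  )
}

#' Run one replicate of the selection experiment
#'
#' Full pipeline for one replicate: draw QTLs and founders from the shared
#' base population, calibrate the trait variances on the base, run the
#' recorded random-mating generations, then per selection generation:
#' estimate variances by REML (unless `use_true_variances`), build the
#' configured relationship matrix over every phenotyped individual, solve
#' the mixed-model equations, truncation-select the best fraction of each
#' sex among the current cohort, and mate them. Every generation, all four
#' coancestry summaries, inbreeding measures and heterozygosity are
#' recorded regardless of which matrix drives selection.
#'
#' @param cfg A [scenario_config()].
#' @param base The shared base `population`.
#' @param replicate_index Replicate number r; the replicate RNG seed is
#'   `cfg$seed + r`.
#' @return A tibble (class `coansel_metrics`) with one row per generation
#'   0..(random + selection generations): scenario label, replicate,
#'   selection matrix, raw metrics, the variance estimates used, and
#'   baseline-scaled columns `delta_tbv` and `log_ratio_f_*` (zero at the
#'   last pre-selection generation).
#' @export
run_replicate <- function(cfg, base, replicate_index = 1) {
  set.seed(cfg$seed + replicate_index)
  map <- base$map
  panel <- marker_panel(map, cfg$markers_per_chromosome)
  qtl <- sample_qtls(base, cfg$n_qtl)
  effects <- draw_effects(cfg$n_qtl)
  vc <- calibrate_variances(compute_tbv(genotype_counts(base, qtl), effects),
                            cfg$h2)
  arch <- trait_architecture(qtl, effects, mu = cfg$mu_trait,
                             sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e)

  st <- draw_founders(base, cfg$N)
  st <- random_mating_generations(st$population, st$pedigree,
                                  cfg$n_random_generations, cfg$N,
                                  cfg$mutation_rate)
  pop <- st$population
  ped <- st$pedigree
  tbv <- compute_tbv(genotype_counts(pop, qtl), effects)
  y <- simulate_phenotypes(tbv, arch)

  g_base <- cfg$n_random_generations
  metrics <- purrr::map(0:g_base, function(g) {
    cohort_metrics(pop, ped, g, panel, cfg$min_run, tbv)
  })
  var_log <- tibble::tibble(generation = integer(), sigma2_a_hat = double(),
                            sigma2_e_hat = double())

  for (r in seq_len(cfg$n_selection_generations)) {
    gen <- g_base + r
    K <- build_relationship(cfg$selection_matrix, pop = pop, pedigree = ped,
                            panel = panel, min_run = cfg$min_run)
    if (cfg$use_true_variances) {
      s2a <- arch$sigma2_a; s2e <- arch$sigma2_e
    } else {
      fit <- mcem_reml(y, K, n_iter = cfg$reml_iter,
                       burnin = cfg$reml_burnin)
      s2a <- fit$sigma2_a; s2e <- fit$sigma2_e
    }
    var_log <- dplyr::bind_rows(var_log, tibble::tibble(
      generation = gen, sigma2_a_hat = s2a, sigma2_e_hat = s2e))
    mme <- solve_mme(y, K, s2a, s2e)
    cand <- which(pop$generation == gen - 1L)
    sel <- truncation_select(mme$ebv[cand], pop$sex[cand], pop$id[cand],
                             cfg$select_fraction)
    st <- mate_selected(pop, ped,
                        sires = sel[pop$sex[match(sel, pop$id)] == "M"],
                        dams = sel[pop$sex[match(sel, pop$id)] == "F"],
                        N = cfg$N, mu = cfg$mutation_rate)
    pop <- st$population
    ped <- st$pedigree
    new_idx <- which(pop$generation == gen)
    tbv_new <- compute_tbv(genotype_counts(
      subset_population(pop, new_idx), qtl), effects)
    tbv <- c(tbv, tbv_new)
    y <- c(y, simulate_phenotypes(tbv_new, arch))
    metrics <- c(metrics, list(
      cohort_metrics(pop, ped, gen, panel, cfg$min_run, tbv)))
  }

  out <- dplyr::bind_rows(metrics)
  out <- dplyr::left_join(out, var_log, by = "generation")
  base_row <- out[out$generation == g_base, ]
  out$delta_tbv <- out$mean_tbv - base_row$mean_tbv
  for (k in c("A", "G", "R", "V")) {
    out[[paste0("log_ratio_f_", k)]] <- log_ratio_metric(
      out[[paste0("mean_f_", k)]], base_row[[paste0("mean_f_", k)]])
  }
  out <- dplyr::bind_cols(
    tibble::tibble(scenario = cfg$label,
                   selection_matrix = cfg$selection_matrix,
                   replicate = as.integer(replicate_index))[
                     rep(1, nrow(out)), ],
    out)
  class(out) <- c("coansel_metrics", class(out))
  out
}

#' Run a grid of scenarios with replication
#'
#' Executes `n_replicates` replicates of each scenario configuration
#' against one shared base population (replicates differ in their QTL and
#' founder draws) and aggregates per-generation replicate means, SDs and
#' standard errors.
#'
#' @param configs A [scenario_config()] or list of them.
#' @param base The shared base `population`.
#' @param n_replicates Replicates per scenario (default: each config's own
#'   `n_replicates`).
#' @param seed Optional base seed overriding each config's; scenario s uses
#'   `seed + 10000 (s - 1) + r` for replicate r.
#' @param verbose If `TRUE`, log per-replicate progress to stderr.
#' @return A list of class `scenario_grid_result` with `replicates` (all
#'   per-generation rows) and `summary` (per scenario x generation x metric
#'   mean, sd, se over replicates).
#' @export
run_scenario_grid <- function(configs, base, n_replicates = NULL,
                              seed = NULL, verbose = FALSE) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  rows <- purrr::imap(configs, function(cfg, s) {
    if (!is.null(seed)) cfg$seed <- as.integer(seed + 10000 * (s - 1))
    R <- n_replicates %||% cfg$n_replicates
    purrr::map(seq_len(R), function(r) {
      if (verbose) message("scenario ", cfg$label, ": replicate ", r,
                           "/", R)
      run_replicate(cfg, base, r)
    }) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- rows |>
    tidyr::pivot_longer(cols = -c("scenario", "selection_matrix",
                                  "replicate", "generation", "n"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$scenario, .data$selection_matrix,
                    .data$generation, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(), .groups = "drop")
  structure(list(replicates = rows, summary = summary),
            class = "scenario_grid_result")
}

#' @export
print.scenario_grid_result <- function(x, ...) {
  cat("<scenario_grid_result> ",
      length(unique(x$replicates$scenario)), " scenario(s), ",
      max(x$replicates$replicate), " replicate(s), generations 0..",
      max(x$replicates$generation), "\n", sep = "")
  invisible(x)
}

#' The study's scenario grid
#'
#' The nine scenarios of the study design: population size, heritability
#' and marker density each varied one-at-a-time around the default
#' (N = 50, h2 = 0.25, 10,100 markers per chromosome).
#'
#' @param ... Further arguments passed to every [scenario_config()] (e.g.
#'   `selection_matrix`).
#' @return A list of nine `scenario_config`s.
#' @export
table_grid <- function(...) {
  grid <- list(
    list(N = 10), list(N = 30), list(N = 50),
    list(h2 = 0.10), list(h2 = 0.25), list(h2 = 0.50),
    list(markers_per_chromosome = 2525),
    list(markers_per_chromosome = 5050),
    list(markers_per_chromosome = 10100)
  )
  purrr::map(grid, function(g) do.call(scenario_config, c(g, list(...))))
}
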