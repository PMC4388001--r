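# shared small world for the driver tests
set.seed(602)
smoke_gm <- genome_map(2, 100)
smoke_base <- sim_base_population(smoke_gm, 60, 20, mu = 2.5e-3)
smoke_cfg <- scenario_config(N = 5, n_qtl = 30, markers_per_chromosome = 100,
                             n_random_generations = 3,
                             n_selection_generations = 3,
                             selection_matrix = "G", min_run = 10,
                             reml_iter = 200, reml_burnin = 50, seed = 7)
smoke_run <- run_replicate(smoke_cfg, smoke_base, 1)

test_that("truncation selection keeps the best fraction of each sex", {
  set.seed(611)
  ebv <- rnorm(20)
  sex <- rep(c("M", "F"), each = 10)
  sel <- truncation_select(ebv, sex, id = 1:20, fraction = 0.5)
  expect_length(sel, 10)
  # brute-force sort-and-slice oracle
  top_m <- order(-ebv[1:10])[1:5]
  top_f <- 10 + order(-ebv[11:20])[1:5]
  expect_setequal(sel, c(top_m, top_f))

  expect_setequal(truncation_select(ebv, sex, 1:20, fraction = 1), 1:20)

  # ties break towards the lower id
  sel_tie <- truncation_select(c(1, 1, 1, 2, 2, 2), rep(c("M", "F"), 3),
                               id = 6:1, fraction = 0.4)
  # males are ids 6, 4, 2 with ebv 1, 1, 2 -> pick 2; females 5, 3, 1 with
  # ebv 1, 2, 2 -> tie between ids 1 and 3 at ebv 2 -> pick 1
  expect_setequal(sel_tie, c(2, 1))

  expect_error(truncation_select(ebv, rep("M", 20), 1:20),
               class = "coansel_invalid_state")
  expect_error(truncation_select(ebv, sex, 1:20, fraction = 0),
               class = "coansel_invalid_argument")
})

test_that("mating selected parents appends a consistent generation", {
  set.seed(621)
  st <- draw_founders(smoke_base, 5)
  st <- random_mating_generations(st$population, st$pedigree, 1, 5, 0)
  cur <- st$pedigree[st$pedigree$generation == 1, ]
  sires <- cur$id[cur$sex == "M"][1:2]
  dams <- cur$id[cur$sex == "F"][1:2]
  st2 <- mate_selected(st$population, st$pedigree, sires, dams, 5, 1e-3)
  kids <- st2$pedigree[st2$pedigree$generation == 2, ]
  expect_equal(nrow(kids), 10)
  expect_equal(sum(kids$sex == "M"), 5)
  expect_true(all(kids$sire %in% sires))
  expect_true(all(kids$dam %in% dams))
  expect_equal(n_ind(st2$population), nrow(st2$pedigree))

  # single selected pair: every offspring is theirs
  st3 <- mate_selected(st$population, st$pedigree, sires[1], dams[1], 3, 0)
  kids3 <- st3$pedigree[st3$pedigree$generation == 2, ]
  expect_true(all(kids3$sire == sires[1] & kids3$dam == dams[1]))
  expect_error(mate_selected(st$population, st$pedigree, integer(0), dams,
                             5, 0), class = "coansel_invalid_state")
})

test_that("the log-ratio diversity metric behaves as defined", {
  expect_equal(log_ratio_metric(0.3, 0.3), 0)
  expect_equal(log_ratio_metric(0.5, 0), log(0.5))
  expect_lt(log_ratio_metric(0.6, 0.2), log_ratio_metric(0.4, 0.2))
  expect_error(log_ratio_metric(1, 0.5), class = "coansel_undefined_metric")
})

test_that("a replicate tracks every metric for every generation", {
  m <- smoke_run
  expect_equal(m$generation, 0:6)
  expect_equal(m$n, rep(10L, 7))
  # cross-performance: all four coancestries recorded under G-driven BLUP
  for (k in c("A", "G", "R", "V")) {
    expect_true(all(is.finite(m[[paste0("mean_f_", k)]])))
    expect_true(all(is.finite(m[[paste0("mean_F_", k)]])))
    expect_true(all(is.finite(m[[paste0("log_ratio_f_", k)]])))
  }
  # baseline scaling: zero at the last pre-selection generation
  b <- which(m$generation == 3)
  expect_equal(m$delta_tbv[b], 0)
  expect_equal(m$log_ratio_f_A[b], 0)
  # variance estimates only exist once selection starts
  expect_true(all(is.na(m$sigma2_a_hat[m$generation < 4])))
  expect_true(all(m$sigma2_a_hat[m$generation >= 4] > 0))
  # genealogical coancestry accumulates monotonically in a closed population
  expect_true(all(diff(m$mean_f_A) >= 0))
  expect_true(all(m$heterozygosity >= 0 & m$heterozygosity <= 1))
  # replicates are reproducible from the manifest seed
  again <- run_replicate(smoke_cfg, smoke_base, 1)
  expect_identical(as.data.frame(m), as.data.frame(again))
})

test_that("selection raises mean TBV while no-pressure runs only drift", {
  cfg_sel <- scenario_config(N = 5, n_qtl = 30, markers_per_chromosome = 100,
                             n_random_generations = 2,
                             n_selection_generations = 4,
                             selection_matrix = "A", min_run = 10,
                             use_true_variances = TRUE, seed = 31)
  gains <- sapply(1:8, function(r) {
    tail(run_replicate(cfg_sel, smoke_base, r)$delta_tbv, 1)
  })
  expect_gt(mean(gains), 0)
  expect_gt(mean(gains > 0), 0.6)

  cfg_null <- scenario_config(N = 5, n_qtl = 30,
                              markers_per_chromosome = 100,
                              n_random_generations = 2,
                              n_selection_generations = 4,
                              selection_matrix = "A", select_fraction = 1,
                              min_run = 10, use_true_variances = TRUE,
                              seed = 32)
  drift <- sapply(1:8, function(r) {
    tail(run_replicate(cfg_null, smoke_base, r)$delta_tbv, 1)
  })
  expect_lt(abs(mean(drift)), 3 * sd(drift) / sqrt(length(drift)))
})

test_that("the scenario grid aggregates replicate summaries", {
  cfg <- scenario_config(N = 4, n_qtl = 20, markers_per_chromosome = 50,
                         n_random_generations = 2,
                         n_selection_generations = 2,
                         selection_matrix = "V", min_run = 10,
                         use_true_variances = TRUE, seed = 11)
  grid <- run_scenario_grid(cfg, smoke_base, n_replicates = 2, seed = 100)
  expect_s3_class(grid, "scenario_grid_result")
  expect_equal(sort(unique(grid$replicates$replicate)), 1:2)
  expect_equal(nrow(grid$replicates), 2 * 5)

  one <- grid$summary[grid$summary$metric == "mean_tbv", ]
  expect_equal(nrow(one), 5)
  expect_equal(one$se, one$sd / sqrt(2))

  # a single replicate reduces to run_replicate under the same seed rule
  cfg1 <- cfg; cfg1$seed <- 100L
  solo <- run_replicate(cfg1, smoke_base, 1)
  g1 <- run_scenario_grid(cfg, smoke_base, n_replicates = 1, seed = 100)
  expect_equal(as.data.frame(g1$replicates), as.data.frame(solo))

  expect_length(table_grid(selection_matrix = "R"), 9)
  expect_equal(table_grid()[[1]]$N, 10L)
  expect_equal(table_grid()[[7]]$markers_per_chromosome, 2525L)
})
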