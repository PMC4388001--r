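test_that("pedigree A reproduces textbook relationships", {
  A <- pedigree_A(full_sib_pedigree())
  expect_equal(A$values[3, 4], 0.5)       # full sibs
  expect_equal(unname(diag(A$values)), rep(1, 4))  # all non-inbred
  expect_equal(A$values[1, 2], 0)

  # offspring of a full-sib mating: F = 0.25
  ped <- tibble::tibble(id = 1:5,
                        sire = c(NA, NA, 1L, 1L, 3L),
                        dam = c(NA, NA, 2L, 2L, 4L),
                        sex = c("M", "F", "M", "F", "M"),
                        generation = c(0L, 0L, 1L, 1L, 2L))
  A <- pedigree_A(ped)
  expect_equal(A$values[5, 5], 1.25)
  expect_equal(inbreeding(A)[[5]], 0.25)
})

test_that("pedigree A agrees with path counting on a looped 8-member pedigree", {
  ped <- tibble::tibble(
    id = 1:8,
    sire = c(NA, NA, 1L, 1L, 3L, 3L, 5L, 5L),
    dam = c(NA, NA, 2L, 2L, 4L, 2L, 6L, 4L),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
    generation = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(pedigree_A(ped)$values, bf_A_paths(ped),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("malformed pedigrees are rejected", {
  bad <- tibble::tibble(id = 1:3, sire = c(NA, 3L, 1L),
                        dam = c(NA, NA, NA),
                        sex = c("M", "M", "F"), generation = 0:2)
  expect_error(pedigree_A(bad), class = "coansel_invalid_pedigree")
  dup <- tibble::tibble(id = c(1L, 1L), sire = c(NA, NA),
                        dam = c(NA, NA), sex = c("M", "F"),
                        generation = c(0L, 0L))
  expect_error(pedigree_A(dup), class = "coansel_invalid_pedigree")
  ghost <- tibble::tibble(id = 1:2, sire = c(NA, 9L), dam = c(NA, NA),
                          sex = c("M", "M"), generation = 0:1)
  expect_error(pedigree_A(ghost), class = "coansel_invalid_pedigree")
})

test_that("IBS coancestry enumerates the four gamete pairs", {
  gm <- genome_map(1, 2)
  # i = (0/1, 1/1), k = (1/1, 0/1): f_G = 0.5
  H <- rbind(c(0L, 1L), c(1L, 1L),
             c(1L, 0L), c(1L, 1L))
  pop <- manual_population(H, gm)
  G <- ibs_G(pop)
  expect_equal(coancestry(G)[1, 2], 0.5)

  # both individuals homozygous 1/1 everywhere: f_G = 1
  hom <- manual_population(matrix(1L, 4, 2), gm)
  expect_equal(coancestry(ibs_G(hom))[1, 2], 1)

  # a fully heterozygous individual with itself: f_G = 0.5, so F_G = 0
  het <- manual_population(rbind(c(0L, 0L), c(1L, 1L),
                                 c(1L, 1L), c(1L, 1L)), gm)
  expect_equal(coancestry(ibs_G(het))[1, 1], 0.5)
  expect_equal(inbreeding(ibs_G(het))[[1]], 0)
})

test_that("IBS self-coancestry equals 1 - H_i / 2", {
  set.seed(301)
  gm <- genome_map(2, 40)
  pop <- init_base(gm, 8)
  f <- coancestry(ibs_G(pop))
  n <- n_ind(pop)
  for (i in seq_len(n)) {
    H_i <- mean(pop$haplotypes[2 * i - 1, ] != pop$haplotypes[2 * i, ])
    expect_equal(f[i, i], 1 - H_i / 2)
  }
  # population-level: mean pairwise f_G = 1 - expected heterozygosity of a
  # random-union offspring between distinct parents (brute-force count)
  bf <- bf_fG(pop$haplotypes)
  expect_equal(mean(f[upper.tri(f)]), 1 - mean(1 - bf[upper.tri(bf)]))
})

test_that("ROH coancestry counts only runs past the threshold", {
  gm <- genome_map(1, 1000)
  set.seed(331)
  a <- rep(c(0L, 1L), 500)
  r2 <- sample(0:1, 1000, replace = TRUE)       # scrambles all other pairs
  # individual 2's first gamete shares exactly markers 101..250 with
  # individual 1's first gamete (a 150-marker run, mismatching flanks);
  # the remaining gamete pairs only match at short random stretches
  r3 <- 1L - a
  r3[101:250] <- a[101:250]
  H <- rbind(a, r2, r3, 1L - r2)
  pop <- manual_population(H, gm)
  f <- coancestry(roh_R(pop, min_run = 100))
  expect_equal(f[1, 2], 150 / (4 * 1000))

  # a 99-marker run contributes nothing at min_run = 100
  r3b <- 1L - a
  r3b[101:199] <- a[101:199]
  f99 <- coancestry(roh_R(manual_population(rbind(a, r2, r3b, 1L - r2), gm),
                          min_run = 100))
  expect_equal(f99[1, 2], 0)

  # all four gametes identical genome-wide: f_R = 1
  same <- manual_population(matrix(rep(a, 4), 4, byrow = TRUE), gm)
  expect_equal(coancestry(roh_R(same, min_run = 100))[1, 2], 1)
  expect_equal(coancestry(roh_R(same, min_run = 100))[1, 1], 1)
})

test_that("ROH runs never span chromosome boundaries", {
  gm <- genome_map(2, 50)
  # two identical gametes per individual, fully identical across individuals:
  # each chromosome yields a 50-marker run; threshold 60 kills them all
  H <- matrix(0L, 4, 100)
  pop <- manual_population(H, gm)
  expect_equal(coancestry(roh_R(pop, min_run = 60))[1, 2], 0)
  expect_equal(coancestry(roh_R(pop, min_run = 50))[1, 2], 1)
})

test_that("VanRaden coancestry matches direct substitution", {
  gm <- genome_map(1, 4)
  hom1 <- matrix(1L, 4, 4)
  expect_equal(coancestry(vanraden_V(manual_population(hom1, gm)))[1, 2], 1)

  het_vs <- rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L),
                  c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_equal(coancestry(vanraden_V(manual_population(het_vs, gm)))[1, 2], 0)

  opp <- rbind(matrix(1L, 2, 4), matrix(0L, 2, 4))
  expect_equal(coancestry(vanraden_V(manual_population(opp, gm)))[1, 2], -1)
})

test_that("all four builders agree with brute force on random fixtures", {
  gm <- genome_map(2, 20)
  for (seed in c(311, 312, 313)) {
    set.seed(seed)
    pop <- init_base(gm, 6)
    expect_equal(coancestry(ibs_G(pop)), bf_fG(pop$haplotypes),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(coancestry(vanraden_V(pop)), bf_fV(pop$haplotypes),
                 ignore_attr = TRUE, tolerance = 1e-12)
    for (mr in c(3, 10)) {
      expect_equal(coancestry(roh_R(pop, min_run = mr)),
                   bf_fR(pop$haplotypes, gm$chr, min_run = mr),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
    # pedigree A on a random 2-generation pedigree
    st <- draw_founders(pop, 3)
    st <- random_mating_generations(st$population, st$pedigree, 2, 3, 0)
    expect_equal(pedigree_A(st$pedigree)$values, bf_A_paths(st$pedigree),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("relationship matrices respect marker panels", {
  set.seed(321)
  gm <- genome_map(2, 40)
  pop <- init_base(gm, 6)
  panel <- marker_panel(gm, 20)
  cols <- panel$marker_indices
  expect_equal(coancestry(ibs_G(pop, panel)),
               bf_fG(pop$haplotypes, cols), ignore_attr = TRUE)
  expect_equal(coancestry(vanraden_V(pop, panel)),
               bf_fV(pop$haplotypes, cols), ignore_attr = TRUE)
  expect_equal(coancestry(roh_R(pop, panel, min_run = 4)),
               bf_fR(pop$haplotypes, gm$chr, cols, min_run = 4),
               ignore_attr = TRUE)
})

test_that("the ROH threshold spans ~4 cM at low and ~1 cM at full density", {
  gm <- genome_map(10, 10100)
  expect_equal(roh_min_span_cM(gm, 2525), 100 * 100 / 2525)
  expect_lt(abs(roh_min_span_cM(gm, 2525) - 4), 0.05)
  expect_lt(abs(roh_min_span_cM(gm, 10100) - 1), 0.05)
})

test_that("coancestry summaries report means, variances and histograms", {
  A <- pedigree_A(tibble::tibble(id = 1:4, sire = NA_integer_,
                                 dam = NA_integer_,
                                 sex = rep(c("M", "F"), 2),
                                 generation = 0L))
  s <- coancestry_summary(A)
  expect_equal(s$summary$mean_f, 0)
  expect_equal(s$summary$mean_F, 0)
  expect_equal(sum(s$histogram$count), 6)  # 4 choose 2 pairs

  toy <- relationship_matrix(matrix(c(1, 0.5, 0.5, 1.2), 2, 2), "A", 1:2)
  s2 <- coancestry_summary(toy)
  expect_equal(s2$summary$mean_f, 0.25)
  expect_equal(s2$summary$mean_F, 0.1)
  expect_equal(s2$summary$var_f, var(c(0.25)))
})
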