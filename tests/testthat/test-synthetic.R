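test_that("the generator is deterministic and emits parser-ready fragment sizes", {
  s1 <- simulate_genotypes(simulation_spec(seed = 5, n_per_pop = c(10, 10),
                                           n_admixed = 2, n_loci = 6))
  s2 <- simulate_genotypes(simulation_spec(seed = 5, n_per_pop = c(10, 10),
                                           n_admixed = 2, n_loci = 6))
  expect_identical(s1$gm$a1, s2$gm$a1)
  expect_identical(s1$Q, s2$Q)
  codes <- unique(c(s1$gm$a1, s1$gm$a2))
  codes <- codes[!is.na(codes)]
  expect_true(all(codes >= 150 & codes %% 2 == 0))   # 150 + 2 * index
  expect_equal(dim(s1$gm), c(22L, 6L))
  expect_identical(s1$gm$pop[1:10], rep("LLR", 10))

  t1 <- simulate_phenotypes(simulation_spec(seed = 5, n_per_pop = c(10, 10),
                                            n_admixed = 2))
  expect_identical(t1$id, accession_ids(s1$gm))      # shared ancestry stream
  expect_identical(t1$pop, s1$gm$pop)
})

test_that("paper-structured preset has the documented dimensions", {
  sim <- simulate_paperlike(seed = 1, n_loci = 8)
  expect_equal(nrow(sim$gm$a1), 179)
  expect_equal(ncol(sim$tt$qualitative), 22)
  expect_equal(ncol(sim$tt$quantitative), 13)
  counts <- vapply(sim$pop_freqs, ncol, 1L)
  expect_true(all(counts >= 2 & counts <= 20))
})

test_that("divergence vanishes as F approaches 0 and grows monotonically in F", {
  fst_at <- function(f) {
    sim <- simulate_genotypes(simulation_spec(seed = 101, n_per_pop = c(60, 60),
                                              n_admixed = 0, n_loci = 15,
                                              fst = f, missing_rate = 0))
    fst_estimate(sim$gm, sim$labels)
  }
  near_zero <- fst_at(0.001)
  expect_lt(near_zero, 0.02)
  grades <- c(near_zero, fst_at(0.05), fst_at(0.15), fst_at(0.3))
  expect_true(all(diff(grades) > 0))
})

test_that("empirical allele frequencies converge to the drawn population frequencies", {
  sim <- simulate_genotypes(simulation_spec(seed = 55, n_pops = 1,
                                            n_per_pop = 10000, n_admixed = 0,
                                            n_loci = 3,
                                            alleles_per_locus = c(2, 5),
                                            fst = 0.2, missing_rate = 0))
  for (l in locus_names(sim$gm)) {
    emp <- allele_frequencies(sim$gm, l)$freq
    truth <- sim$pop_freqs[[l]][1, ]
    truth <- truth[names(emp)]                      # unobserved rare alleles drop out
    expect_lt(max(abs(emp - truth)), 0.01)
  }
})

test_that("generated category frequencies reproduce the target Shannon index", {
  f <- c(0.17, 0.766, 0.064)
  spec <- simulation_spec(seed = 77, n_per_pop = c(5000, 5000), n_admixed = 0,
                          missing_rate = 0,
                          qual_traits = list(habit = rbind(f, f)),
                          quant_traits = list(ht = list(mean = c(100, 100),
                                                        sd = c(10, 10))))
  tt <- simulate_phenotypes(spec)
  h <- shannon_index(category_frequencies(tt$qualitative$habit, 3))
  expect_lt(abs(h - 0.68), 0.02)
})

test_that("equal population specs give near-zero comparison differences", {
  f <- c(0.3, 0.5, 0.2)
  spec <- simulation_spec(seed = 78, n_per_pop = c(1500, 1500), n_admixed = 0,
                          missing_rate = 0,
                          qual_traits = list(t1 = rbind(f, f)),
                          quant_traits = list(x = list(mean = c(50, 50),
                                                       sd = c(5, 5))))
  pd <- pheno_diversity(simulate_phenotypes(spec))
  dif <- compare_populations(pd$qualitative[pd$qualitative$pop == "LLR", ],
                             pd$qualitative[pd$qualitative$pop == "CBL", ])
  expect_lt(abs(dif$dh), 0.05)
  difq <- compare_populations(pd$quantitative[pd$quantitative$pop == "LLR", ],
                              pd$quantitative[pd$quantitative$pop == "CBL", ])
  expect_lt(abs(difq$dh), 0.15)
})

test_that("spec validation rejects malformed inputs and degenerate traits are flagged", {
  expect_error(simulation_spec(fst = 0), "fst")
  expect_error(simulation_spec(alleles_per_locus = c(1, 3)), "at least 2 alleles")
  expect_error(simulation_spec(qual_traits = list(bad = rbind(c(0.5, 0.4),
                                                              c(0.5, 0.5)))),
               "sum to 1")
  # a constant quantitative trait has CV 0 but cannot be scored
  spec <- simulation_spec(seed = 9, n_per_pop = c(20, 20), n_admixed = 0,
                          missing_rate = 0,
                          qual_traits = list(t1 = rbind(c(0.5, 0.5), c(0.5, 0.5))),
                          quant_traits = list(flat = list(mean = c(7, 7),
                                                          sd = c(0, 0))))
  tt <- simulate_phenotypes(spec)
  v <- tt$quantitative$flat
  expect_equal(sd(v) / mean(v) * 100, 0)
  expect_error(quantitative_trait_summary(v), "degenerate")
})
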