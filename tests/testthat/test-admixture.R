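sim_small <- function(seed = 42) {
  simulate_paperlike(seed = seed, n_per_pop = c(30, 30), n_admixed = 0,
                     n_loci = 10, fst = 0.3, missing_rate = 0.02)
}

test_that("K = 1 puts every accession fully in the single cluster", {
  sim <- sim_small()
  fit <- run_admixture(sim$gm, admixture_config(K = 1, iterations = 200,
                                                burnin = 50, runs = 1))
  expect_equal(unname(fit$runs[[1]]$Q[, 1]), rep(1, 60))
  expect_true(is.finite(fit$lnpk))
})

test_that("chains are reproducible from the seed and Q rows stay on the simplex", {
  sim <- sim_small()
  cfg <- admixture_config(K = 2, iterations = 300, burnin = 100, runs = 2, seed = 11)
  f1 <- run_admixture(sim$gm, cfg)
  f2 <- run_admixture(sim$gm, cfg)
  expect_identical(f1$runs[[1]]$Q, f2$runs[[1]]$Q)
  expect_identical(f1$runs[[2]]$lnl, f2$runs[[2]]$lnl)
  for (r in f1$runs) {
    expect_true(all(abs(rowSums(r$Q) - 1) < 1e-9))
    for (pl in r$P) expect_true(all(abs(rowSums(pl) - 1) < 1e-9))
  }
  # different run index = different chain
  expect_false(identical(f1$runs[[1]]$Q, f1$runs[[2]]$Q))
})

test_that("two diverged populations are recovered with high confidence", {
  sim <- sim_small()
  fit <- run_admixture(sim$gm, admixture_config(K = 2, iterations = 800,
                                                burnin = 200, runs = 2, seed = 3))
  al <- align_runs(lapply(fit$runs, `[[`, "Q"))
  grp <- assign_groups(al$mean_q, threshold = 0.6)
  cl <- grp$assignments$cluster
  # align cluster indices to the generating labels
  acc <- max(mean(cl == sim$labels), mean(cl == 3 - sim$labels))
  expect_gte(acc, 0.95)
  expect_gte(mean(grp$assignments$max_q > 0.9), 0.9)
})

test_that("pinned-anchor runs recover the generating allele frequencies", {
  sim <- simulate_paperlike(seed = 13, n_per_pop = c(50, 50), n_admixed = 0,
                            n_loci = 20, fst = 0.3, missing_rate = 0)
  pin <- integer(100)
  pin[1] <- 1L; pin[51] <- 2L       # one fully assigned individual per cluster
  fit <- run_admixture(sim$gm, admixture_config(K = 2, iterations = 5000,
                                                burnin = 1000, runs = 1,
                                                seed = 2), pin = pin)
  P <- fit$runs[[1]]$P
  err <- c()
  for (l in names(P)) {
    codes <- names(allele_frequencies(sim$gm, l)$freq)  # observed alleles only
    truth <- sim$pop_freqs[[l]][, codes, drop = FALSE]
    # anchors fix the labels: cluster k estimates population k
    err <- c(err, abs(P[[l]] - truth))
  }
  expect_lt(mean(err), 0.05)
})

test_that("the Evanno table matches hand-evaluated formulas", {
  lnpk <- rbind(`1` = c(-99, -101), `2` = c(-79, -81), `3` = c(-77, -79))
  ev <- evanno_delta_k(lnpk)
  expect_equal(ev$mean_l, c(-100, -80, -78))
  expect_equal(ev$l_prime, c(NA, 20, 2))
  expect_equal(ev$l_second_abs, c(NA, 18, NA))
  expect_equal(ev$delta_k[2], 18 / sqrt(2))
  expect_equal(attr(ev, "optimal_k"), 2L)
})

test_that("linear mean likelihoods give zero delta-K and zero sd is reported, not fabricated", {
  lnpk <- cbind(c(-100, -90, -80, -70) + 0.5, c(-100, -90, -80, -70) - 0.5)
  rownames(lnpk) <- 1:4
  ev <- evanno_delta_k(lnpk)
  expect_equal(ev$delta_k[2:3], c(0, 0))

  flat <- matrix(rep(c(-100, -90, -85), 2), 3, dimnames = list(1:3, NULL))
  expect_warning(ev2 <- evanno_delta_k(flat), "zero run-to-run sd")
  expect_true(is.na(ev2$delta_k[2]))
  expect_error(evanno_delta_k(lnpk[1:2, ]), "at least 3")
  expect_error(evanno_delta_k(lnpk[, 1, drop = FALSE]), "at least 2 runs")
})

test_that("delta-K peaks at the generating K on two-population data", {
  sim <- sim_small(seed = 29)
  scan <- structure_scan(sim$gm, 1:4, runs = 3, iterations = 600,
                         burnin = 200, seed = 17)
  ev <- evanno_delta_k(scan$lnpk)
  expect_equal(attr(ev, "optimal_k"), 2L)
})

test_that("group assignment applies the Q threshold and matches a row-scan oracle", {
  q <- rbind(c(0.95, 0.05), c(0.55, 0.45), c(0.3, 0.7))
  grp <- assign_groups(q, threshold = 0.6)
  expect_equal(grp$assignments$cluster, c(1L, 1L, 2L))
  expect_equal(grp$assignments$admixed, c(FALSE, TRUE, FALSE))
  expect_equal(grp$counts$members, c(2L, 1L))
  expect_equal(grp$counts$above_threshold, c(1L, 1L))

  set.seed(99)
  qbig <- t(apply(matrix(rgamma(300, 1), 100, 3), 1, function(x) x / sum(x)))
  grp <- assign_groups(qbig, threshold = 0.7)
  for (i in sample(100, 10)) {                      # independent row scan
    k <- which.max(qbig[i, ])
    expect_equal(grp$assignments$cluster[i], k)
    expect_equal(grp$assignments$admixed[i], qbig[i, k] <= 0.7)
  }
  expect_error(assign_groups(rbind(c(0.5, 0.6))), "sum to 1")
  expect_error(assign_groups(q, threshold = 0.5), "threshold")
})

test_that("run alignment undoes label switching and greedy matches exhaustive search at K = 2", {
  set.seed(15)
  q1 <- t(apply(matrix(rgamma(60, 1), 20, 3), 1, function(x) x / sum(x)))
  q2 <- q1[, c(3, 1, 2)]
  al <- align_runs(list(q1, q2))
  expect_equal(al$aligned[[2]], q1, ignore_attr = TRUE)
  expect_equal(al$mean_q, q1, ignore_attr = TRUE)
  expect_equal(align_runs(list(q1))$permutations[[1]], 1:3)
  expect_error(align_runs(list(q1, q1[, 1:2])), "differing K")

  for (seed in 1:5) {
    set.seed(seed)
    qa <- t(apply(matrix(rgamma(30, 1), 15, 2), 1, function(x) x / sum(x)))
    qb <- t(apply(matrix(rgamma(30, 1), 15, 2), 1, function(x) x / sum(x)))
    al <- align_runs(list(qa, qb))
    score <- function(perm) sum(diag(cor(qa, qb[, perm])))
    best <- if (score(1:2) >= score(2:1)) 1:2 else 2:1
    expect_equal(al$permutations[[2]], best)
  }
})

test_that("the lnPr(X|K) estimator is mean minus half the variance", {
  trace <- c(-100, -98, -103, -101)
  expect_equal(ln_pr_k(trace), mean(trace) - var(trace) / 2)
  expect_error(ln_pr_k(-1), "at least 2")
})
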