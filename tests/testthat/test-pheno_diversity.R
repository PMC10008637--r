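test_that("category frequencies match hand counts and drop missing", {
  habit <- c(rep(1L, 16), rep(2L, 72), rep(3L, 6))   # 94 landrace plant-habit calls
  f <- category_frequencies(habit)
  expect_equal(round(as.numeric(f), 3), c(0.170, 0.766, 0.064))
  expect_equal(sum(f), 1)

  expect_equal(as.numeric(category_frequencies(c(2L, 2L, 2L))), c(0, 1))
  expect_equal(as.numeric(category_frequencies(c(1L, 1L, 2L, 2L))), c(0.5, 0.5))
  expect_equal(as.numeric(category_frequencies(c(1L, NA, 2L))), c(0.5, 0.5))
  expect_error(category_frequencies(c(NA_integer_, NA_integer_)), "missing")
})

test_that("Shannon index reproduces published worked examples and closed forms", {
  expect_equal(round(shannon_index(c(0.170, 0.766, 0.064)), 2), 0.68)
  expect_equal(round(shannon_index(c(0.118, 0.788, 0.094)), 2), 0.66)
  expect_equal(round(shannon_index(c(0.053, 0.947)), 2), 0.21)
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_error(shannon_index(c(-0.1, 1.1)), "negative")
})

test_that("H' is maximal for uniform categories, zero only when degenerate, and merging never increases it", {
  set.seed(41)
  for (rep in 1:25) {
    k <- sample(2:9, 1)
    p <- rdirichlet1(rep(1, k))
    h <- shannon_index(p)
    expect_lte(h, log(k) + 1e-12)
    expect_gt(h, 0)
    merged <- c(p[1] + p[2], p[-(1:2)])   # merge two categories
    expect_lte(shannon_index(merged), h + 1e-12)
  }
  expect_equal(shannon_index(rep(1 / 7, 7)), log(7))
})

test_that("1-10 scoring follows the M/S bin construction", {
  sch <- scoring_scheme(M = 100, S = 10)
  expect_equal(score_quantitative(100, sch), 6L)          # x = M sits in the 6 bin
  expect_equal(score_quantitative(100 - 30, sch), 1L)     # M - 3S
  expect_equal(score_quantitative(100 + 20, sch), 10L)    # M + 2S boundary is score 10
  expect_equal(score_quantitative(100 - 20, sch), 2L)     # M - 2S boundary starts score 2
  expect_true(is.na(score_quantitative(NA, sch)))
  expect_error(scoring_scheme(M = 5, S = 0), "degenerate")
})

test_that("scoring is a monotone partition of the real line", {
  set.seed(42)
  for (rep in 1:20) {
    M <- runif(1, -50, 50); S <- runif(1, 0.1, 20)
    sch <- scoring_scheme(M = M, S = S)
    x <- sort(c(rnorm(200, M, 2 * S), sch$edges[2:10]))  # include the bin edges
    sc <- score_quantitative(x, sch)
    expect_true(all(sc %in% 1:10))                        # every value exactly one score
    expect_true(all(diff(sc) >= 0))                       # monotone in x
  }
})

test_that("score frequencies of normal data match normal-CDF bin probabilities", {
  M <- 50; S <- 8; n <- 1000
  set.seed(7)
  x <- rnorm(n, M, S)
  sc <- score_quantitative(x, scoring_scheme(M = M, S = S))
  f <- category_frequencies(sc, n_categories = 10)
  edges <- c(-Inf, M - 2 * S + 0.5 * S * (0:8), Inf)
  p <- diff(pnorm(edges, M, S))                           # independent CDF oracle
  tol <- 4 * sqrt(p * (1 - p) / n) + 1e-9                 # ~4 binomial SEs
  expect_true(all(abs(as.numeric(f) - p) < tol))
  expect_equal(sum(f), 1)
})

test_that("quantitative summaries separate score-based H' from raw-value statistics", {
  s <- quantitative_trait_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)            # sample SD, n - 1 denominator
  expect_equal(s$cv, 50)
  expect_equal(s$range, 2)

  set.seed(8)
  v <- rnorm(120, 20, 5)
  sch <- scoring_scheme(v)
  s <- quantitative_trait_summary(v, sch)
  expect_equal(s$h, shannon_index(category_frequencies(
    score_quantitative(v, sch), n_categories = 10)))
  expect_equal(s$cv, sd(v) / mean(v) * 100)
  expect_error(quantitative_trait_summary(c(-1, 1)), "CV undefined")
})

test_that("population comparison reproduces difference rows and a synthetic construction", {
  qual <- reference_table("qualitative")
  llr <- qual[qual$pop == "LLR", ]
  cbl <- qual[qual$pop == "CBL", ]
  dif <- compare_populations(llr, cbl)
  expect_equal(dif$dh[dif$trait == "plant_habit"], 0.68 - 0.66)
  expect_equal(dif$dfreq.1[dif$trait == "plant_habit"], 17.0 - 11.8)

  same <- compare_populations(llr, llr)
  expect_true(all(same$dh == 0))
  expect_true(all(as.matrix(same[grep("dfreq", names(same))]) == 0, na.rm = TRUE))

  # two populations built with a known frequency shift
  fA <- c(0.2, 0.5, 0.3); fB <- c(0.4, 0.4, 0.2)
  mk <- function(f, pop) {
    v <- rep(1:3, round(1000 * f))
    pd <- pheno_diversity(trait_table(sprintf("%s%04d", pop, seq_along(v)),
                                      rep(pop, length(v)),
                                      qualitative = data.frame(t1 = v)))
    pd$qualitative
  }
  dif <- compare_populations(mk(fA, "A"), mk(fB, "B"))
  expect_equal(dif$dh, shannon_index(fA) - shannon_index(fB))
  expect_equal(c(dif$dfreq.1, dif$dfreq.2, dif$dfreq.3), 100 * (fA - fB))
})

test_that("mismatched category dictionaries are an alignment error", {
  a <- data.frame(trait = "t", pop = "A", h = 1, freq.1 = 50, freq.2 = 50)
  b <- data.frame(trait = "t", pop = "B", h = 1, freq.1 = 50, freq.3 = 50)
  expect_error(compare_populations(a, b), "dictionaries differ")
})
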