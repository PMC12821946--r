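test_that("rank-abundance orders by count with lexicographic tie-break", {
  s <- make_rep(c(5, 9, 5), keys = c("a", "b", "c"))
  ra <- rank_abundance(s)
  expect_equal(ra$keys, c("b", "a", "c"))
  expect_equal(ra$counts, c(9, 5, 5))
  one <- rank_abundance(make_rep(4))
  expect_length(one$counts, 1)
  # row order of the input is irrelevant
  s2 <- make_rep(c(5, 5, 9), keys = c("c", "a", "b"))
  expect_equal(rank_abundance(s2), ra)
})

test_that("constant and too-short sequences yield a no-change result", {
  res <- amoc_variance_changepoint(rep(7, 20))
  expect_equal(res$tau, 0L)
  expect_equal(res$reason, "constant")
  res <- amoc_variance_changepoint(c(3, 1, 2))
  expect_equal(res$tau, 0L)
  expect_equal(res$reason, "too_short")
})

test_that("the two-regime fixture splits after the third clone", {
  v <- c(90, 70, 50, 4, 3, 3, 2, 2, 2, 2)
  res <- amoc_variance_changepoint(v)
  expect_equal(res$tau, 3L)
  expect_equal(res$tau, brute_amoc(v)$tau)
  expect_equal(res$loglik_gain, brute_amoc(v)$gain, tolerance = 1e-10)
})

test_that("the search agrees exactly with brute force on random sequences", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(6:80, 1)
    v <- sort(rlnorm(n, 3, 1.5), decreasing = TRUE)
    a <- amoc_variance_changepoint(v)
    b <- brute_amoc(v)
    if (a$tau > 0) {
      expect_equal(a$tau, b$tau)
      expect_equal(a$loglik_gain, b$gain, tolerance = 1e-10)
    } else {
      # below-penalty results still found the same best split
      expect_true(a$reason %in% c("below_penalty", "constant"))
      if (a$reason == "below_penalty") expect_lte(b$gain, a$penalty_used + 1e-9)
    }
  }
})

test_that("the change point is invariant to scaling all counts", {
  set.seed(14)
  v <- c(rnorm(30, 200, 20), rnorm(50, 10, 1))
  a <- amoc_variance_changepoint(v)
  b <- amoc_variance_changepoint(v * 17)
  expect_equal(a$tau, b$tau)
})

test_that("planted variance regimes are recovered at the known split", {
  set.seed(15)
  hits <- 0L
  n_sim <- 100L
  for (i in seq_len(n_sim)) {
    v <- c(rnorm(40, 500, 20), rnorm(160, 20, 1))
    res <- amoc_variance_changepoint(v)
    if (abs(res$tau - 40L) <= 3L) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("classification maps the split back to clonotype keys", {
  # one clone holding 90% of reads among 50 clones must be expanded
  s <- make_rep(c(4500, rep(10, 49)) + sample(0:3, 50, replace = TRUE))
  res <- classify_expanded(s)
  expect_true(s$records$key[which.max(s$records$count)] %in% res$expanded_keys)
  # partition is exact and consistent
  expect_setequal(c(res$expanded_keys, res$background_keys), s$records$key)
  expect_equal(res$tau, length(res$expanded_keys))
  expect_equal(res$expanded_abundance,
               til_abundance(s, res$expanded_keys), tolerance = 1e-12)
  expect_equal(res$threshold_fraction,
               min(s$records$count[s$records$key %in% res$expanded_keys]) /
                 total_reads(s))
  # uniform repertoire: empty expanded set
  u <- classify_expanded(make_rep(rep(10, 50)))
  expect_equal(u$tau, 0L)
  expect_equal(u$expanded_abundance, 0)
})

test_that("expanded abundance is nondecreasing in a forced tau sweep", {
  set.seed(16)
  s <- make_rep(sort(rpois(40, 50), decreasing = TRUE) + 1)
  prev <- -1
  for (tau in 0:40) {
    res <- classify_expanded(s, forced_tau = tau)
    expect_gte(res$expanded_abundance, prev - 1e-12)
    prev <- res$expanded_abundance
  }
})

test_that("the data-driven threshold beats a fixed 1% cut on planted regimes", {
  # planted expanded regime at ~0.4% relative abundance: a 1% rule misses it
  set.seed(17)
  sens_cp <- sens_fixed <- spec_cp <- spec_fixed <- numeric(0)
  for (i in 1:20) {
    n_exp <- 12
    counts <- c(round(rnorm(n_exp, 4000, 300)),          # expanded regime
                round(rlnorm(600, log(150), 0.35)))      # background
    truth <- c(rep(TRUE, n_exp), rep(FALSE, 600))
    keys <- sprintf("k%04d", seq_along(counts))
    s <- make_rep(counts, keys = keys)
    res <- classify_expanded(s)
    called_cp <- keys %in% res$expanded_keys
    called_fx <- counts / sum(counts) > 0.01
    sens_cp <- c(sens_cp, mean(called_cp[truth]))
    sens_fixed <- c(sens_fixed, mean(called_fx[truth]))
    spec_cp <- c(spec_cp, mean(!called_cp[!truth]))
    spec_fixed <- c(spec_fixed, mean(!called_fx[!truth]))
  }
  expect_gte(mean(sens_cp), mean(sens_fixed))
  expect_gt(mean(sens_cp), 0.9)
  expect_gte(mean(spec_cp), 0.9)
})

test_that("log transform is available and recorded", {
  s <- make_rep(c(5000, 4500, 120, 110, 100, 90, 80, 70, 60, 50))
  res <- classify_expanded(s, transform = "log")
  expect_equal(res$transform, "log")
  expect_equal(res$tau, 2L)
})
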