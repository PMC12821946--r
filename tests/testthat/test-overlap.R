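test_that("Morisita-Horn self-overlap is 1 and disjoint overlap is 0", {
  a <- make_rep(c(10, 5, 2))
  expect_equal(morisita_overlap(a, a), 1)
  b <- make_rep(c(4, 4), keys = c("ZZ00001", "ZZ00002"))
  expect_equal(morisita_overlap(a, b), 0)
  expect_error(morisita_overlap(a, make_rep(integer())),
               class = "tilrep_empty_sample_error")
})

test_that("the x=(3,1,0), y=(1,1,2) pair gives M = 0.5", {
  keys <- c("K1", "K2", "K3")
  a <- make_rep(c(3, 1), keys = keys[1:2])
  b <- make_rep(c(1, 1, 2), keys = keys)
  expect_equal(morisita_overlap(a, b), 0.5)
  expect_equal(naive_morisita(c(3, 1, 0), c(1, 1, 2)), 0.5)
})

test_that("Morisita is symmetric and invariant to count scaling", {
  set.seed(7)
  for (i in 1:100) {
    S <- sample(3:60, 1)
    shared <- sample(0:S, 1)
    ka <- sprintf("A%04d", 1:S)
    kb <- c(sample(ka, shared), sprintf("B%04d", seq_len(S - shared)))
    a <- make_rep(sample(1:500, S, replace = TRUE), keys = ka)
    b <- make_rep(sample(1:500, S, replace = TRUE), keys = kb)
    m1 <- morisita_overlap(a, b)
    m2 <- morisita_overlap(b, a)
    expect_equal(m1, m2, tolerance = 1e-12)
    expect_gte(m1, 0)
    expect_lte(m1, 1 + 1e-12)
    a10 <- make_rep(a$records$count * 10L, keys = a$records$cdr3_nt)
    expect_equal(morisita_overlap(a10, b), m1, tolerance = 1e-12)
  }
})

test_that("mixing a disjoint pair raises the overlap monotonically", {
  set.seed(8)
  ka <- sprintf("A%03d", 1:20)
  kb <- sprintf("B%03d", 1:20)
  fa <- as.numeric(sample(1:100, 20))
  fb <- as.numeric(sample(1:100, 20))
  a <- make_rep(fa, keys = ka)
  prev <- -1
  for (t in seq(0, 1, by = 0.1)) {
    mix <- make_rep(c(round(1000 * (1 - t) * fb / sum(fb)),
                      round(1000 * t * fa / sum(fa))) + 0,
                    keys = c(kb, ka))
    mix$records <- mix$records[mix$records$count > 0, ]
    if (richness(mix) == 0) next
    m <- morisita_overlap(a, mix)
    expect_gte(m, prev - 0.02)  # nondecreasing up to rounding
    prev <- m
  }
})

test_that("the overlap matrix is symmetric with unit diagonal and pooled means", {
  a <- make_rep(c(5, 3), sample_id = "a", patient_id = "P1", cohort = "PBMC_DNA")
  b <- make_rep(c(5, 3), sample_id = "b", patient_id = "P1", cohort = "PBMC_DNA")
  c3 <- make_rep(c(2, 2), keys = c("ZZ1", "ZZ2"), sample_id = "c",
                 patient_id = "P1", cohort = "PBMC_DNA")
  om <- overlap_matrix(list(a, b, c3))
  expect_equal(diag(om$matrix), rep(1, 3), ignore_attr = TRUE)
  expect_equal(om$matrix, t(om$matrix), tolerance = 1e-12)
  # pairs: (a,b)=1, (a,c)=0, (b,c)=0 -> mean 1/3
  expect_equal(om$patient_means$mean_morisita, 1 / 3)
  expect_equal(om$patient_means$n_pairs, 3L)

  # identical samples give all-ones off-diagonal
  om2 <- overlap_matrix(list(a, b))
  expect_equal(om2$matrix["a", "b"], 1)

  # permuting sample order permutes the matrix, same mean
  om3 <- overlap_matrix(list(c3, b, a))
  expect_equal(om3$matrix["a", "c"], om$matrix["a", "c"])
  expect_equal(om3$patient_means$mean_morisita, om$patient_means$mean_morisita)
})

test_that("cross-cohort R2 matches Pearson and honours scope rules", {
  a <- make_rep(c(50, 30, 20), keys = c("K1", "K2", "K3"))
  expect_equal(cross_cohort_r2(a, a), 1)
  # exact linear rescaling of shared abundances
  b <- make_rep(c(5, 3, 2), keys = c("K1", "K2", "K3"))
  expect_equal(cross_cohort_r2(a, b), 1, tolerance = 1e-12)
  # hand-derived: abundances (0.5,0.3,0.2) vs (0.2,0.3,0.5)
  b2 <- make_rep(c(20, 30, 50), keys = c("K1", "K2", "K3"))
  r2 <- cross_cohort_r2(a, b2)
  expect_equal(r2, cor(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))^2)
  expect_equal(round(r2, 4), 0.8622)  # r = -0.9286, sign discarded by squaring
  # fewer than 3 shared clonotypes: sentinel, not an error
  d <- make_rep(c(9, 1), keys = c("K1", "ZZ"))
  expect_true(is.na(cross_cohort_r2(a, d)))
  # subset restriction
  expect_true(is.na(cross_cohort_r2(a, b2, subset = c("K1", "K2"))))
  # log10 mode drops union zeros and still works on shared support
  expect_equal(cross_cohort_r2(a, b2, scope = "union", transform = "log10"),
               cor(log10(c(0.5, 0.3, 0.2)), log10(c(0.2, 0.3, 0.5)))^2)
})

test_that("R2 is invariant to relabeling and uniform count scaling", {
  set.seed(9)
  keys <- sprintf("K%03d", 1:30)
  a <- make_rep(sample(1:200, 30), keys = keys)
  b <- make_rep(sample(1:200, 30), keys = keys)
  r <- cross_cohort_r2(a, b)
  b5 <- make_rep(b$records$count * 5L, keys = b$records$cdr3_nt)
  expect_equal(cross_cohort_r2(a, b5), r, tolerance = 1e-12)
})
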