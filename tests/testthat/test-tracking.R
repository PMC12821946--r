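mk_patient <- function(response = "SD") {
  # product shares k2,k3 with baseline; post dominated by product clones
  base <- make_rep(c(50, 30, 20), keys = c("k1", "k2", "k3"),
                   sample_id = "base", cohort = "PBMC_DNA",
                   timepoint_days = -14L)
  product <- make_rep(c(40, 40, 20), keys = c("k2", "k3", "k9"),
                      sample_id = "prod", cohort = "TIL_DNA",
                      timepoint_days = 0L)
  post <- make_rep(c(35, 30, 25, 10), keys = c("k2", "k9", "k1", "k7"),
                   sample_id = "post", cohort = "PBMC_DNA",
                   timepoint_days = 28L)
  patient_series("P1", response, list(base, product, post))
}

test_that("TIL sets follow the product / product-and-PBMC definitions", {
  p <- mk_patient()
  prod_only <- til_clonotype_set(p, "product_only")
  expect_setequal(prod_only$keys, c("k2", "k3", "k9"))
  both <- til_clonotype_set(p, "product_and_pbmc")
  # k9 appears in the post PBMC sample, k3 only at baseline
  expect_setequal(both$keys, c("k2", "k3", "k9"))
  expect_true(all(both$keys %in% prod_only$keys))

  # PBMC union disjoint from the product -> empty strict set
  base <- make_rep(c(5, 5), keys = c("x1", "x2"), sample_id = "b",
                   cohort = "PBMC_DNA", timepoint_days = -1L)
  product <- make_rep(c(5, 5), keys = c("y1", "y2"), sample_id = "pr",
                      cohort = "TIL_DNA", timepoint_days = 0L)
  p2 <- patient_series("P2", "PD", list(base, product))
  expect_length(til_clonotype_set(p2, "product_and_pbmc")$keys, 0)
  # missing product errors with the patient named
  p3 <- patient_series("P3", "PD", list(base))
  expect_error(til_clonotype_set(p3), "P3",
               class = "tilrep_missing_product_error")
})

test_that("TIL abundance is the summed relative abundance over the set", {
  s <- make_rep(c(50, 30, 20), keys = c("k1", "k2", "k3"))
  expect_equal(til_abundance(s, c("k1", "k3")), 0.7)
  expect_equal(til_abundance(s, c("zz")), 0)
  expect_equal(til_abundance(s, c("k1", "k2", "k3", "zz")), 1)
})

test_that("TIL abundance is monotone and additive over set partitions", {
  set.seed(11)
  s <- make_rep(sample(1:100, 50), keys = sprintf("k%03d", 1:50))
  all_keys <- s$records$key
  sub <- sample(all_keys, 20)
  expect_gte(til_abundance(s, c(sub, sample(all_keys, 5))),
             til_abundance(s, sub) - 1e-12)
  part <- split(all_keys, rep(1:5, 10))
  expect_equal(sum(vapply(part, function(k) til_abundance(s, k), numeric(1))),
               til_abundance(s, all_keys), tolerance = 1e-12)
})

test_that("persistence works in abundance and clonotype-fraction modes", {
  p <- mk_patient()
  post <- first_post_sample(p, "PBMC_DNA")
  product <- infusion_product(p)
  expect_equal(persistence(post, post), 1)
  expect_equal(persistence(post, post, "clonotype_fraction"), 1)
  # shared with product: k2 (35) and k9 (30) of 100
  expect_equal(persistence(post, product), 0.65)
  expect_equal(persistence(post, product, "clonotype_fraction"), 2 / 4)
  # restriction to an expanded-set style label
  expect_equal(persistence(post, product, "clonotype_fraction",
                           restrict_to = c("k2", "k1", "k7")), 1 / 3)
  expect_true(is.na(persistence(post, product, "clonotype_fraction",
                                restrict_to = "absent")))
})

test_that("clonotype-fraction persistence mirrors simple counting", {
  ref_keys <- sprintf("r%02d", 1:4)
  post <- make_rep(rep(2, 10), keys = c(ref_keys, sprintf("n%02d", 1:6)))
  ref <- make_rep(rep(3, 4), keys = ref_keys)
  expect_equal(persistence(post, ref, "clonotype_fraction"), 0.4)
  sub7 <- c(ref_keys[1:3], sprintf("n%02d", 1:4))
  expect_equal(persistence(post, ref, "clonotype_fraction", restrict_to = sub7),
               3 / 7)
})

test_that("tracking tables zero-fill and normalize within timepoints", {
  p <- mk_patient()
  til <- til_clonotype_set(p)
  tt <- tracking_table(p, "PBMC_DNA", til)
  sums <- tapply(tt$abundance, tt$timepoint_days, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  # k3 absent post-infusion: explicit zero row
  expect_equal(tt$abundance[tt$key == "k3" & tt$timepoint_days == 28], 0)
  expect_true(all(tt$is_til[tt$key %in% c("k2", "k3", "k9")]))
  expect_false(any(tt$is_til[tt$key %in% c("k1", "k7")]))
})

test_that("per-patient TIL summaries carry both definitions and modes", {
  p <- mk_patient("PR")
  ts <- til_summary(p)
  expect_equal(nrow(ts), 2)
  row <- ts[ts$definition == "product_only", ]
  expect_equal(row$baseline_til_abundance, 0.5)        # k2+k3 at baseline
  expect_equal(row$first_post_til_abundance, 0.65)     # k2+k9 post
  expect_equal(row$persistence_abundance, 0.65)
  expect_true(row$responder)
})
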