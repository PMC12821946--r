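# Small, fast configuration used throughout these tests; study-scale defaults
# are exercised in the acceptance suite.
small_cfg <- function(seed = 1, ...) {
  cohort_config(
    baseline_richness = 150L, infusion_richness = 80L,
    depths = c(PBMC_DNA = 60000, PBMC_RNA = 30000, CFDNA = 30000,
               TIL_DNA = 60000, TIL_RNA = 30000),
    seed = seed, ...
  )
}

test_that("config validation rejects infeasible sharing and bad fractions", {
  expect_error(cohort_config(theta = 1.2), class = "tilrep_config_error")
  expect_error(cohort_config(theta = 0.9, responder_theta_mult = 1,
                             baseline_richness = 600L,
                             infusion_richness = 300L),
               class = "tilrep_config_error")
  expect_error(cohort_config(depths = c(PBMC_DNA = 100)),
               class = "tilrep_config_error")
})

test_that("patients simulate all five compartments with valid samples", {
  sim <- simulate_patient(small_cfg(), 1)
  cohorts <- vapply(sim$series$samples, function(s) s$cohort, character(1))
  expect_setequal(unique(cohorts),
                  c("PBMC_DNA", "PBMC_RNA", "CFDNA", "TIL_DNA", "TIL_RNA"))
  for (s in sim$series$samples) {
    expect_gt(total_reads(s), 0)
    expect_false(anyDuplicated(s$records$key) > 0)
    p <- rel_abundance(s)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # contamination present: some unproductive and some singleton records
  dna <- sim$series$samples[[1]]
  expect_gt(sum(!dna$records$productive), 0)
  expect_gt(sum(dna$records$count == 1), 0)
  # both unproductive encodings are exercised
  aa <- dna$records$cdr3_aa[!dna$records$productive]
  expect_true(any(grepl("_", aa)) && any(grepl("\\*", aa)))
})

test_that("ground-truth provenance labels partition the simulated keys", {
  sim <- simulate_patient(small_cfg(), 2)
  prov <- sim$truth$provenance
  expect_false(anyDuplicated(prov$key) > 0)
  post <- first_post_sample(sim$series, "PBMC_DNA")
  post_real <- post$records$key[post$records$productive &
                                  post$records$count > 1]
  expect_true(all(post_real %in% prov$key))
  expect_setequal(sim$truth$shared_keys,
                  intersect(sim$truth$product_keys,
                            clonotype_key(
                              baseline_sample(sim$series, "PBMC_DNA")$records)))
})

test_that("the same master seed reproduces a cohort byte for byte", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  cfg <- small_cfg(seed = 9, n_patients = 2L)
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("adding a patient never perturbs existing patients' draws", {
  cfg2 <- small_cfg(seed = 4, n_patients = 2L)
  cfg3 <- small_cfg(seed = 4, n_patients = 3L)
  a <- simulate_cohort(cfg2)
  b <- simulate_cohort(cfg3)
  expect_equal(a$patients[[1]]$samples[[1]]$records,
               b$patients[[1]]$samples[[1]]$records)
  expect_equal(a$patients[[2]]$samples[[6]]$records,
               b$patients[[2]]$samples[[6]]$records)
})

test_that("responder allocation is deterministic", {
  cfg <- small_cfg(n_patients = 9L, responder_fraction = 1 / 3)
  sim <- simulate_cohort(cfg)
  responders <- vapply(sim$patients, function(p) p$responder, logical(1))
  expect_equal(sum(responders), 3L)
  expect_equal(responders, c(rep(TRUE, 3), rep(FALSE, 6)))
  man_resp <- unique(sim$manifest[, c("patient_id", "response")])
  expect_equal(sum(man_resp$response == "PR"), 3L)
})

test_that("degenerate mixing weights collapse the post-infusion repertoire", {
  # w=1, no survival, no influx: post keys are product keys (+ contamination)
  cfg <- small_cfg(seed = 6, w = 1, survival = 0, influx = 0,
                   unproductive_rate = 0, singleton_rate = 0,
                   responder_w_mult = 1)
  sim <- simulate_patient(cfg, 1)
  post <- first_post_sample(sim$series, "PBMC_DNA")
  expect_true(all(post$records$key %in% sim$truth$product_keys))
  til <- til_clonotype_set(sim$series)
  expect_equal(til_abundance(post, til), 1)

  # w=0, full survival, no influx: post is a resampling of baseline
  cfg0 <- small_cfg(seed = 6, w = 0, survival = 1, influx = 0,
                    unproductive_rate = 0, singleton_rate = 0,
                    responder_w_mult = 1, theta = 0.1,
                    responder_theta_mult = 1)
  sim0 <- simulate_patient(cfg0, 1)
  base <- baseline_sample(sim0$series, "PBMC_DNA")
  post0 <- first_post_sample(sim0$series, "PBMC_DNA")
  expect_true(all(post0$records$key %in% base$records$key))
  expect_gt(morisita_overlap(base, post0), 0.98)
})

test_that("the realized sharing fraction matches theta on key sets", {
  cfg <- small_cfg(seed = 8, theta = 0.4, responder_theta_mult = 1)
  shares <- vapply(1:30, function(i) {
    sim <- simulate_patient(cfg, i)
    length(sim$truth$shared_keys) / cfg$baseline_richness
  }, numeric(1))
  expect_equal(unique(shares), 0.4)
  # and the product/baseline key overlap measured from the samples agrees
  sim <- simulate_patient(cfg, 1)
  base_keys <- filter_repertoire(
    baseline_sample(sim$series, "PBMC_DNA"))$sample$records$key
  prod_keys <- filter_repertoire(
    infusion_product(sim$series))$sample$records$key
  measured <- length(intersect(base_keys, prod_keys)) / cfg$baseline_richness
  expect_equal(measured, 0.4, tolerance = 0.1)
})

test_that("first-post TIL abundance grows with the mixing weight", {
  ab <- vapply(c(0.1, 0.5, 0.9), function(w) {
    cfg <- small_cfg(seed = 11, w = w, responder_w_mult = 1)
    sim <- simulate_patient(cfg, 1)
    til <- til_clonotype_set(sim$series)
    til_abundance(first_post_sample(sim$series, "PBMC_DNA"), til)
  }, numeric(1))
  expect_true(all(diff(ab) > 0))
})
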