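#' Synthetic cohort configuration
#'
#' Parameters of the synthetic TIL-ACT cohort generator. The defaults
#' describe a nine-patient melanoma-style cohort (three responders) with
#' five compartments per patient (PBMC DNA/RNA, cfDNA, TIL product
#' DNA/RNA), a heavy-tailed Zipf clone-size law with a planted expanded
#' head, partial clonotype sharing between baseline and infusion product,
#' multinomial sequencing noise at compartment-specific depths, and
#' unproductive / singleton contamination.
#'
#' Responder patients receive effect multipliers on the
#' baseline-to-product sharing fraction `theta`, the infusion mixing
#' weight `w`, and the baseline clone-size skew, reproducing the
#' direction (not the exact values) of the response-associated contrasts:
#' higher baseline and post-infusion TIL abundance, higher DNA
#' between-timepoint overlap, and higher baseline clonality in
#' responders.
#'
#' @param n_patients Number of patients (default 9).
#' @param responder_fraction Fraction of responders; responders are
#'   allocated deterministically to the first
#'   `round(n_patients * responder_fraction)` patients (default 1/3).
#' @param clone_size_law `"zipf"` (default) or `"lognormal"`.
#' @param zipf_s Zipf exponent (default 1.1).
#' @param lognormal_meanlog,lognormal_sdlog Lognormal clone-size
#'   parameters (used when `clone_size_law = "lognormal"`).
#' @param n_expanded,expanded_boost Number of planted expanded clones per
#'   repertoire head and their frequency boost factor -- this creates the
#'   sharp two-regime drop in the rank-abundance curve that the
#'   change-point method targets.
#' @param baseline_richness,infusion_richness Clonotypes in the baseline
#'   blood repertoire and the infusion product.
#' @param theta Fraction of baseline clonotypes shared with the infusion
#'   product.
#' @param w Infusion mixing weight: fraction of the post-infusion
#'   repertoire drawn from product clonotype frequencies.
#' @param w_decay Multiplier applied to `w` at each subsequent
#'   post-infusion timepoint (product clones wane).
#' @param survival Fraction of baseline clonotypes surviving
#'   lymphodepletion.
#' @param influx Fraction of the endogenous post-infusion repertoire made
#'   of novel (previously unseen) clonotypes. The default (0.8) makes
#'   reconstitution after lymphodepletion mostly de novo, keeping the
#'   abundance overlap between baseline and post-infusion repertoires
#'   low unless product sharing carries it.
#' @param cfdna_sparsity cfDNA richness as a fraction of the DNA richness
#'   (cfDNA repertoires are sparse: tens of clonotypes against hundreds).
#' @param cfdna_skew Power applied to DNA frequencies before cfDNA
#'   sampling (cfDNA over-represents dominant clones).
#' @param rna_sdlog Lognormal sd of the per-clone expression multiplier
#'   linking DNA to RNA frequencies.
#' @param depths Named integer vector of sequencing depths (total clone
#'   units) per compartment.
#' @param unproductive_rate Fraction of clonotypes that are unproductive
#'   contamination (default 0.221, the rate observed in genomic DNA
#'   repertoires of this assay).
#' @param singleton_rate Singleton inflation: extra count-1 productive
#'   clonotypes as a fraction of richness.
#' @param responder_theta_mult,responder_w_mult,responder_clonality_mult
#'   Responder effect multipliers on `theta`, `w` and the clone-size tail
#'   exponent.
#' @param post_timepoints Days of the post-infusion draws (baseline is
#'   day -14, product day 0).
#' @param seed Master seed; all randomness is keyed off it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 9L,
                          responder_fraction = 1 / 3,
                          clone_size_law = c("zipf", "lognormal"),
                          zipf_s = 0.45,
                          lognormal_meanlog = 0, lognormal_sdlog = 1.5,
                          n_expanded = 15L, expanded_boost = 3,
                          baseline_richness = 600L, infusion_richness = 300L,
                          theta = 0.05, w = 0.25, w_decay = 0.7,
                          survival = 0.10, influx = 0.80,
                          cfdna_sparsity = 0.06, cfdna_skew = 1.5,
                          rna_sdlog = 0.5,
                          depths = c(PBMC_DNA = 2500000, PBMC_RNA = 170000,
                                     CFDNA = 1000000, TIL_DNA = 2500000,
                                     TIL_RNA = 170000),
                          unproductive_rate = 0.221,
                          singleton_rate = 0.15,
                          responder_theta_mult = 8,
                          responder_w_mult = 2,
                          responder_clonality_mult = 1.5,
                          post_timepoints = c(28L, 98L),
                          seed = 1L) {
  clone_size_law <- match.arg(clone_size_law)
  cfg <- as.list(environment())
  fracs <- c(responder_fraction = responder_fraction, theta = theta, w = w,
             survival = survival, influx = influx,
             cfdna_sparsity = cfdna_sparsity)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions must lie in [0, 1]", class = "tilrep_config_error")
  }
  if (any(depths < 1) || !all(.tilrep_cohorts %in% names(depths))) {
    abort("depths must be positive and name all five compartments",
          class = "tilrep_config_error")
  }
  theta_max <- theta * max(1, responder_theta_mult)
  if (round(theta_max * baseline_richness) > infusion_richness) {
    abort("infeasible config: theta * baseline_richness exceeds infusion richness",
          class = "tilrep_config_error")
  }
  structure(cfg, class = "cohort_config")
}

# ---- internal generators ----------------------------------------------------

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

gen_cdr3_pool <- function(n, seed) {
  withr::with_seed(seed, {
    paste_rows <- function(m) do.call(paste0, asplit(m, 2))
    draw <- function(k) {
      paste_rows(matrix(sample(c("A", "C", "G", "T"), k * 36L, replace = TRUE),
                        nrow = k))
    }
    nt <- draw(n)
    while (anyDuplicated(nt)) {
      dup <- which(duplicated(nt))
      nt[dup] <- draw(length(dup))
    }
    aa <- paste0("CASS",
                 paste_rows(matrix(sample(.aa_alphabet, n * 7L, replace = TRUE),
                                   nrow = n)),
                 "F")
    v <- paste0("TRBV", sample(1:30, n, replace = TRUE), "-",
                sample(1:3, n, replace = TRUE), "*01")
    j <- paste0("TRBJ", sample(1:2, n, replace = TRUE), "-",
                sample(1:7, n, replace = TRUE), "*01")
    tibble(cdr3_nt = nt, cdr3_aa = aa, v_call = v, j_call = j)
  })
}

# Clone-size law frequencies for S clones, with the first n_expanded ranks
# boosted to plant a distinct expanded regime. Returned in rank order.
# boost = FALSE gives the unboosted law -- used for novel reconstitution
# clones, which are naive-like and carry no antigen-expanded head.
clone_frequencies <- function(cfg, S, seed, clonality_mult = 1, boost = TRUE) {
  withr::with_seed(seed, {
    if (cfg$clone_size_law == "zipf") {
      f <- seq_len(S)^(-cfg$zipf_s * clonality_mult)
    } else {
      f <- sort(stats::rlnorm(S, cfg$lognormal_meanlog,
                              cfg$lognormal_sdlog * clonality_mult),
                decreasing = TRUE)
    }
    if (boost) {
      k <- min(cfg$n_expanded, S)
      f[seq_len(k)] <- f[seq_len(k)] * cfg$expanded_boost
    }
    f / sum(f)
  })
}

# Multinomial read sampling of a frequency vector at a given depth;
# returns integer counts (zeros retained).
draw_reads <- function(freqs, depth, seed) {
  withr::with_seed(seed, as.integer(stats::rmultinom(1, depth, freqs)))
}

make_sample <- function(pool, spare, idx, freqs, depth, cfg, sample_id,
                        patient_id, cohort, timepoint_days, seed) {
  counts <- draw_reads(freqs, depth, derive_seed(seed, 1))
  keep <- counts > 0
  rec <- pool[idx[keep], , drop = FALSE]
  rec$count <- counts[keep]
  rec$productive <- TRUE

  # contamination: unproductive clonotypes (half frameshift '_', half
  # stop '*') and inflated productive singletons, drawn from spare keys
  S_obs <- nrow(rec)
  n_unprod <- round(cfg$unproductive_rate / (1 - cfg$unproductive_rate) * S_obs)
  n_single <- round(cfg$singleton_rate * S_obs)
  extra <- withr::with_seed(derive_seed(seed, 2), {
    n_extra <- n_unprod + n_single
    if (n_extra > 0) {
      ex <- pool[spare(n_extra), , drop = FALSE]
      if (n_unprod > 0) {
        half <- ceiling(n_unprod / 2)
        sub_at <- sample(5:9, n_unprod, replace = TRUE)
        ex$cdr3_aa[seq_len(n_unprod)] <- vapply(seq_len(n_unprod), function(i) {
          sym <- if (i <= half) "_" else "*"
          s <- ex$cdr3_aa[i]
          paste0(substr(s, 1, sub_at[i] - 1), sym,
                 substr(s, sub_at[i] + 1, nchar(s)))
        }, character(1))
      }
      ex$count <- c(if (n_unprod > 0) 1L + stats::rgeom(n_unprod, 0.25) else integer(),
                    rep(1L, n_single))
      ex$productive <- rep(c(FALSE, TRUE), c(n_unprod, n_single))
      ex
    } else NULL
  })
  rec <- bind_rows(rec, extra)
  repertoire_sample(rec, sample_id = sample_id, patient_id = patient_id,
                    cohort = cohort, timepoint_days = timepoint_days,
                    key = cfg$key %||% "nt_vj")
}

#' Simulate one patient's longitudinal sample series
#'
#' Generates the full five-compartment series for a patient: a baseline
#' PBMC repertoire from the clone-size law, an infusion product sharing a
#' fraction `theta` of baseline clonotypes, post-infusion repertoires
#' mixing product frequencies (weight `w`, waning over time) with
#' surviving baseline and novel clones, cfDNA as a sparse skewed
#' resampling of the DNA frequencies, RNA as DNA frequencies modulated by
#' per-clone lognormal expression, and multinomial read noise plus
#' unproductive/singleton contamination on every sample.
#'
#' @param config A [cohort_config()].
#' @param patient_seed Integer seed for this patient; all of the
#'   patient's draws are keyed off `(config$seed, patient_seed)`.
#' @param patient_id Identifier (defaults to `"SIM<patient_seed>"`).
#' @param responder Logical: apply the responder effect multipliers.
#' @return A list with `series` (a [patient_series()]; response `"PR"`
#'   for responders, `"SD"` otherwise) and `truth`, the ground-truth
#'   record: realized `theta` and `w`, the shared / product / novel key
#'   sets, per-key provenance labels, and the planted expanded head keys.
#' @export
simulate_patient <- function(config, patient_seed,
                             patient_id = paste0("SIM", patient_seed),
                             responder = FALSE) {
  cfg <- config
  base_seed <- derive_seed(cfg$seed, patient_seed)
  theta <- min(1, cfg$theta * if (responder) cfg$responder_theta_mult else 1)
  w <- min(1, cfg$w * if (responder) cfg$responder_w_mult else 1)
  cl_mult <- if (responder) cfg$responder_clonality_mult else 1

  S_b <- cfg$baseline_richness
  S_p <- cfg$infusion_richness
  n_shared <- round(theta * S_b)
  if (n_shared > S_p) {
    abort("infeasible config: shared clonotypes exceed product richness",
          class = "tilrep_config_error")
  }
  S_novel <- round(cfg$influx * S_b)

  pool_n <- S_b + S_p + S_novel + 4000L
  pool <- gen_cdr3_pool(pool_n, derive_seed(base_seed, 101))
  counter_env <- new.env()
  counter_env$next_free <- S_b + S_p + S_novel + 1L
  spare <- function(k) {
    i <- counter_env$next_free
    if (i + k - 1L > pool_n) abort("clonotype pool exhausted")
    counter_env$next_free <- i + k
    seq.int(i, i + k - 1L)
  }

  base_idx <- seq_len(S_b)
  # product = shared baseline keys + its own private keys
  shared_idx <- withr::with_seed(derive_seed(base_seed, 102),
                                 sort(sample(base_idx, n_shared)))
  prod_private <- seq.int(S_b + 1L, S_b + (S_p - n_shared))
  prod_idx <- c(shared_idx, prod_private)
  novel_idx <- if (S_novel > 0) {
    seq.int(S_b + S_p - n_shared + 1L, S_b + S_p - n_shared + S_novel)
  } else integer()

  f_base <- clone_frequencies(cfg, S_b, derive_seed(base_seed, 103), cl_mult)
  # random assignment of law ranks to keys
  f_base <- withr::with_seed(derive_seed(base_seed, 104), sample(f_base))
  # Product frequencies follow the clone-size law; the ranks allotted to the
  # shared clonotypes are a random subset, but within it the ordering tracks
  # the baseline frequencies -- the infusion product over-represents the
  # patient's own expanded clones.
  f_law <- clone_frequencies(cfg, S_p, derive_seed(base_seed, 105))
  f_prod <- withr::with_seed(derive_seed(base_seed, 106), {
    shared_ranks <- sort(sample(S_p, n_shared))
    private_ranks <- sample(setdiff(seq_len(S_p), shared_ranks))
    f <- numeric(S_p)  # aligned with prod_idx = c(shared_idx, prod_private)
    f[order(-f_base[shared_idx])] <- f_law[shared_ranks]
    if (n_shared < S_p) {
      f[seq.int(n_shared + 1L, S_p)] <- f_law[private_ranks]
    }
    f
  })
  # Novel reconstitution clones are naive-like background: no antigen-driven
  # expansion, hence similar per-clone sizes (uniform frequencies).
  f_novel <- if (S_novel > 0) rep(1 / S_novel, S_novel) else numeric()

  surv_idx <- withr::with_seed(derive_seed(base_seed, 109),
                               sort(sample(base_idx, round(cfg$survival * S_b))))

  # population frequency vector over the union of keys at a given weight w_t
  post_freqs <- function(w_t) {
    idx <- sort(unique(c(prod_idx, surv_idx, novel_idx)))
    f <- stats::setNames(numeric(length(idx)), idx)
    endo <- stats::setNames(numeric(length(idx)), idx)
    if (length(surv_idx) > 0) {
      endo[as.character(surv_idx)] <- (1 - cfg$influx) *
        f_base[surv_idx] / sum(f_base[surv_idx])
    }
    if (S_novel > 0) {
      endo[as.character(novel_idx)] <- endo[as.character(novel_idx)] +
        cfg$influx * f_novel
    }
    f[as.character(prod_idx)] <- w_t * f_prod
    if (sum(endo) > 0) f <- f + (1 - w_t) * endo / sum(endo)
    keep <- f > 0
    list(idx = idx[keep], freqs = f[keep] / sum(f[keep]))
  }

  cfdna_freqs <- function(idx, freqs, seed) {
    S_cf <- max(5L, round(cfg$cfdna_sparsity * length(idx)))
    q <- freqs^cfg$cfdna_skew
    keep <- withr::with_seed(seed, {
      sample(seq_along(idx), min(S_cf, length(idx)), prob = q)
    })
    list(idx = idx[keep], freqs = q[keep] / sum(q[keep]))
  }

  rna_freqs <- function(freqs, seed) {
    mult <- withr::with_seed(seed, stats::rlnorm(length(freqs), 0, cfg$rna_sdlog))
    f <- freqs * mult
    f / sum(f)
  }

  samples <- list()
  add <- function(s) samples[[length(samples) + 1]] <<- s
  sid <- function(cohort, day) sprintf("%s_%s_d%+04d", patient_id, cohort, day)

  # baseline (day -14): PBMC DNA, PBMC RNA, cfDNA
  day0 <- -14L
  add(make_sample(pool, spare, base_idx, f_base, cfg$depths[["PBMC_DNA"]], cfg,
                  sid("PBMC_DNA", day0), patient_id, "PBMC_DNA", day0,
                  derive_seed(base_seed, 201)))
  add(make_sample(pool, spare, base_idx, rna_freqs(f_base, derive_seed(base_seed, 202)),
                  cfg$depths[["PBMC_RNA"]], cfg, sid("PBMC_RNA", day0),
                  patient_id, "PBMC_RNA", day0, derive_seed(base_seed, 203)))
  cf0 <- cfdna_freqs(base_idx, f_base, derive_seed(base_seed, 204))
  add(make_sample(pool, spare, cf0$idx, cf0$freqs, cfg$depths[["CFDNA"]], cfg,
                  sid("CFDNA", day0), patient_id, "CFDNA", day0,
                  derive_seed(base_seed, 205)))

  # infusion product (day 0): DNA and RNA
  add(make_sample(pool, spare, prod_idx, f_prod, cfg$depths[["TIL_DNA"]], cfg,
                  sid("TIL_DNA", 0L), patient_id, "TIL_DNA", 0L,
                  derive_seed(base_seed, 206)))
  add(make_sample(pool, spare, prod_idx, rna_freqs(f_prod, derive_seed(base_seed, 207)),
                  cfg$depths[["TIL_RNA"]], cfg, sid("TIL_RNA", 0L),
                  patient_id, "TIL_RNA", 0L, derive_seed(base_seed, 208)))

  # post-infusion draws
  for (k in seq_along(cfg$post_timepoints)) {
    day <- as.integer(cfg$post_timepoints[k])
    w_t <- w * cfg$w_decay^(k - 1)
    pf <- post_freqs(w_t)
    add(make_sample(pool, spare, pf$idx, pf$freqs, cfg$depths[["PBMC_DNA"]], cfg,
                    sid("PBMC_DNA", day), patient_id, "PBMC_DNA", day,
                    derive_seed(base_seed, 300 + 10 * k + 1)))
    add(make_sample(pool, spare, pf$idx, rna_freqs(pf$freqs,
                                            derive_seed(base_seed, 300 + 10 * k + 2)),
                    cfg$depths[["PBMC_RNA"]], cfg, sid("PBMC_RNA", day),
                    patient_id, "PBMC_RNA", day,
                    derive_seed(base_seed, 300 + 10 * k + 3)))
    if (k == 1) {
      cfp <- cfdna_freqs(pf$idx, pf$freqs, derive_seed(base_seed, 300 + 10 * k + 4))
      add(make_sample(pool, spare, cfp$idx, cfp$freqs, cfg$depths[["CFDNA"]], cfg,
                      sid("CFDNA", day), patient_id, "CFDNA", day,
                      derive_seed(base_seed, 300 + 10 * k + 5)))
    }
  }

  key_of <- function(idx) clonotype_key(pool[idx, , drop = FALSE],
                                        cfg$key %||% "nt_vj")
  provenance <- tibble(
    key = key_of(c(base_idx, prod_private, novel_idx)),
    label = rep(c("baseline", "product_private", "novel"),
                c(S_b, length(prod_private), length(novel_idx)))
  )
  provenance$label[provenance$key %in% key_of(surv_idx)] <- "baseline_survivor"

  series <- patient_series(patient_id, if (responder) "PR" else "SD", samples)
  truth <- list(
    patient_id = patient_id, responder = responder,
    theta = theta, w = w,
    shared_keys = key_of(shared_idx),
    product_keys = key_of(prod_idx),
    novel_keys = key_of(novel_idx),
    survivor_keys = key_of(surv_idx),
    planted_expanded_baseline =
      key_of(base_idx[order(-f_base)][seq_len(min(cfg$n_expanded, S_b))]),
    provenance = provenance
  )
  list(series = series, truth = truth)
}

#' Simulate a full cohort
#'
#' Simulates `n_patients` patients with per-patient seeds derived from
#' the master seed (so adding a patient never perturbs existing ones) and
#' optionally writes AIRR Rearrangement TSVs, a sample manifest and the
#' ground-truth JSON to a directory. Responders are the first
#' `round(n_patients * responder_fraction)` patients.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory; created if needed.
#' @return A list with `patients` (list of `patient_series`), `truth`
#'   (list of per-patient ground truth), and `manifest` (tibble; `path`
#'   and `format` columns populated when files were written).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  n <- config$n_patients
  n_resp <- round(n * config$responder_fraction)
  patients <- vector("list", n)
  truths <- vector("list", n)
  man_rows <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n) ) {
    pid <- sprintf("SIM%02d", i)
    sim <- simulate_patient(config, patient_seed = i, patient_id = pid,
                            responder = i <= n_resp)
    patients[[i]] <- sim$series
    truths[[i]] <- sim$truth
    for (s in sim$series$samples) {
      fname <- paste0(s$sample_id, ".tsv")
      if (!is.null(out_dir)) write_airr(s, file.path(out_dir, fname))
      man_rows[[length(man_rows) + 1]] <- tibble(
        path = fname, format = "airr", patient_id = pid,
        cohort = s$cohort, timepoint_days = s$timepoint_days,
        response = sim$series$response
      )
    }
  }
  manifest <- bind_rows(man_rows)
  if (!is.null(out_dir)) {
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                     progress = FALSE)
    truth_json <- lapply(truths, function(t) {
      t$provenance <- NULL  # bulky; key sets carry the usable truth
      t
    })
    jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  names(truths) <- vapply(patients, function(p) p$patient_id, character(1))
  list(patients = patients, truth = truths, manifest = manifest)
}
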