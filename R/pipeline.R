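#' Default analysis configuration
#'
#' Every tunable of the analysis in one list: the clonotype identity key,
#' locus and filtering switches, the Morisita variant, correlation scope
#' and transform, change-point transform and penalty, relative-risk
#' zero-cell handling, and saturation-QC settings. A YAML file with any
#' subset of these fields can be merged over the defaults with
#' [read_config()].
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    key = "nt_vj",
    locus = "TRB",
    drop_unproductive = TRUE,
    drop_singletons = TRUE,
    morisita_variant = "horn",
    r2_scope = "intersection",
    r2_transform = "linear",
    til_definition = "product_only",
    changepoint_transform = "raw",
    changepoint_penalty = "BIC",
    changepoint_min_segment = 2L,
    rr_correction = "none",
    saturation_run = TRUE,
    saturation_replicates = 3L,
    saturation_epsilon = 1e-4,
    seed = 1L
  )
}

#' Merge a YAML config file over the defaults
#' @param path YAML file with any subset of [default_config()]'s fields.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "tilrep_config_error")
  }
  utils::modifyList(cfg, user)
}

#' One-way ANOVA with Tukey HSD on (optionally log10) values
#'
#' Used for the sample-cohort diversity comparison: a one-way ANOVA on
#' log10-transformed values with Tukey's HSD pairwise adjusted p-values.
#' Groups with fewer than 2 values are excluded with a warning; with
#' fewer than 2 usable groups, or no within-group variance at all, a
#' sentinel result is returned instead of a crash.
#'
#' @param values Numeric vector (strictly positive in log10 mode).
#' @param groups Group labels, same length.
#' @param log10_transform Apply log10 first (default `TRUE`).
#' @return List with `F`, `p`, `tukey` (tibble `comparison`, `diff`,
#'   `p_adj`) and `reason` (`"ok"` or why the result is a sentinel with
#'   `F`/`p` = `NA`).
#' @export
compare_groups_anova <- function(values, groups, log10_transform = TRUE) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups[keep])
  sentinel <- function(reason) list(F = NA_real_, p = NA_real_, tukey = NULL,
                                    reason = reason)
  if (log10_transform) {
    if (any(values <= 0)) return(sentinel("nonpositive_values_in_log_mode"))
    values <- log10(values)
  }
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding group(s) with < 2 values: ",
                paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) return(sentinel("fewer_than_two_groups"))
  if (stats::var(values) < 1e-24) {
    # identical values everywhere: no between- or within-group variation
    return(list(F = 0, p = 1, tukey = NULL, reason = "ok"))
  }
  within_var <- stats::ave(values, groups, FUN = stats::var)
  if (all(within_var < 1e-12)) return(sentinel("degenerate_within_group_variance"))
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = factor(groups)))
  an <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$g
  list(
    F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
    tukey = tibble(comparison = rownames(hsd), diff = hsd[, "diff"],
                   p_adj = hsd[, "p adj"]),
    reason = "ok"
  )
}

#' Median and range of a statistic by response group
#'
#' Descriptive per-group summary (median, min, max, n) in the reporting
#' style used for small ACT cohorts -- no hypothesis test attached.
#'
#' @param values Numeric vector (one per patient).
#' @param responder Logical vector, same length.
#' @param statistic Label for the output rows.
#' @return Tibble with one row per group.
#' @export
summarize_by_response <- function(values, responder, statistic = "statistic") {
  stopifnot(length(values) == length(responder))
  keep <- !is.na(values) & !is.na(responder)
  tibble(value = values[keep],
         group = ifelse(responder[keep], "responder", "non_responder")) |>
    group_by(.data$group) |>
    summarise(statistic = statistic, n = n(),
              median = stats::median(.data$value),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop") |>
    select("statistic", "group", "n", "median", "min", "max")
}

load_manifest_samples <- function(manifest, config) {
  results <- list()
  quarantine <- list(tibble(path = character(), stage = character(),
                            reason = character()))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    s <- tryCatch(
      read_clonotype_table(row$path, format = row$format,
                           patient_id = row$patient_id, cohort = row$cohort,
                           timepoint_days = row$timepoint_days,
                           key = config$key),
      error = function(e) e
    )
    if (inherits(s, "error")) {
      quarantine[[length(quarantine) + 1]] <- tibble(
        path = row$path, stage = "read", reason = conditionMessage(s))
      next
    }
    f <- tryCatch(
      filter_repertoire(s, locus = config$locus,
                        drop_unproductive = config$drop_unproductive,
                        drop_singletons = config$drop_singletons),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      quarantine[[length(quarantine) + 1]] <- tibble(
        path = row$path, stage = "filter", reason = conditionMessage(f))
      next
    }
    results[[length(results) + 1]] <- list(sample = f$sample,
                                           report = f$report,
                                           response = row$response)
  }
  list(results = results, quarantine = bind_rows(quarantine))
}

#' Run the full repertoire-tracking analysis on a manifest
#'
#' Executes, per patient: parsing and filtering, saturation QC, diversity
#' profiling, all-pairs overlap, TIL tracking, expanded-clone
#' classification of DNA repertoires, and relative-risk analysis; then a
#' cohort-level summary by response group. Per-sample failures are
#' quarantined with a reason code and the pipeline completes on the
#' remaining samples. All outputs are CSV tables plus a JSON run log of
#' the settings used; figures are advisory extras.
#'
#' @param manifest A manifest TSV path or a tibble as returned by
#'   [read_manifest()] / [simulate_cohort()].
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Also write PNG figures (overlap heatmap, tracking bars,
#'   diversity timelines). Default `FALSE`.
#' @return `out_dir`, invisibly. Side effect: writes `diversity.csv`,
#'   `filter_reports.csv`, `saturation.csv`, `overlap_matrix.csv`,
#'   `overlap_pairs.csv`, `patient_mean_overlap.csv`, `til_summary.csv`,
#'   `tracking.csv`, `expansion.csv`, `expansion_clonotypes.csv`,
#'   `risk.csv`, `cohort_summary.csv`, `anova_diversity.csv`,
#'   `quarantine.csv`, `run_log.json`.
#' @export
run_pipeline <- function(manifest, config = default_config(), out_dir,
                         figures = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(x, name) readr::write_csv(x, file.path(out_dir, name),
                                             progress = FALSE)

  loaded <- load_manifest_samples(manifest, config)
  samples <- lapply(loaded$results, `[[`, "sample")
  reports <- bind_rows(lapply(loaded$results, `[[`, "report"))
  wcsv(reports, "filter_reports.csv")
  quarantine <- loaded$quarantine
  if (length(samples) == 0) {
    abort("no samples survived loading", class = "tilrep_empty_sample_error")
  }

  # patient series
  resp_by_patient <- manifest |> distinct(.data$patient_id, .data$response)
  patients <- lapply(seq_len(nrow(resp_by_patient)), function(i) {
    pid <- resp_by_patient$patient_id[i]
    ss <- samples[vapply(samples, function(s) s$patient_id == pid, logical(1))]
    if (length(ss) == 0) return(NULL)
    patient_series(pid, resp_by_patient$response[i], ss)
  })
  patients <- patients[!vapply(patients, is.null, logical(1))]

  # saturation QC
  if (isTRUE(config$saturation_run)) {
    sat <- bind_rows(lapply(samples, function(s) {
      sc <- fit_saturation(
        saturation_curve(s, replicates = config$saturation_replicates,
                         seed = derive_seed(config$seed, s$sample_id)),
        epsilon = config$saturation_epsilon
      )
      tibble(sample_id = s$sample_id, derivative = sc$fit$derivative,
             ci_low = sc$fit$ci_low, ci_high = sc$fit$ci_high,
             epsilon = sc$fit$epsilon, saturated = sc$fit$saturated,
             rule = sc$fit$rule)
    }))
    wcsv(sat, "saturation.csv")
  }

  # diversity
  diversity <- bind_rows(lapply(patients, function(p) {
    bind_rows(lapply(.tilrep_cohorts, function(co) {
      suppressWarnings(diversity_timeline(p, co))
    }))
  }))
  wcsv(diversity, "diversity.csv")

  # cohort-level ANOVA on log10 inverse Simpson across compartment types
  compartment <- dplyr::case_when(
    diversity$cohort %in% c("PBMC_DNA", "TIL_DNA") ~ "DNA",
    diversity$cohort %in% c("PBMC_RNA", "TIL_RNA") ~ "RNA",
    TRUE ~ "cfDNA"
  )
  an <- compare_groups_anova(diversity$inv_simpson, compartment)
  an_tab <- tibble(F = an$F, p = an$p, reason = an$reason)
  wcsv(an_tab, "anova_diversity.csv")
  if (!is.null(an$tukey)) wcsv(an$tukey, "anova_diversity_tukey.csv")

  # overlap
  om <- overlap_matrix(samples, variant = config$morisita_variant)
  mat_out <- as_tibble(om$matrix, rownames = "sample_id")
  wcsv(mat_out, "overlap_matrix.csv")
  wcsv(om$patient_means, "patient_mean_overlap.csv")

  meta <- tibble(
    idx = seq_along(samples),
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    patient_id = vapply(samples, function(s) s$patient_id, character(1)),
    cohort = vapply(samples, function(s) s$cohort, character(1)),
    timepoint_days = vapply(samples, function(s) s$timepoint_days, integer(1))
  )
  pair_rows <- list()
  for (i in seq_len(nrow(meta) - 1)) {
    for (j in seq.int(i + 1, nrow(meta))) {
      if (meta$patient_id[i] != meta$patient_id[j]) next
      pair_rows[[length(pair_rows) + 1]] <- tibble(
        sample_a = meta$sample_id[i], sample_b = meta$sample_id[j],
        patient_id = meta$patient_id[i],
        morisita = om$matrix[i, j],
        r2 = cross_cohort_r2(samples[[i]], samples[[j]],
                             scope = config$r2_scope,
                             transform = config$r2_transform)
      )
    }
  }
  wcsv(bind_rows(pair_rows), "overlap_pairs.csv")

  # tracking + expansion + risk
  til_rows <- list(); track_rows <- list()
  exp_rows <- list(); exp_clone_rows <- list(); risk_rows <- list()
  for (p in patients) {
    has_product <- !is.null(infusion_product(p))
    if (has_product) {
      til_rows[[length(til_rows) + 1]] <- til_summary(p)
      til <- til_clonotype_set(p, config$til_definition)
    } else {
      quarantine <- bind_rows(quarantine, tibble(
        path = p$patient_id, stage = "tracking",
        reason = "no TIL_DNA infusion product"))
      til <- NULL
    }
    for (co in c("PBMC_DNA", "CFDNA")) {
      if (length(cohort_samples(p, co)) == 0) next
      tt <- tracking_table(p, co, til)
      tt$patient_id <- p$patient_id
      tt$cohort <- co
      track_rows[[length(track_rows) + 1]] <- tt
    }
    for (s in p$samples) {
      if (!s$cohort %in% c("PBMC_DNA", "TIL_DNA")) next
      ex <- classify_expanded(s, transform = config$changepoint_transform,
                              penalty = config$changepoint_penalty,
                              min_segment = config$changepoint_min_segment)
      exp_rows[[length(exp_rows) + 1]] <- tibble(
        patient_id = p$patient_id, sample_id = s$sample_id, cohort = s$cohort,
        timepoint_days = s$timepoint_days, tau = ex$tau,
        threshold_count = ex$threshold_count,
        threshold_fraction = ex$threshold_fraction,
        expanded_abundance = ex$expanded_abundance,
        loglik_gain = ex$loglik_gain, penalty_used = ex$penalty_used,
        reason = ex$reason)
      exp_clone_rows[[length(exp_clone_rows) + 1]] <- tibble(
        sample_id = s$sample_id, key = s$records$key,
        expanded = s$records$key %in% ex$expanded_keys)
    }
    risk_rows[[length(risk_rows) + 1]] <- patient_risk_profile(
      p, correction = config$rr_correction,
      transform = config$changepoint_transform,
      penalty = config$changepoint_penalty,
      min_segment = config$changepoint_min_segment)
  }
  til_tab <- bind_rows(til_rows)
  wcsv(til_tab, "til_summary.csv")
  wcsv(bind_rows(track_rows), "tracking.csv")
  exp_tab <- bind_rows(exp_rows)
  wcsv(exp_tab, "expansion.csv")
  wcsv(bind_rows(exp_clone_rows), "expansion_clonotypes.csv")
  risk_tab <- bind_rows(risk_rows)
  wcsv(risk_tab, "risk.csv")

  # cohort summary by response group
  summary_rows <- list()
  add_stat <- function(values, responder, label) {
    summary_rows[[length(summary_rows) + 1]] <<-
      summarize_by_response(values, responder, label)
  }
  if (nrow(til_tab) > 0) {
    t1 <- til_tab |> filter(.data$definition == "product_only")
    add_stat(t1$baseline_til_abundance, t1$responder, "baseline_til_abundance")
    add_stat(t1$first_post_til_abundance, t1$responder,
             "first_post_til_abundance")
    add_stat(t1$persistence_abundance, t1$responder, "persistence_abundance")
  }
  pm <- om$patient_means |>
    filter(.data$cohort == "PBMC_DNA") |>
    left_join(resp_by_patient, by = "patient_id")
  if (nrow(pm) > 0) {
    add_stat(pm$mean_morisita, pm$response == "PR", "mean_morisita_pbmc_dna")
  }
  div_base <- diversity |>
    filter(.data$cohort == "PBMC_DNA", .data$timepoint_days <= 0) |>
    group_by(.data$patient_id) |>
    slice_max(.data$timepoint_days, n = 1) |>
    ungroup() |>
    left_join(resp_by_patient, by = "patient_id")
  if (nrow(div_base) > 0) {
    add_stat(div_base$clonality, div_base$response == "PR",
             "baseline_clonality_pbmc_dna")
    add_stat(div_base$frac_large + div_base$frac_hyper,
             div_base$response == "PR", "baseline_large_hyper_abundance")
  }
  exp_base <- exp_tab |>
    filter(.data$cohort == "PBMC_DNA", .data$timepoint_days <= 0) |>
    left_join(resp_by_patient, by = "patient_id")
  if (nrow(exp_base) > 0) {
    add_stat(exp_base$expanded_abundance, exp_base$response == "PR",
             "baseline_expanded_abundance")
  }
  for (ref in unique(risk_tab$reference)) {
    rt <- risk_tab |>
      filter(.data$reference == ref, .data$status == "ok") |>
      left_join(resp_by_patient, by = "patient_id")
    if (nrow(rt) > 0) {
      add_stat(rt$rr, rt$response == "PR", paste0("rr_", ref))
    }
  }
  wcsv(bind_rows(summary_rows), "cohort_summary.csv")
  wcsv(quarantine, "quarantine.csv")

  run_log <- list(
    package = "tilrep",
    version = as.character(utils::packageVersion("tilrep")),
    config = config,
    n_manifest = nrow(manifest),
    n_analysed = length(samples),
    n_quarantined = nrow(quarantine)
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(figures)) {
    write_figures(out_dir, om, bind_rows(track_rows), diversity)
  }
  invisible(out_dir)
}
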