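#' Bundle a patient's samples into a longitudinal series
#'
#' @param patient_id Identifier string.
#' @param response RECIST-style response: `"PR"`, `"SD"` or `"PD"`.
#'   Patients with `PR` are responders; `SD`/`PD` are non-responders.
#' @param samples List of `repertoire_sample` objects across compartments
#'   and timepoints.
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, response, samples) {
  if (!response %in% .tilrep_responses) {
    abort(paste0("unknown response '", response, "'"),
          class = "tilrep_argument_error")
  }
  for (co in .tilrep_cohorts) {
    tps <- vapply(samples, function(s) {
      if (identical(s$cohort, co)) s$timepoint_days else NA_integer_
    }, integer(1))
    tps <- tps[!is.na(tps)]
    if (anyDuplicated(tps)) {
      abort(paste0("duplicate timepoints within cohort ", co,
                   " for patient ", patient_id),
            class = "tilrep_argument_error")
    }
  }
  structure(
    list(patient_id = patient_id, response = response,
         responder = response == "PR", samples = samples),
    class = "patient_series"
  )
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> %s  response=%s (%s)  %d samples\n",
              x$patient_id, x$response,
              if (x$responder) "responder" else "non-responder",
              length(x$samples)))
  invisible(x)
}

#' Samples of one compartment, ordered by timepoint
#' @param patient A `patient_series`.
#' @param cohort Compartment name.
#' @return List of `repertoire_sample`, sorted by `timepoint_days`.
#' @export
cohort_samples <- function(patient, cohort) {
  keep <- vapply(patient$samples, function(s) identical(s$cohort, cohort),
                 logical(1))
  out <- patient$samples[keep]
  tps <- vapply(out, function(s) s$timepoint_days, integer(1))
  out[order(tps)]
}

#' Baseline sample of a compartment: largest non-positive timepoint
#' @inheritParams cohort_samples
#' @return A `repertoire_sample` or `NULL` when absent.
#' @export
baseline_sample <- function(patient, cohort) {
  ss <- cohort_samples(patient, cohort)
  tps <- vapply(ss, function(s) s$timepoint_days, integer(1))
  pre <- which(tps <= 0)
  if (length(pre) == 0) return(NULL)
  ss[[max(pre)]]
}

#' First post-infusion sample: smallest strictly positive timepoint
#' @inheritParams cohort_samples
#' @return A `repertoire_sample` or `NULL` when absent.
#' @export
first_post_sample <- function(patient, cohort) {
  ss <- cohort_samples(patient, cohort)
  tps <- vapply(ss, function(s) s$timepoint_days, integer(1))
  post <- which(tps > 0)
  if (length(post) == 0) return(NULL)
  ss[[min(post)]]
}

#' Infusion-product reference sample (DNA by default)
#' @param patient A `patient_series`.
#' @param product_cohort `"TIL_DNA"` (default) or `"TIL_RNA"`.
#' @return A `repertoire_sample` or `NULL`.
#' @export
infusion_product <- function(patient, product_cohort = "TIL_DNA") {
  ss <- cohort_samples(patient, product_cohort)
  if (length(ss) == 0) return(NULL)
  ss[[1]]
}

#' TIL clonotype set for a patient
#'
#' TIL clonotypes are those observed in the TIL infusion product. The
#' stricter definition additionally requires presence in at least one
#' PBMC sample (DNA or RNA, any timepoint), so it is always a subset of
#' the product-only set.
#'
#' @param patient A `patient_series` with a TIL infusion-product sample.
#' @param definition `"product_only"` or `"product_and_pbmc"`.
#' @param product_cohort Which product to use as the reference, default
#'   `"TIL_DNA"`.
#' @return A list of class `til_set` with `keys` (character vector) and
#'   `definition`.
#' @export
til_clonotype_set <- function(patient,
                              definition = c("product_only", "product_and_pbmc"),
                              product_cohort = "TIL_DNA") {
  definition <- match.arg(definition)
  product <- infusion_product(patient, product_cohort)
  if (is.null(product)) {
    abort(paste0("patient ", patient$patient_id, " has no ", product_cohort,
                 " infusion-product sample"),
          class = "tilrep_missing_product_error")
  }
  keys <- product$records$key
  if (definition == "product_and_pbmc") {
    pbmc <- c(cohort_samples(patient, "PBMC_DNA"),
              cohort_samples(patient, "PBMC_RNA"))
    pbmc_keys <- unique(unlist(lapply(pbmc, function(s) s$records$key)))
    keys <- intersect(keys, pbmc_keys)
  }
  structure(list(keys = keys, definition = definition), class = "til_set")
}

#' TIL abundance of a sample
#'
#' The proportion of the repertoire occupied by TIL clonotypes: summed
#' relative abundance over the clonotypes shared between the sample and
#' the TIL set.
#'
#' @param sample A `repertoire_sample`.
#' @param til A `til_set` or a character vector of clonotype keys.
#' @return Numeric in \[0, 1\].
#' @export
til_abundance <- function(sample, til) {
  keys <- if (inherits(til, "til_set")) til$keys else til
  p <- rel_abundance(sample)
  sum(p[names(p) %in% keys])
}

#' Persistence of reference clonotypes in a post-infusion sample
#'
#' In `"abundance"` mode, the share of the post-infusion repertoire held
#' by clonotypes present in the reference sample (the classical
#' persistence statistic). In `"clonotype_fraction"` mode, the fraction
#' of the post sample's clonotypes (optionally restricted to a label set
#' such as the expanded clones) that are present in the reference.
#'
#' @param post,reference Non-empty `repertoire_sample` objects.
#' @param mode `"abundance"` (default) or `"clonotype_fraction"`.
#' @param restrict_to Optional character vector of keys; the post sample's
#'   clonotypes are first intersected with it (clonotype_fraction mode).
#' @return Numeric in \[0, 1\], or `NA_real_` when `restrict_to` is
#'   disjoint from the post sample.
#' @export
persistence <- function(post, reference,
                        mode = c("abundance", "clonotype_fraction"),
                        restrict_to = NULL) {
  mode <- match.arg(mode)
  if (richness(post) == 0 || richness(reference) == 0) {
    abort("both samples must be non-empty", class = "tilrep_empty_sample_error")
  }
  ref_keys <- reference$records$key
  if (mode == "abundance") {
    p <- rel_abundance(post)
    return(sum(p[names(p) %in% ref_keys]))
  }
  post_keys <- post$records$key
  if (!is.null(restrict_to)) post_keys <- intersect(post_keys, restrict_to)
  if (length(post_keys) == 0) return(NA_real_)
  length(intersect(post_keys, ref_keys)) / length(post_keys)
}

#' Longitudinal clonotype tracking table
#'
#' Long-format table of every clonotype ever observed in a patient's
#' series within one compartment, with explicit zero rows where a
#' clonotype is absent at a timepoint -- the input for stacked-bar
#' tracking plots and for differencing.
#'
#' @param patient A `patient_series`.
#' @param cohort Compartment name.
#' @param til Optional `til_set` (or key vector) used to set the `is_til`
#'   flag.
#' @return Tibble with `timepoint_days`, `key`, `abundance` (relative,
#'   summing to 1 within each timepoint), `is_til`.
#' @export
tracking_table <- function(patient, cohort, til = NULL) {
  samples <- cohort_samples(patient, cohort)
  if (length(samples) == 0) {
    abort(paste0("patient ", patient$patient_id, " has no samples in ", cohort),
          class = "tilrep_argument_error")
  }
  long <- bind_rows(lapply(samples, function(s) {
    tibble(timepoint_days = s$timepoint_days, key = s$records$key,
           abundance = s$records$count / sum(s$records$count))
  }))
  til_keys <- if (inherits(til, "til_set")) til$keys else til %||% character()
  grid <- tidyr::expand_grid(timepoint_days = unique(long$timepoint_days),
                             key = unique(long$key))
  grid |>
    left_join(long, by = c("timepoint_days", "key")) |>
    mutate(abundance = ifelse(is.na(.data$abundance), 0, .data$abundance),
           is_til = .data$key %in% til_keys) |>
    arrange(.data$timepoint_days, desc(.data$abundance), .data$key)
}

#' Per-patient TIL tracking summary
#'
#' Convenience summary used by the pipeline: baseline and first
#' post-infusion TIL abundance and persistence in both modes for one
#' compartment, for each TIL-set definition.
#'
#' @param patient A `patient_series` with a TIL_DNA product sample.
#' @param cohort Compartment to summarise, default `"PBMC_DNA"`.
#' @return Tibble with one row per TIL-set definition.
#' @export
til_summary <- function(patient, cohort = "PBMC_DNA") {
  base <- baseline_sample(patient, cohort)
  post <- first_post_sample(patient, cohort)
  product <- infusion_product(patient)
  rows <- lapply(c("product_only", "product_and_pbmc"), function(def) {
    til <- til_clonotype_set(patient, def)
    tibble(
      patient_id = patient$patient_id, response = patient$response,
      responder = patient$responder, cohort = cohort, definition = def,
      baseline_til_abundance =
        if (is.null(base)) NA_real_ else til_abundance(base, til),
      first_post_til_abundance =
        if (is.null(post)) NA_real_ else til_abundance(post, til),
      persistence_abundance =
        if (is.null(post) || is.null(product)) NA_real_ else
          persistence(post, product, "abundance"),
      persistence_clonotype_fraction =
        if (is.null(post) || is.null(product)) NA_real_ else
          persistence(post, product, "clonotype_fraction")
    )
  })
  bind_rows(rows)
}
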