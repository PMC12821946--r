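#' Per-sample diversity statistics
#'
#' Computes the full set of repertoire diversity statistics from clone
#' counts: Simpson's index \eqn{\lambda = \sum_i (n_i/N)^2}, inverse
#' Simpson \eqn{1/\lambda}, Shannon's index
#' \eqn{H = -\sum_i (n_i/N)\ln(n_i/N)} (natural log throughout), richness
#' \eqn{S}, Shannon evenness \eqn{SEI = H/\ln S}, clonality
#' \eqn{C = 1 - SEI}, and the abundance fractions held by large
#' (1--5\% of the repertoire) and hyperexpanded (>5\%) clonotypes.
#'
#' For a single-clonotype repertoire \eqn{\ln S = 0}; the evenness is
#' defined as 0 and clonality as 1 (a one-clone repertoire is maximally
#' clonal), avoiding 0/0.
#'
#' @param sample A `repertoire_sample` (already filtered), or a bare
#'   numeric vector of clone counts.
#' @return One-row tibble with columns `richness`, `simpson_lambda`,
#'   `inv_simpson`, `shannon`, `evenness`, `clonality`, `frac_large`,
#'   `frac_hyper`.
#' @examples
#' diversity_profile(c(5, 3, 2))
#' @export
diversity_profile <- function(sample) {
  n <- if (inherits(sample, "repertoire_sample")) sample$records$count else sample
  n <- n[n > 0]
  if (length(n) == 0) {
    abort("empty sample: no clonotypes with positive count",
          class = "tilrep_empty_sample_error")
  }
  N <- sum(n)
  p <- n / N
  S <- length(n)
  lambda <- sum(p^2)
  H <- -sum(p * log(p))
  sei <- if (S == 1L) 0 else H / log(S)
  cls <- size_class_fractions(n)
  tibble(
    richness = S, simpson_lambda = lambda, inv_simpson = 1 / lambda,
    shannon = H, evenness = sei, clonality = 1 - sei,
    frac_large = cls$frac_large, frac_hyper = cls$frac_hyper
  )
}

#' Abundance held by large and hyperexpanded clonotypes
#'
#' Size classes are half-open on the left so they partition (1%, 100%]:
#' large clones occupy (1\%, 5\%] of the repertoire and hyperexpanded
#' clones (>5\%]. Returned values are abundance-weighted (summed relative
#' abundance of member clonotypes); set `weighted = FALSE` for the
#' fraction of clonotypes instead.
#'
#' @param sample A `repertoire_sample` or numeric count vector.
#' @param weighted Abundance-weighted (default) or clonotype-count based.
#' @return One-row tibble with `frac_large` and `frac_hyper`.
#' @export
size_class_fractions <- function(sample, weighted = TRUE) {
  n <- if (inherits(sample, "repertoire_sample")) sample$records$count else sample
  n <- n[n > 0]
  if (length(n) == 0) {
    abort("empty sample", class = "tilrep_empty_sample_error")
  }
  p <- n / sum(n)
  hyper <- p > 0.05
  large <- p > 0.01 & p <= 0.05
  if (weighted) {
    tibble(frac_large = sum(p[large]), frac_hyper = sum(p[hyper]))
  } else {
    tibble(frac_large = mean(large), frac_hyper = mean(hyper))
  }
}

#' Longitudinal diversity table for one patient
#'
#' @param patient A `patient_series` (see [patient_series()]).
#' @param cohort Compartment to profile, e.g. `"PBMC_DNA"`.
#' @return Tibble sorted by timepoint, one row per sample, with
#'   `patient_id`, `cohort`, `sample_id`, `timepoint_days` and all
#'   [diversity_profile()] columns. Empty (with a warning) when the
#'   patient has no samples in the cohort.
#' @export
diversity_timeline <- function(patient, cohort) {
  samples <- cohort_samples(patient, cohort)
  if (length(samples) == 0) {
    warn(paste0("patient ", patient$patient_id, " has no samples in cohort ",
                cohort))
    return(tibble(patient_id = character(), cohort = character(),
                  sample_id = character(), timepoint_days = integer()))
  }
  rows <- lapply(samples, function(s) {
    bind_cols(
      tibble(patient_id = patient$patient_id, cohort = cohort,
             sample_id = s$sample_id, timepoint_days = s$timepoint_days),
      diversity_profile(s)
    )
  })
  bind_rows(rows) |> arrange(.data$timepoint_days)
}
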