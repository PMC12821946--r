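#' Expansion-by-reference contingency table
#'
#' Cross-classifies the target sample's clonotypes (its expanded /
#' background partition from [classify_expanded()]) by presence in a
#' reference sample's key set:
#' A = expanded & present, B = background & present,
#' C = expanded & absent, D = background & absent.
#' The clonotype universe is the target sample's post-filter clonotypes
#' only, so A + C equals the expanded-set size and B + D the
#' background-set size.
#'
#' @param target An `expansion_result` with non-empty expanded and
#'   background sets.
#' @param reference A `repertoire_sample` (or character vector of keys).
#' @return Named integer vector `c(A=, B=, C=, D=)`.
#' @export
expansion_contingency <- function(target, reference) {
  if (length(target$expanded_keys) == 0 || length(target$background_keys) == 0) {
    abort("degenerate partition: empty expanded or background set",
          class = "tilrep_degenerate_table_error")
  }
  ref_keys <- if (inherits(reference, "repertoire_sample")) {
    reference$records$key
  } else reference
  exp_in <- target$expanded_keys %in% ref_keys
  bg_in <- target$background_keys %in% ref_keys
  c(A = sum(exp_in), B = sum(bg_in),
    C = sum(!exp_in), D = sum(!bg_in))
}

#' Relative risk of expansion with 95% confidence interval
#'
#' \deqn{RR = \frac{A/(A+B)}{C/(C+D)}, \quad
#'       SE(\log RR) = \sqrt{\frac{B}{A(A+B)} + \frac{D}{C(C+D)}}}
#' with the 95\% CI \eqn{\exp(\ln RR \pm 1.96\,SE)}. Here the "exposed"
#' group is the clonotypes present in the reference sample, and the event
#' is membership in the expanded set, so A and B are the present
#' clonotypes (expanded / background) and C and D the absent ones.
#'
#' A zero in A or C makes RR or its SE undefined; with
#' `correction = "none"` (default) a sentinel row is returned carrying
#' the raw table, while `"haldane"` adds 0.5 to every cell
#' (flagged `corrected = TRUE`) before computing.
#'
#' @param A,B,C,D Non-negative integers, or `A` may be a named vector
#'   from [expansion_contingency()].
#' @param correction `"none"` or `"haldane"`.
#' @return One-row tibble: `A`, `B`, `C`, `D`, `rr`, `se_log_rr`,
#'   `ci_low`, `ci_high`, `excludes_one`, `corrected`. The `excludes_one`
#'   flag is `TRUE` when the 95\% CI does not contain 1, i.e. presence in
#'   the reference changes the expansion risk.
#' @examples
#' relative_risk(30, 10, 20, 40)
#' @export
relative_risk <- function(A, B = NULL, C = NULL, D = NULL,
                          correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  if (length(A) == 4 && is.null(B)) {
    B <- A[["B"]]; C <- A[["C"]]; D <- A[["D"]]; A <- A[["A"]]
  }
  if (any(c(A, B, C, D) < 0)) {
    abort("cell counts must be non-negative", class = "tilrep_argument_error")
  }
  if (A + B == 0 || C + D == 0) {
    abort("degenerate table: an exposure margin is empty",
          class = "tilrep_degenerate_table_error")
  }
  raw <- c(A = A, B = B, C = C, D = D)
  corrected <- FALSE
  if ((A == 0 || C == 0)) {
    if (correction == "haldane") {
      A <- A + 0.5; B <- B + 0.5; C <- C + 0.5; D <- D + 0.5
      corrected <- TRUE
    } else {
      return(tibble(
        A = raw[["A"]], B = raw[["B"]], C = raw[["C"]], D = raw[["D"]],
        rr = NA_real_, se_log_rr = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, excludes_one = NA, corrected = FALSE
      ))
    }
  }
  rr <- (A / (A + B)) / (C / (C + D))
  se <- sqrt(B / (A * (A + B)) + D / (C * (C + D)))
  ci_low <- exp(log(rr) - 1.96 * se)
  ci_high <- exp(log(rr) + 1.96 * se)
  tibble(
    A = raw[["A"]], B = raw[["B"]], C = raw[["C"]], D = raw[["D"]],
    rr = rr, se_log_rr = se, ci_low = ci_low, ci_high = ci_high,
    excludes_one = ci_low > 1 | ci_high < 1, corrected = corrected
  )
}

#' Relative-risk profile for one patient
#'
#' For the patient's first post-infusion PBMC DNA sample, asks whether
#' presence in (i) the baseline PBMC DNA repertoire and (ii) the DNA TIL
#' infusion product predicts membership in the post-infusion expanded
#' set. Missing references are skipped with a reason code rather than
#' failing the patient.
#'
#' @param patient A `patient_series`.
#' @param target Optional precomputed `expansion_result` for the first
#'   post-infusion PBMC DNA sample; computed with defaults when `NULL`.
#' @param correction Passed to [relative_risk()].
#' @param ... Passed to [classify_expanded()] when `target` is `NULL`.
#' @return Tibble with one row per reference (`"baseline_pbmc_dna"`,
#'   `"til_product"`): the [relative_risk()] columns plus `patient_id`,
#'   `reference`, `status` (`"ok"` or a skip reason).
#' @export
patient_risk_profile <- function(patient, target = NULL,
                                 correction = c("none", "haldane"), ...) {
  correction <- match.arg(correction)
  post <- first_post_sample(patient, "PBMC_DNA")
  skip_all <- function(reason) {
    tibble(patient_id = patient$patient_id,
           reference = c("baseline_pbmc_dna", "til_product"),
           A = NA_integer_, B = NA_integer_, C = NA_integer_, D = NA_integer_,
           rr = NA_real_, se_log_rr = NA_real_, ci_low = NA_real_,
           ci_high = NA_real_, excludes_one = NA, corrected = NA,
           status = reason)
  }
  if (is.null(post)) return(skip_all("no_post_infusion_sample"))
  if (is.null(target)) target <- classify_expanded(post, ...)
  if (target$tau == 0 || length(target$background_keys) == 0) {
    return(skip_all("degenerate_changepoint"))
  }
  refs <- list(baseline_pbmc_dna = baseline_sample(patient, "PBMC_DNA"),
               til_product = infusion_product(patient))
  rows <- lapply(names(refs), function(nm) {
    ref <- refs[[nm]]
    if (is.null(ref)) {
      return(tibble(patient_id = patient$patient_id, reference = nm,
                    A = NA_integer_, B = NA_integer_, C = NA_integer_,
                    D = NA_integer_, rr = NA_real_, se_log_rr = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, excludes_one = NA,
                    corrected = NA, status = "missing_reference"))
    }
    tab <- expansion_contingency(target, ref)
    rr <- relative_risk(tab, correction = correction)
    bind_cols(tibble(patient_id = patient$patient_id, reference = nm),
              rr, tibble(status = "ok"))
  })
  bind_rows(rows)
}
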