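#' Morisita overlap between two repertoires
#'
#' Abundance-weighted similarity of two clonotype tables over the union of
#' their keys. The default is the Morisita--Horn form
#' \deqn{M = \frac{2\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}}
#' with \eqn{p_i = x_i/X}, \eqn{q_i = y_i/Y}: it is 1 for proportionally
#' identical repertoires (in particular for self-comparison), 0 for
#' disjoint ones, and invariant to scaling either sample's counts. The
#' `"literal"` variant instead divides \eqn{2\sum_i x_i y_i} by
#' \eqn{(S_x + S_y) X Y} with \eqn{S} the richness of each sample; it is
#' retained for auditability but does not normalise self-overlap to 1.
#'
#' @param a,b `repertoire_sample` objects sharing a key convention.
#' @param variant `"horn"` (default) or `"literal"`.
#' @return A single numeric overlap value.
#' @export
morisita_overlap <- function(a, b, variant = c("horn", "literal")) {
  variant <- match.arg(variant)
  if (richness(a) == 0 || richness(b) == 0) {
    abort("cannot compute overlap with an empty sample",
          class = "tilrep_empty_sample_error")
  }
  x <- rel_abundance(a)
  y <- rel_abundance(b)
  keys <- union(names(x), names(y))
  p <- ifelse(keys %in% names(x), x[keys], 0)
  q <- ifelse(keys %in% names(y), y[keys], 0)
  if (variant == "horn") {
    2 * sum(p * q) / (sum(p^2) + sum(q^2))
  } else {
    2 * sum(p * q) / (richness(a) + richness(b))
  }
}

#' All-pairs overlap matrix with per-patient per-cohort means
#'
#' Computes the Morisita overlap for every pair of samples (the Fig-2B
#' style heatmap matrix) and, for each patient and compartment, the mean
#' overlap over distinct unordered within-cohort pairs (self-pairs and
#' cross-cohort pairs excluded).
#'
#' @param samples List of `repertoire_sample` objects with sample, patient
#'   and cohort metadata set.
#' @param variant Passed to [morisita_overlap()].
#' @return A list of class `overlap_matrix`: `sample_ids`, `matrix`
#'   (symmetric, unit diagonal for the horn variant), and `patient_means`
#'   (tibble `patient_id`, `cohort`, `n_pairs`, `mean_morisita`).
#' @export
overlap_matrix <- function(samples, variant = c("horn", "literal")) {
  variant <- match.arg(variant)
  if (length(samples) < 2) {
    abort("need at least two samples", class = "tilrep_argument_error")
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    abort("sample ids must be unique", class = "tilrep_argument_error")
  }
  k <- length(samples)
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- morisita_overlap(samples[[i]], samples[[j]], variant)
    }
  }
  if (variant == "literal") {
    diag(m) <- vapply(samples, function(s) morisita_overlap(s, s, "literal"),
                      numeric(1))
  }
  dimnames(m) <- list(ids, ids)

  meta <- tibble(
    idx = seq_len(k), sample_id = ids,
    patient_id = vapply(samples, function(s) s$patient_id, character(1)),
    cohort = vapply(samples, function(s) s$cohort %||% NA_character_, character(1))
  )
  pairs <- meta |>
    inner_join(meta, by = c("patient_id", "cohort"),
               suffix = c("_a", "_b"), relationship = "many-to-many") |>
    filter(.data$idx_a < .data$idx_b)
  pairs$morisita <- m[cbind(pairs$idx_a, pairs$idx_b)]
  patient_means <- pairs |>
    group_by(.data$patient_id, .data$cohort) |>
    summarise(n_pairs = n(), mean_morisita = mean(.data$morisita),
              .groups = "drop")

  structure(list(sample_ids = ids, matrix = m, patient_means = patient_means),
            class = "overlap_matrix")
}

#' Cross-compartment clonotype-abundance correlation (R-squared)
#'
#' Squared Pearson correlation of relative clonotype abundances between
#' two samples (e.g. a cfDNA vs a PBMC DNA repertoire), optionally
#' restricted to a clonotype subset such as the TIL set. With
#' `scope = "intersection"` only shared clonotypes enter; with `"union"`
#' absent clonotypes contribute zero abundance. In `log10` mode
#' abundances are log-transformed, and zeros arising from union scope are
#' excluded first.
#'
#' @param a,b `repertoire_sample` objects.
#' @param subset Optional character vector of clonotype keys to restrict to.
#' @param scope `"intersection"` (default) or `"union"`.
#' @param transform `"linear"` (default) or `"log10"`.
#' @return Squared Pearson correlation, or `NA_real_` when fewer than 3
#'   points remain (or either abundance vector is constant).
#' @export
cross_cohort_r2 <- function(a, b, subset = NULL,
                            scope = c("intersection", "union"),
                            transform = c("linear", "log10")) {
  scope <- match.arg(scope)
  transform <- match.arg(transform)
  x <- rel_abundance(a)
  y <- rel_abundance(b)
  keys <- if (scope == "intersection") {
    intersect(names(x), names(y))
  } else {
    union(names(x), names(y))
  }
  if (!is.null(subset)) keys <- intersect(keys, subset)
  p <- ifelse(keys %in% names(x), x[keys], 0)
  q <- ifelse(keys %in% names(y), y[keys], 0)
  if (transform == "log10") {
    pos <- p > 0 & q > 0
    p <- log10(p[pos])
    q <- log10(q[pos])
  }
  if (length(p) < 3 || stats::sd(p) == 0 || stats::sd(q) == 0) {
    return(NA_real_)
  }
  stats::cor(p, q)^2
}
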