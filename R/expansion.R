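#' Rank-abundance curve of a repertoire
#'
#' Counts sorted in non-increasing order, ties broken deterministically by
#' lexicographic clonotype key, with the rank-to-key mapping retained so a
#' change point on the curve maps back to clonotypes.
#'
#' @param sample A filtered, non-empty `repertoire_sample`.
#' @return A list of class `rank_abundance` with `counts` (non-increasing
#'   integer vector) and `keys` (same order).
#' @export
rank_abundance <- function(sample) {
  rec <- sample$records
  if (nrow(rec) == 0) {
    abort("empty sample", class = "tilrep_empty_sample_error")
  }
  ord <- order(-rec$count, rec$key, method = "radix")
  structure(list(counts = rec$count[ord], keys = rec$key[ord]),
            class = "rank_abundance")
}

# Gaussian segment cost m * log(sigma2_MLE), segment-specific mean. The
# variance is floored at a fraction of the full-sequence variance: clone
# counts are integers, so rank-abundance tails contain long runs of tied
# values whose MLE variance is exactly zero -- an absolute floor near zero
# would make any split isolating such a run look infinitely good. A floor
# relative to the overall variance keeps constant segments finite without
# rewarding them, and keeps the search exactly scale-invariant.
segment_cost <- function(x, var_floor) {
  m <- length(x)
  v <- sum((x - mean(x))^2) / m
  m * log(max(v, var_floor))
}

#' At-most-one-change variance change point
#'
#' Exhaustive single change-point search on a numeric sequence (normally a
#' rank-abundance curve): for every candidate split \eqn{\tau} the cost of
#' modelling the two segments with their own Gaussian mean and variance,
#' \eqn{m\,\ln\hat\sigma^2_{MLE}} per segment, is compared with the
#' unsplit cost. The split minimising the total cost is reported as a
#' change point only when the twice-log-likelihood gain exceeds the
#' penalty (BIC by default); clonotypes at ranks \eqn{1..\tau} are the
#' expanded set, the rest the background.
#'
#' Ties between equal-cost splits go to the smallest \eqn{\tau} (fewest
#' expanded clones). Segment variances are floored at `1e-4` of the
#' full-sequence variance so that runs of tied counts (ubiquitous in
#' rank-abundance tails) cannot act as artificial zero-variance segments;
#' the relative floor keeps the search scale-invariant. A constant
#' sequence, or one shorter than `2 * min_segment`, yields a no-change
#' result with a reason code rather than an error.
#'
#' @param values Numeric sequence (descending for rank-abundance use, but
#'   the search itself does not require monotonicity).
#' @param penalty `"BIC"` (default, \eqn{p \ln n} with `p = 3` extra
#'   parameters for the added mean, variance and location) or `"manual"`.
#' @param manual_penalty Penalty value when `penalty = "manual"`.
#' @param min_segment Minimum points per segment (default 2, the least
#'   that defines a variance).
#' @return A list of class `changepoint_result`: `tau` (0 when no change
#'   point), `loglik_gain`, `penalty_used`, `reason` (`"ok"`,
#'   `"too_short"`, `"constant"`, `"below_penalty"`), and `costs` (the
#'   per-candidate total cost, for audit).
#' @export
amoc_variance_changepoint <- function(values, penalty = c("BIC", "manual"),
                                      manual_penalty = NULL, min_segment = 2L) {
  penalty <- match.arg(penalty)
  n <- length(values)
  pen <- if (penalty == "BIC") 3 * log(n) else {
    if (is.null(manual_penalty)) {
      abort("manual penalty requires manual_penalty", class = "tilrep_argument_error")
    }
    manual_penalty
  }
  no_change <- function(reason) {
    structure(list(tau = 0L, loglik_gain = NA_real_, penalty_used = pen,
                   reason = reason, costs = NULL),
              class = "changepoint_result")
  }
  if (n < 2 * min_segment) return(no_change("too_short"))
  if (max(values) == min(values)) return(no_change("constant"))

  full_var <- sum((values - mean(values))^2) / n
  var_floor <- max(1e-4 * full_var, 1e-300)
  full_cost <- segment_cost(values, var_floor)
  taus <- seq.int(min_segment, n - min_segment)
  costs <- vapply(taus, function(tau) {
    segment_cost(values[seq_len(tau)], var_floor) +
      segment_cost(values[seq.int(tau + 1, n)], var_floor)
  }, numeric(1))
  best <- which.min(costs)  # first minimum: smallest tau wins ties
  gain <- full_cost - costs[best]
  if (gain <= pen) {
    res <- no_change("below_penalty")
    res$loglik_gain <- gain
    res$costs <- tibble(tau = taus, cost = costs)
    return(res)
  }
  structure(list(tau = as.integer(taus[best]), loglik_gain = gain,
                 penalty_used = pen, reason = "ok",
                 costs = tibble(tau = taus, cost = costs)),
            class = "changepoint_result")
}

#' Expanded / background partition of a repertoire
#'
#' Runs the variance change-point search on the sample's rank-abundance
#' curve and maps the split back to clonotypes, yielding the data-driven
#' expanded-clone threshold that replaces fixed cutoffs such as "> 1% of
#' the repertoire".
#'
#' @param sample A filtered `repertoire_sample`.
#' @param transform `"raw"` (default: clone counts as-is) or `"log"`
#'   (natural log of counts) before the search.
#' @param forced_tau Optional integer: skip the search and cut at this
#'   rank (used for threshold sweeps).
#' @inheritParams amoc_variance_changepoint
#' @return A list of class `expansion_result`: `tau`, `expanded_keys`,
#'   `background_keys`, `threshold_count` (count of the smallest expanded
#'   clonotype; `NA` when `tau` = 0), `threshold_fraction`,
#'   `expanded_abundance`, `loglik_gain`, `penalty_used`, `reason`,
#'   `transform`.
#' @export
classify_expanded <- function(sample, transform = c("raw", "log"),
                              penalty = c("BIC", "manual"),
                              manual_penalty = NULL, min_segment = 2L,
                              forced_tau = NULL) {
  transform <- match.arg(transform)
  penalty <- match.arg(penalty)
  ra <- rank_abundance(sample)
  values <- if (transform == "log") log(ra$counts) else as.numeric(ra$counts)
  if (is.null(forced_tau)) {
    cp <- amoc_variance_changepoint(values, penalty, manual_penalty, min_segment)
  } else {
    if (forced_tau < 0 || forced_tau > length(values)) {
      abort("forced_tau out of range", class = "tilrep_argument_error")
    }
    cp <- structure(list(tau = as.integer(forced_tau), loglik_gain = NA_real_,
                         penalty_used = NA_real_, reason = "forced",
                         costs = NULL),
                    class = "changepoint_result")
  }
  tau <- cp$tau
  N <- sum(ra$counts)
  expanded <- if (tau > 0) ra$keys[seq_len(tau)] else character()
  background <- setdiff(ra$keys, expanded)
  structure(list(
    tau = tau,
    expanded_keys = expanded, background_keys = background,
    threshold_count = if (tau > 0) ra$counts[tau] else NA_real_,
    threshold_fraction = if (tau > 0) ra$counts[tau] / N else NA_real_,
    expanded_abundance = if (tau > 0) sum(ra$counts[seq_len(tau)]) / N else 0,
    loglik_gain = cp$loglik_gain, penalty_used = cp$penalty_used,
    reason = cp$reason, transform = transform
  ), class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf(
    "<expansion_result> tau=%d (%s)  threshold=%s reads (%.3g%%)  expanded abundance=%.3g\n",
    x$tau, x$reason, format(x$threshold_count),
    100 * (x$threshold_fraction %||% NA_real_), x$expanded_abundance
  ))
  invisible(x)
}
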