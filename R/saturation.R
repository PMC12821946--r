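#' Richness-versus-depth saturation curve
#'
#' Repeatedly subsamples the clonotype table to a grid of fractions of
#' the observed depth (default 10%..95% in 5% steps plus the full
#' sample) and records the clonotype richness at each level, giving the
#' raw material for the saturation decision. Every subsample is drawn by
#' the multivariate hypergeometric of [downsample_counts()], seeded
#' deterministically from `(seed, level, replicate)`.
#'
#' @param sample A `repertoire_sample`.
#' @param fractions Depth fractions in (0, 1].
#' @param replicates Subsampling replicates per level (default 5).
#' @param seed Master seed for the subsampling draws.
#' @return A list of class `saturation_curve` with `table` (tibble
#'   `depth`, `fraction`, `replicate`, `richness`), `sample_id`, and
#'   empty fit fields to be filled by [fit_saturation()].
#' @export
saturation_curve <- function(sample,
                             fractions = c(seq(0.10, 0.95, by = 0.05), 1.0),
                             replicates = 5L, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("fractions must lie in (0, 1]", class = "tilrep_argument_error")
  }
  fractions <- sort(unique(fractions))
  N <- total_reads(sample)
  rows <- list()
  for (li in seq_along(fractions)) {
    depth <- max(1L, as.integer(round(fractions[li] * N)))
    for (ri in seq_len(replicates)) {
      sub_seed <- derive_seed(seed, li, ri)
      rich <- if (depth >= N) {
        richness(sample)
      } else {
        richness(downsample_counts(sample, depth, seed = sub_seed))
      }
      rows[[length(rows) + 1]] <- tibble(
        depth = depth, fraction = fractions[li], replicate = ri,
        richness = rich
      )
    }
  }
  structure(list(sample_id = sample$sample_id, table = bind_rows(rows),
                 fit = NULL), class = "saturation_curve")
}

#' Fit the saturation smooth and decide saturation
#'
#' Fits a penalized cubic spline (a generalized additive model with
#' smoothing chosen by GCV) of richness on sequencing depth, estimates
#' the first derivative of the smooth at the deepest level with a 95\%
#' confidence interval from the smoother's coefficient covariance, and
#' declares the sample saturated when the upper CI bound of that
#' derivative is at most `epsilon` -- i.e. when further sequencing would
#' yield essentially no new clonotypes.
#'
#' @param curve A `saturation_curve` (or a tibble with `depth` and
#'   `richness` columns), with at least 5 distinct depth levels.
#' @param epsilon Slope tolerance in new clonotypes per read; default
#'   `1e-4` (one new clonotype per 10,000 reads).
#' @return The curve with `fit` populated: a list with `fitted` (tibble
#'   `depth`, `fit`), `derivative`, `ci_low`, `ci_high`, `epsilon`,
#'   `saturated`, and `rule` (a human-readable statement of the decision
#'   rule applied). `NA` fit fields (saturated = `NA`) when fewer than 5
#'   depth levels are available.
#' @export
fit_saturation <- function(curve, epsilon = 1e-4) {
  tab <- if (inherits(curve, "saturation_curve")) curve$table else as_tibble(curve)
  levels_n <- length(unique(tab$depth))
  out <- if (inherits(curve, "saturation_curve")) curve else {
    structure(list(sample_id = NA_character_, table = tab, fit = NULL),
              class = "saturation_curve")
  }
  rule <- paste0("saturated iff upper 95% CI of d(richness)/d(depth) at max ",
                 "depth <= ", format(epsilon))
  if (levels_n < 5) {
    out$fit <- list(fitted = NULL, derivative = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, epsilon = epsilon, saturated = NA,
                    rule = rule, reason = "too_few_levels")
    return(out)
  }
  k <- max(3L, min(levels_n - 1L, 18L))
  fit <- mgcv::gam(richness ~ s(depth, k = k, bs = "cr"), data = tab,
                   method = "GCV.Cp")
  d_max <- max(tab$depth)
  h <- diff(range(tab$depth)) * 1e-3
  newd <- data.frame(depth = c(d_max - h, d_max))
  Xp <- stats::predict(fit, newd, type = "lpmatrix")
  dvec <- (Xp[2, ] - Xp[1, ]) / h
  deriv <- sum(dvec * stats::coef(fit))
  se <- sqrt(drop(t(dvec) %*% fit$Vp %*% dvec))
  grid <- data.frame(depth = seq(min(tab$depth), d_max, length.out = 100))
  out$fit <- list(
    fitted = tibble(depth = grid$depth,
                    fit = as.numeric(stats::predict(fit, grid))),
    derivative = deriv, ci_low = deriv - 1.96 * se,
    ci_high = deriv + 1.96 * se, epsilon = epsilon,
    saturated = (deriv + 1.96 * se) <= epsilon, rule = rule, reason = "ok"
  )
  out
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("<saturation_curve> %s  %d levels x %d replicates\n",
              x$sample_id %||% "?", length(unique(x$table$depth)),
              max(x$table$replicate)))
  if (!is.null(x$fit)) {
    cat(sprintf("  derivative at max depth: %.3g [%.3g, %.3g]; saturated: %s\n",
                x$fit$derivative, x$fit$ci_low, x$fit$ci_high,
                x$fit$saturated))
  }
  invisible(x)
}

# Deterministic 32-bit seed stream: integer hash of a (seed, codes...) tuple.
# Keyed draws mean adding a patient/sample never perturbs existing ones.
derive_seed <- function(seed, ...) {
  codes <- list(seed, ...)
  h <- 0
  for (x in codes) {
    if (is.character(x)) x <- sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
    h <- (h * 69069 + as.numeric(x) * 2654435761) %% 2147483647
  }
  as.integer(h)
}
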