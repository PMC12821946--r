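# Builders and independent oracles used across the suite.

# Quick repertoire from a count vector; keys default to zero-padded labels
# so lexicographic tie-breaking is predictable.
make_rep <- function(counts, keys = sprintf("NT%05d", seq_along(counts)),
                     locus = "TRB", productive = TRUE,
                     sample_id = "S1", patient_id = "P1",
                     cohort = NA_character_, timepoint_days = NA_integer_,
                     cdr3_aa = NULL) {
  v <- paste0(locus, "V1*01")
  rec <- tibble::tibble(
    cdr3_nt = keys,
    cdr3_aa = cdr3_aa %||% rep("CASSF", length(counts)),
    v_call = rep_len(v, length(counts)),
    j_call = paste0(rep_len(locus, length(counts)), "J1-1*01"),
    count = counts,
    productive = rep_len(productive, length(counts))
  )
  repertoire_sample(rec, sample_id = sample_id, patient_id = patient_id,
                    cohort = cohort, timepoint_days = timepoint_days,
                    key = "nt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------------

# Naive two-line diversity recomputation straight from the printed formulas.
naive_diversity <- function(n) {
  p <- n / sum(n)
  lambda <- sum(p^2)
  H <- -sum(p * log(p))
  S <- length(n)
  sei <- if (S == 1) 0 else H / log(S)
  list(lambda = lambda, inv = 1 / lambda, H = H, sei = sei, C = 1 - sei)
}

# Morisita-Horn from two abundance vectors over an explicit shared support.
naive_morisita <- function(x, y) {
  p <- x / sum(x)
  q <- y / sum(y)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

# Brute-force at-most-one-change search: literal re-derivation, looping over
# every split and both segments without any shared code with the package.
brute_amoc <- function(values, min_segment = 2L) {
  n <- length(values)
  floor_v <- 1e-4 * (sum((values - mean(values))^2) / n)
  cost <- function(x) {
    v <- sum((x - mean(x))^2) / length(x)
    length(x) * log(max(v, floor_v))
  }
  best_tau <- 0L
  best_cost <- Inf
  for (tau in min_segment:(n - min_segment)) {
    cc <- cost(values[1:tau]) + cost(values[(tau + 1):n])
    if (cc < best_cost - 1e-12) {
      best_cost <- cc
      best_tau <- tau
    }
  }
  list(tau = best_tau, gain = cost(values) - best_cost)
}

# Closed-form relative risk per the printed formulas.
naive_rr <- function(A, B, C, D) {
  rr <- (A / (A + B)) / (C / (C + D))
  se <- sqrt(B / (A * (A + B)) + D / (C * (C + D)))
  list(rr = rr, se = se,
       lo = exp(log(rr) - 1.96 * se), hi = exp(log(rr) + 1.96 * se))
}

# Write a small AIRR TSV fixture and return its path.
write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}
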