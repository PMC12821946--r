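#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Closed vocabularies used across the package
.tilrep_loci <- c("TRA", "TRB", "TRG", "TRD", "IGH", "IGK", "IGL")
.tilrep_cohorts <- c("PBMC_DNA", "PBMC_RNA", "CFDNA", "TIL_DNA", "TIL_RNA")
.tilrep_responses <- c("PR", "SD", "PD")

#' Clonotype identity keys
#'
#' Builds the string key that decides "same clonotype" within and across
#' samples. The default matches on the CDR3 nucleotide sequence together
#' with the V and J gene (alleles stripped, so `"TRBV7-2*01"` and
#' `"TRBV7-2*02"` agree). Amino-acid-level matching (`"aa_vj"`) and bare
#' nucleotide matching (`"nt"`) are available because different platforms
#' disagree on how much context belongs to a clonotype.
#'
#' @param records A tibble with columns `cdr3_nt`, `cdr3_aa`, `v_call`,
#'   `j_call` (as produced by [read_clonotype_table()]).
#' @param key One of `"nt_vj"` (default), `"aa_vj"`, `"nt"`.
#' @return Character vector of keys, one per row.
#' @export
clonotype_key <- function(records, key = c("nt_vj", "aa_vj", "nt")) {
  key <- match.arg(key)
  v <- strip_allele(records$v_call)
  j <- strip_allele(records$j_call)
  switch(key,
    nt_vj = paste(records$cdr3_nt, v, j, sep = "|"),
    aa_vj = paste(records$cdr3_aa, v, j, sep = "|"),
    nt    = records$cdr3_nt
  )
}

#' Strip the allele suffix from a gene call ("TRBV7-2*01" -> "TRBV7-2")
#' @param x Character vector of gene calls.
#' @return Character vector without `*NN` allele designations.
#' @export
strip_allele <- function(x) sub("\\*.*$", "", x)

infer_locus <- function(v_call) {
  pre <- toupper(substr(strip_allele(v_call), 1L, 3L))
  ifelse(pre %in% .tilrep_loci, pre, NA_character_)
}

# Unproductive when the productive flag says so, or (flag missing) when the
# amino-acid junction carries a stop '*' or frameshift '_' symbol.
is_productive <- function(productive, cdr3_aa) {
  flagged <- !is.na(productive)
  frame_ok <- !grepl("[*_]", cdr3_aa %||% "")
  out <- ifelse(flagged, productive, frame_ok)
  # a productive flag contradicted by a stop/frameshift symbol is demoted
  out & frame_ok
}

#' Construct a repertoire sample
#'
#' Low-level constructor for the container used throughout the package: a
#' clonotype table plus sample metadata. Most users will obtain these from
#' [read_clonotype_table()] or [simulate_cohort()].
#'
#' @param records Tibble with columns `cdr3_nt`, `cdr3_aa`, `v_call`,
#'   `j_call`, `count`, and optionally `productive` and `locus`.
#' @param sample_id,patient_id Identifier strings.
#' @param cohort One of `PBMC_DNA`, `PBMC_RNA`, `CFDNA`, `TIL_DNA`,
#'   `TIL_RNA` (or `NA` when unknown).
#' @param timepoint_days Integer day relative to infusion (negative or zero
#'   = baseline).
#' @param key Clonotype-identity convention, see [clonotype_key()].
#' @return An object of class `repertoire_sample`: a list with elements
#'   `sample_id`, `patient_id`, `cohort`, `timepoint_days`, `key_type` and
#'   `records` (tibble keyed by `key`, duplicate keys merged by summing
#'   counts).
#' @export
repertoire_sample <- function(records, sample_id = NA_character_,
                              patient_id = NA_character_,
                              cohort = NA_character_,
                              timepoint_days = NA_integer_,
                              key = c("nt_vj", "aa_vj", "nt")) {
  key <- match.arg(key)
  if (!is.na(cohort) && !cohort %in% .tilrep_cohorts) {
    abort(paste0("unknown cohort '", cohort, "'"), class = "tilrep_argument_error")
  }
  records <- as_tibble(records)
  if (!"cdr3_aa" %in% names(records)) records$cdr3_aa <- NA_character_
  if (!"productive" %in% names(records)) records$productive <- NA
  records$count <- as.integer(round(records$count))
  if (any(is.na(records$count)) || any(records$count < 0)) {
    abort("clone counts must be non-negative integers", class = "tilrep_row_error")
  }
  if (!"locus" %in% names(records)) records$locus <- infer_locus(records$v_call)
  records$productive <- is_productive(records$productive, records$cdr3_aa)
  records$key <- clonotype_key(records, key)
  if (anyDuplicated(records$key)) {
    records <- records |>
      group_by(.data$key) |>
      summarise(
        cdr3_nt = first(.data$cdr3_nt), cdr3_aa = first(.data$cdr3_aa),
        v_call = first(.data$v_call), j_call = first(.data$j_call),
        locus = first(.data$locus), productive = all(.data$productive),
        count = sum(.data$count), .groups = "drop"
      )
  }
  ord <- order(-records$count, records$key, method = "radix")
  records <- records[ord, c("key", "cdr3_nt", "cdr3_aa", "v_call", "j_call",
                            "locus", "productive", "count")]
  structure(
    list(sample_id = sample_id, patient_id = patient_id, cohort = cohort,
         timepoint_days = as.integer(timepoint_days), key_type = key,
         records = records),
    class = "repertoire_sample"
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "<repertoire_sample> %s  patient=%s cohort=%s day=%s\n  %d clonotypes, %s reads (key: %s)\n",
    x$sample_id %||% "?", x$patient_id %||% "?", x$cohort %||% "?",
    x$timepoint_days %||% "?", nrow(x$records),
    format(sum(x$records$count), big.mark = ","), x$key_type
  ))
  invisible(x)
}

#' Total read/clone count of a sample
#' @param sample A `repertoire_sample`.
#' @return Integer sum of clone counts.
#' @export
total_reads <- function(sample) sum(sample$records$count)

#' Clonotype richness of a sample
#' @param sample A `repertoire_sample`.
#' @return Number of distinct clonotype keys.
#' @export
richness <- function(sample) nrow(sample$records)

#' Relative clonotype abundances
#' @param sample A `repertoire_sample`.
#' @return Named numeric vector n_i / N, named by clonotype key.
#' @export
rel_abundance <- function(sample) {
  n <- sample$records$count
  stats::setNames(n / sum(n), sample$records$key)
}

#' Read a clonotype table (AIRR Rearrangement or MiXCR clone export)
#'
#' Parses one sample's clonotype table into a [repertoire_sample()]. MiXCR
#' clone-export columns are mapped onto AIRR names at parse time, so the
#' AIRR Rearrangement TSV is the canonical representation. Rows sharing a
#' clonotype key are merged by summing counts; the locus is inferred from
#' the V call prefix.
#'
#' @param path Path to a tab-separated clonotype table.
#' @param format `"airr"` (columns `junction`, `junction_aa`, `v_call`,
#'   `j_call`, `duplicate_count`, optionally `productive`) or `"mixcr"`
#'   (columns `cloneCount`, `nSeqCDR3`, `aaSeqCDR3`, `allVHitsWithScore`,
#'   `allJHitsWithScore`).
#' @param key Clonotype-identity convention, see [clonotype_key()].
#' @inheritParams repertoire_sample
#' @return A `repertoire_sample`.
#' @export
read_clonotype_table <- function(path, format = c("airr", "mixcr"),
                                 sample_id = NA_character_,
                                 patient_id = NA_character_,
                                 cohort = NA_character_,
                                 timepoint_days = NA_integer_,
                                 key = c("nt_vj", "aa_vj", "nt")) {
  format <- match.arg(format)
  key <- match.arg(key)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tilrep_io_error")
  }
  if (is.na(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tab) == 0) {
    abort(paste0("empty clonotype table: ", path), class = "tilrep_empty_sample_error")
  }
  required <- switch(format,
    airr  = c("junction", "junction_aa", "v_call", "j_call", "duplicate_count"),
    mixcr = c("cloneCount", "nSeqCDR3", "aaSeqCDR3", "allVHitsWithScore",
              "allJHitsWithScore")
  )
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required ", format, " column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tilrep_format_error")
  }
  if (format == "airr") {
    records <- tibble(
      cdr3_nt = tab$junction, cdr3_aa = tab$junction_aa,
      v_call = tab$v_call, j_call = tab$j_call,
      count_raw = tab$duplicate_count,
      productive = if ("productive" %in% names(tab)) {
        tolower(tab$productive) %in% c("t", "true")
      } else NA
    )
  } else {
    # MiXCR reports hits as "TRBV7-2*00(123.4),..." -- take the best hit
    best_hit <- function(x) strip_allele(sub("\\(.*$", "", sub(",.*$", "", x)))
    records <- tibble(
      cdr3_nt = tab$nSeqCDR3, cdr3_aa = tab$aaSeqCDR3,
      v_call = best_hit(tab$allVHitsWithScore),
      j_call = best_hit(tab$allJHitsWithScore),
      count_raw = tab$cloneCount, productive = NA
    )
  }
  counts <- suppressWarnings(as.numeric(records$count_raw))
  if (any(is.na(counts))) {
    bad <- which(is.na(counts))[1]
    abort(paste0("non-numeric clone count at data row ", bad, " of ", path),
          class = "tilrep_row_error")
  }
  records$count <- counts
  records$count_raw <- NULL
  repertoire_sample(records, sample_id = sample_id, patient_id = patient_id,
                    cohort = cohort, timepoint_days = timepoint_days, key = key)
}

#' Write a sample as an AIRR Rearrangement TSV
#'
#' @param sample A `repertoire_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(sample, path) {
  out <- tibble(
    junction = sample$records$cdr3_nt,
    junction_aa = sample$records$cdr3_aa,
    v_call = sample$records$v_call,
    j_call = sample$records$j_call,
    productive = ifelse(sample$records$productive, "T", "F"),
    duplicate_count = sample$records$count
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter a repertoire to the analysis set
#'
#' Restricts to one locus (TCR-beta by default), removes unproductive
#' clonotypes (stop/frameshift junctions), then removes singletons
#' (count == 1, judged after the unproductive step). The order is fixed so
#' that the filter report is deterministic.
#'
#' @param sample A `repertoire_sample`.
#' @param locus Locus to keep, default `"TRB"`; `NULL` keeps all loci.
#' @param drop_unproductive,drop_singletons Logical switches for the two
#'   filtering steps.
#' @return A list with elements `sample` (the filtered `repertoire_sample`)
#'   and `report`, a one-row tibble with clonotypes removed at each step,
#'   the unproductive fraction at clonotype and at read level, and input /
#'   output richness.
#' @export
filter_repertoire <- function(sample, locus = "TRB",
                              drop_unproductive = TRUE,
                              drop_singletons = TRUE) {
  rec <- sample$records
  if (nrow(rec) == 0) {
    abort("cannot filter an empty sample", class = "tilrep_empty_sample_error")
  }
  s_in <- nrow(rec)
  reads_in <- sum(rec$count)

  if (!is.null(locus)) {
    keep <- !is.na(rec$locus) & rec$locus == locus
    removed_locus <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]
    if (nrow(rec) == 0) {
      abort("no clonotypes left after locus restriction",
            class = "tilrep_empty_after_filter_error")
    }
  } else {
    removed_locus <- 0L
  }

  unprod <- !rec$productive
  unprod_frac_clonotype <- mean(unprod)
  unprod_frac_read <- sum(rec$count[unprod]) / sum(rec$count)
  if (drop_unproductive) {
    removed_unproductive <- sum(unprod)
    rec <- rec[!unprod, , drop = FALSE]
    if (nrow(rec) == 0) {
      abort("no clonotypes left after unproductive removal",
            class = "tilrep_empty_after_filter_error")
    }
  } else {
    removed_unproductive <- 0L
  }

  if (drop_singletons) {
    single <- rec$count == 1L
    removed_singletons <- sum(single)
    rec <- rec[!single, , drop = FALSE]
    if (nrow(rec) == 0) {
      abort("no clonotypes left after singleton removal",
            class = "tilrep_empty_after_filter_error")
    }
  } else {
    removed_singletons <- 0L
  }

  out <- sample
  out$records <- rec
  report <- tibble(
    sample_id = sample$sample_id,
    richness_in = s_in, richness_out = nrow(rec),
    reads_in = reads_in, reads_out = sum(rec$count),
    removed_locus = as.integer(removed_locus),
    removed_unproductive = as.integer(removed_unproductive),
    removed_singletons = as.integer(removed_singletons),
    unproductive_frac_clonotype = unprod_frac_clonotype,
    unproductive_frac_read = unprod_frac_read
  )
  list(sample = out, report = report)
}

#' Downsample a repertoire to a fixed total count
#'
#' Draws `target_total` reads without replacement from the observed clone
#' counts (multivariate hypergeometric), emulating read-level subsampling
#' at the clone-table level. Clonotypes reduced to zero are dropped.
#'
#' @param sample A `repertoire_sample`.
#' @param target_total Desired total count (>= 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `repertoire_sample` with total count exactly
#'   `min(target_total, N)`. If `target_total >= N` the sample is returned
#'   unchanged with attribute `downsample_noop = TRUE` and a warning.
#' @export
downsample_counts <- function(sample, target_total, seed = 1L) {
  if (!is.numeric(target_total) || target_total < 1) {
    abort("target_total must be >= 1", class = "tilrep_argument_error")
  }
  n <- sample$records$count
  N <- sum(n)
  if (target_total >= N) {
    if (target_total > N) {
      warn(sprintf("target_total (%s) >= sample total (%s); returning unchanged",
                   format(target_total), format(N)))
    }
    attr(sample, "downsample_noop") <- TRUE
    return(sample)
  }
  new_counts <- withr::with_seed(as.integer(seed),
                                 rmvhyper(n, as.integer(target_total)))
  out <- sample
  out$records$count <- new_counts
  out$records <- out$records[new_counts > 0L, , drop = FALSE]
  out
}

# Multivariate hypergeometric draw by sequential conditioning: clone i gets
# a univariate hypergeometric share of what remains.
rmvhyper <- function(n, k) {
  m <- length(n)
  out <- integer(m)
  rest <- sum(n)
  for (i in seq_len(m)) {
    rest <- rest - n[i]
    out[i] <- as.integer(stats::rhyper(1L, n[i], rest, k))
    k <- k - out[i]
    if (k == 0L) break
  }
  out
}

#' Read a sample manifest
#'
#' The manifest is a TSV with columns `path`, `format`, `patient_id`,
#' `cohort`, `timepoint_days`, `response`. Paths are resolved relative to
#' the manifest's own directory when not absolute.
#'
#' @param path Manifest TSV path.
#' @return Tibble with the manifest rows, a `responder` flag
#'   (`response == "PR"`), and absolute `path`s, validated for existence
#'   and per-patient response consistency.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(
    path = "c", format = "c", patient_id = "c", cohort = "c",
    timepoint_days = "i", response = "c"
  ), progress = FALSE)
  need <- c("path", "format", "patient_id", "cohort", "timepoint_days", "response")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tilrep_format_error")
  }
  root <- dirname(normalizePath(path))
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(root, man$path))
  gone <- !file.exists(man$path)
  if (any(gone)) {
    abort(paste0("manifest references missing file(s): ",
                 paste(man$path[gone], collapse = ", ")),
          class = "tilrep_io_error")
  }
  bad_cohort <- !man$cohort %in% .tilrep_cohorts
  if (any(bad_cohort)) {
    abort(paste0("unknown cohort in manifest: ",
                 paste(unique(man$cohort[bad_cohort]), collapse = ", ")),
          class = "tilrep_format_error")
  }
  inconsistent <- man |>
    group_by(.data$patient_id) |>
    summarise(k = n_distinct(.data$response), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(inconsistent) > 0) {
    abort(paste0("response not constant within patient: ",
                 paste(inconsistent$patient_id, collapse = ", ")),
          class = "tilrep_format_error")
  }
  man$responder <- man$response == "PR"
  man
}
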