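#' Counts-per-million standardization
#'
#' Standardizes libraries to a common size: each locus's reads are divided by
#' the library size (total reads mapped to the reference loci, i.e. the column
#' sum) and multiplied by one million, so every column of the result sums to
#' 1e6.
#'
#' @param counts Wide count tibble: `locus_id` plus one non-negative integer
#'   column per library.
#' @return Tibble of the same shape with CPM values.
#' @examples
#' counts <- tibble::tibble(locus_id = c("L1", "L2"), a = c(15L, 999985L))
#' cpm_normalize(counts)
#' @export
cpm_normalize <- function(counts) {
  m <- wide_to_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  sizes <- colSums(m)
  empty <- names(sizes)[sizes == 0]
  if (length(empty)) {
    abort(paste0("library with zero total reads cannot be CPM-normalized: ",
                 paste(empty, collapse = ", ")))
  }
  matrix_to_wide(sweep(m, 2, sizes, "/") * 1e6)
}

#' Retain loci sufficiently covered in every RAD library
#'
#' A locus is retained when its CPM value reaches `threshold` in *every*
#' methylation-insensitive (RAD) library.  Loci failing in any library are
#' dropped as non-conclusive: a zero in their methylation-sensitive partner
#' could reflect shallow coverage rather than methylation.
#'
#' @param cpm_rad CPM tibble ([cpm_normalize()]) restricted to RAD libraries.
#' @param threshold Retention threshold in CPM units (default 15; 7 and 21 are
#'   conventional sensitivity settings).
#' @return A tibble with one row per locus: `locus_id`, `min_cpm` (the
#'   locus's worst coverage across libraries) and logical `retained`; the
#'   threshold is kept in attribute `"threshold"`.  Use [retained_loci()] for
#'   the retained ids.
#' @export
filter_loci <- function(cpm_rad, threshold = 15) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  m <- wide_to_matrix(cpm_rad)
  min_cpm <- apply(m, 1, min)
  # at threshold 0 a locus entirely absent from some library is still dropped
  keep <- if (threshold > 0) min_cpm >= threshold else min_cpm > 0
  out <- tibble(
    locus_id = rownames(m),
    min_cpm = unname(min_cpm),
    retained = unname(keep)
  )
  if (!any(out$retained)) {
    warn(paste0("no locus passes the ", threshold, "-CPM retention filter"))
  }
  attr(out, "threshold") <- threshold
  out
}

#' @rdname filter_loci
#' @param filter Output of [filter_loci()].
#' @export
retained_loci <- function(filter) filter$locus_id[filter$retained]

#' Zero-read methylation calling
#'
#' Over the retained loci, a locus is called methylated (1) in a sample when
#' its *raw* methylation-sensitive (EpiRAD) read count is exactly zero, and
#' unmethylated (0) otherwise — a single read already proves the
#' methylation-sensitive enzyme cut the site.  The rule depends only on the
#' zero pattern, so it is invariant to library scaling.  Partially methylated
#' loci usually yield a few reads and are therefore called unmethylated; the
#' method underestimates total methylation by design, trading sensitivity for
#' the absence of a depth cut-off.
#'
#' @param counts_epirad Wide raw-count tibble of EpiRAD libraries.
#' @param retained Character vector of retained locus ids, or the tibble from
#'   [filter_loci()].
#' @param meta Optional metadata ([simulate_metadata()] layout).  When given,
#'   every EpiRAD library must pair with a RAD library of the same
#'   (individual, tissue), and call columns are named by `sample_id`;
#'   otherwise EpiRAD column names are used as sample ids.
#' @return Wide tibble `locus_id` + one 0/1 integer column per sample,
#'   restricted to retained loci.
#' @export
call_methylation <- function(counts_epirad, retained, meta = NULL) {
  if (is.data.frame(retained)) retained <- retained_loci(retained)
  if (!length(retained)) {
    abort("empty retained locus set: nothing to call")
  }
  m <- wide_to_matrix(counts_epirad)
  missing <- setdiff(retained, rownames(m))
  if (length(missing)) {
    abort(paste0(length(missing),
                 " retained loci are absent from the EpiRAD counts"))
  }
  m <- m[retained, , drop = FALSE]

  sample_ids <- colnames(m)
  if (!is.null(meta)) {
    epi <- meta[match(colnames(m), meta$library_id), ]
    if (anyNA(epi$library_id) || any(epi$library_type != "EpiRAD")) {
      abort("EpiRAD count columns must match EpiRAD `library_id`s in `meta`")
    }
    rad <- meta[meta$library_type == "RAD", ]
    unpaired <- setdiff(epi$sample_id, rad$sample_id)
    if (length(unpaired)) {
      abort(paste0("EpiRAD libraries without a paired RAD library: ",
                   paste(unpaired, collapse = ", ")))
    }
    sample_ids <- epi$sample_id
  }

  calls <- matrix(as.integer(m == 0), nrow = nrow(m),
                  dimnames = list(rownames(m), sample_ids))
  matrix_to_wide(calls)
}

#' Per-sample methylation proportion
#'
#' The percentage of retained loci called methylated in each sample.
#'
#' @param calls Call matrix from [call_methylation()].
#' @param meta Optional metadata; when given, sample sex, age group and tissue
#'   are joined onto the result.
#' @return Tibble: `sample_id`, `n_methylated`, `n_retained`,
#'   `proportion_pct` (plus metadata columns when `meta` is supplied).
#' @export
methylation_proportion <- function(calls, meta = NULL) {
  m <- wide_to_matrix(calls)
  if (nrow(m) == 0) abort("no retained loci: methylation proportion undefined")
  out <- tibble(
    sample_id = colnames(m),
    n_methylated = as.integer(colSums(m)),
    n_retained = nrow(m),
    proportion_pct = as.numeric(100 * colSums(m) / nrow(m))
  )
  if (!is.null(meta)) {
    info <- dplyr::distinct(meta, .data$sample_id, .data$individual_id,
                            .data$sex, .data$age_group, .data$tissue)
    out <- dplyr::left_join(out, info, by = "sample_id")
  }
  out
}

#' Retention-threshold sensitivity of methylation proportions
#'
#' Re-runs retention and calling at several CPM thresholds and lines up the
#' per-sample proportions, reporting each sample's largest absolute deviation
#' across thresholds — a direct robustness check of the retention cut-off.
#'
#' @param counts_rad,counts_epirad Wide raw-count tibbles.
#' @param meta Optional metadata passed to [call_methylation()].
#' @param thresholds CPM thresholds to compare (default 7, 15, 21).
#' @return Tibble: `sample_id`, one `pct_at_<threshold>` column per threshold,
#'   and `max_abs_delta`.
#' @export
threshold_sensitivity <- function(counts_rad, counts_epirad, meta = NULL,
                                  thresholds = c(7, 15, 21)) {
  cpm_rad <- cpm_normalize(counts_rad)
  runs <- purrr::map(thresholds, function(th) {
    filt <- filter_loci(cpm_rad, threshold = th)
    calls <- call_methylation(counts_epirad, filt, meta)
    prop <- methylation_proportion(calls)
    dplyr::select(prop, "sample_id", "proportion_pct") |>
      dplyr::rename(!!paste0("pct_at_", th) := "proportion_pct")
  })
  out <- purrr::reduce(runs, dplyr::left_join, by = "sample_id")
  pcts <- as.matrix(out[paste0("pct_at_", thresholds)])
  out$max_abs_delta <- apply(pcts, 1, function(x) max(x) - min(x))
  out
}
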