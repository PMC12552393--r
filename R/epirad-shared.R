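#' Differentially vs uniformly methylated loci
#'
#' Classifies every called locus by whether its binary methylation call varies
#' across the samples: loci identical in all samples are "uniform"
#' (methylated or unmethylated); the rest are the differentially methylated
#' set used for ordination and shared-locus accounting.
#'
#' @param calls Call matrix from [call_methylation()].
#' @return Tibble: `locus_id`, `status` in
#'   `{"differential", "uniform_methylated", "uniform_unmethylated"}`,
#'   `n_methylated` (samples in which the locus is methylated).
#' @export
differential_loci <- function(calls) {
  m <- wide_to_matrix(calls)
  if (ncol(m) < 2) abort("need at least 2 samples to classify loci")
  k <- rowSums(m)
  tibble(
    locus_id = rownames(m),
    status = dplyr::case_when(
      k == 0 ~ "uniform_unmethylated",
      k == ncol(m) ~ "uniform_methylated",
      TRUE ~ "differential"
    ),
    n_methylated = as.integer(k)
  )
}

#' @rdname differential_loci
#' @export
differential_universe <- function(calls) {
  cls <- differential_loci(calls)
  cls$locus_id[cls$status == "differential"]
}

#' Shared methylation status within sample groups
#'
#' For each group of samples, counts how many loci of the differential
#' universe are uniformly unmethylated — and how many uniformly methylated —
#' across *every* sample of the group, with percentages relative to the
#' universe size.  High shared-unmethylated counts are what make samples of a
#' tissue cluster together.
#'
#' @param calls Call matrix from [call_methylation()].
#' @param groups Named list of character vectors of sample ids.
#' @param universe Locus ids of the differential universe (default:
#'   [differential_universe()] of `calls`).
#' @return Tibble, one row per group: `group`, `n_samples`, `n_universe`,
#'   `n_uniform_unmethylated`, `n_uniform_methylated`,
#'   `pct_uniform_unmethylated`, `pct_uniform_methylated`.
#' @export
shared_status_counts <- function(calls, groups,
                                 universe = differential_universe(calls)) {
  m <- wide_to_matrix(calls)
  if (!length(universe)) abort("empty differential universe")
  missing_loci <- setdiff(universe, rownames(m))
  if (length(missing_loci)) abort("`universe` contains loci absent from `calls`")
  m <- m[universe, , drop = FALSE]
  if (is.character(groups)) groups <- list(group = groups)
  purrr::imap(groups, function(samples, label) {
    if (!length(samples)) abort(paste0("group '", label, "' is empty"))
    unknown <- setdiff(samples, colnames(m))
    if (length(unknown)) {
      abort(paste0("group '", label, "' references unknown samples: ",
                   paste(unknown, collapse = ", ")))
    }
    sub <- m[, samples, drop = FALSE]
    n0 <- sum(rowSums(sub) == 0)
    n1 <- sum(rowSums(sub) == ncol(sub))
    tibble(
      group = label,
      n_samples = length(samples),
      n_universe = length(universe),
      n_uniform_unmethylated = n0,
      n_uniform_methylated = n1,
      pct_uniform_unmethylated = 100 * n0 / length(universe),
      pct_uniform_methylated = 100 * n1 / length(universe)
    )
  }) |>
    dplyr::bind_rows()
}

# The four tissue-by-sex groups conventionally reported.
tissue_sex_groups <- function(meta) {
  info <- dplyr::distinct(meta, .data$sample_id, .data$sex, .data$tissue)
  grp <- split(info$sample_id, paste(info$tissue, info$sex, sep = "_"))
  grp[order(names(grp))]
}

#' Fin-gonad methylation concordance per individual
#'
#' For every individual, counts the differential-universe loci methylated in
#' *both* its fin and its gonad sample, as a count and as a percentage of the
#' universe; individuals missing a tissue are skipped with a warning.  Also
#' reports, per sex, the loci methylated in both tissues of every individual
#' of that sex (the across-individual intersection).
#'
#' @inheritParams shared_status_counts
#' @param meta Sample metadata with `sample_id`, `individual_id`, `sex`,
#'   `tissue`.
#' @return List of class `fin_gonad_concordance`: `$individuals` (tibble with
#'   `individual_id`, `sex`, `n_shared_methylated`, `pct_of_universe`) and
#'   `$sex_intersection` (tibble with `sex`, `n_individuals`,
#'   `n_shared_all_individuals`).
#' @export
fin_gonad_concordance <- function(calls, meta,
                                  universe = differential_universe(calls)) {
  m <- wide_to_matrix(calls)
  if (!length(universe)) abort("empty differential universe")
  m <- m[universe, , drop = FALSE]
  info <- dplyr::distinct(meta, .data$sample_id, .data$individual_id,
                          .data$sex, .data$tissue)
  info <- info[info$sample_id %in% colnames(m), ]
  wide <- tidyr::pivot_wider(info, id_cols = c("individual_id", "sex"),
                             names_from = "tissue",
                             values_from = "sample_id")
  complete <- !is.na(wide$fin %||% NA) & !is.na(wide$gonad %||% NA)
  if (!all(complete)) {
    warn(paste0("skipping ", sum(!complete),
                " individual(s) missing a fin or gonad sample"))
    wide <- wide[complete, ]
  }
  if (!nrow(wide)) abort("no individual has both fin and gonad calls")

  both <- m[, wide$fin, drop = FALSE] * m[, wide$gonad, drop = FALSE]
  individuals <- tibble(
    individual_id = wide$individual_id,
    sex = wide$sex,
    n_shared_methylated = as.integer(colSums(both)),
    n_universe = length(universe),
    pct_of_universe = as.numeric(100 * colSums(both) / length(universe))
  )
  sex_intersection <- dplyr::bind_rows(lapply(split(
    seq_len(nrow(wide)), wide$sex), function(idx) {
      tibble(
        sex = wide$sex[idx[1]],
        n_individuals = length(idx),
        n_shared_all_individuals =
          sum(rowSums(both[, idx, drop = FALSE] > 0) == length(idx))
      )
    }))
  structure(list(individuals = individuals,
                 sex_intersection = sex_intersection),
            class = "fin_gonad_concordance")
}

#' @export
print.fin_gonad_concordance <- function(x, ...) {
  rng <- range(x$individuals$n_shared_methylated)
  prng <- range(x$individuals$pct_of_universe)
  cat(sprintf(
    "Fin-gonad shared methylated loci per individual: %d-%d (%.2f-%.2f%% of %d differential loci)\n",
    rng[1], rng[2], prng[1], prng[2], x$individuals$n_universe[1]))
  print(x$sex_intersection)
  invisible(x)
}

#' @export
tidy.fin_gonad_concordance <- function(x, ...) x$individuals
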