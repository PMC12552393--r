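#' Group summaries of methylation proportions and telomere medians
#'
#' Mean, standard error (sd/sqrt(n)), minimum and maximum per tissue and per
#' tissue x sex x age group, for the per-sample methylation proportions and
#' (when supplied) the telomere medians.  Groups of size one get a missing
#' standard error with a message.
#'
#' @param proportions Output of [methylation_proportion()] including metadata
#'   columns (`tissue`, `sex`, `age_group`).
#' @param telomeres Optional tidy telomere table (`individual_id`, `tissue`,
#'   `median_kb`); sex and age are joined from `meta` if absent.
#' @param meta Optional metadata used to complete the telomere table.
#' @return Tibble: `measure`, `grouping`, `tissue`, `sex`, `age_group`, `n`,
#'   `mean`, `se`, `min`, `max`.
#' @export
summarize_proportions <- function(proportions, telomeres = NULL, meta = NULL) {
  if (!nrow(proportions)) abort("empty proportions table")
  pieces <- list(
    group_summary(proportions, "proportion_pct", "methylation_pct", "tissue"),
    group_summary(proportions, "proportion_pct", "methylation_pct",
                  c("tissue", "sex", "age_group"))
  )
  if (!is.null(telomeres)) {
    tel <- telomeres
    if (!all(c("sex", "age_group") %in% names(tel)) && !is.null(meta)) {
      info <- dplyr::distinct(meta, .data$individual_id, .data$sex,
                              .data$age_group)
      tel <- dplyr::left_join(tel, info, by = "individual_id")
    }
    pieces <- c(pieces, list(
      group_summary(tel, "median_kb", "telomere_kb", "tissue"),
      group_summary(tel, "median_kb", "telomere_kb",
                    c("tissue", "sex", "age_group"))
    ))
  }
  dplyr::bind_rows(pieces)
}

group_summary <- function(df, value, measure, groups) {
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      se = ifelse(dplyr::n() > 1,
                  stats::sd(.data[[value]]) / sqrt(dplyr::n()), NA_real_),
      min = min(.data[[value]]),
      max = max(.data[[value]]),
      .groups = "drop"
    )
  if (anyNA(out$se)) {
    inform(paste0(sum(is.na(out$se)), " group(s) of size 1: s.e. reported as NA"))
  }
  out$measure <- measure
  out$grouping <- paste(groups, collapse = ":")
  for (g in setdiff(c("tissue", "sex", "age_group"), names(out))) {
    out[[g]] <- NA_character_
  }
  dplyr::select(out, "measure", "grouping", "tissue", "sex", "age_group",
                "n", "mean", "se", "min", "max")
}

#' Run the full methylation + telomere analysis
#'
#' Orchestrates the end-to-end analysis: simulate (or load) paired RAD/EpiRAD
#' counts, metadata and telomere medians; CPM-normalize; retain loci at the
#' CPM threshold; call methylation by zero reads; summarize proportions;
#' compare tissues by Welch t-tests; fit and AICc-rank the age/sex and
#' fin-gonad model ladders; classify differential loci, count shared statuses
#' per tissue-sex group and per-individual fin-gonad concordance; ordinate
#' the binary calls by classical MDS; and re-run the retention filter at the
#' sensitivity thresholds.  When `out_dir` is given, every intermediate table
#' is persisted (TSV/CSV) together with a JSON report, so any stage can be
#' audited or re-run.
#'
#' @param config A [sim_config()] for synthetic input.  Exactly one of
#'   `config` and `input` must be supplied.
#' @param input A named list of paths for real input: `rad`, `epirad`, `meta`
#'   (CSV with library metadata) and optionally `telomeres`.
#' @param out_dir Output directory for artifacts (created if needed);
#'   `NULL` keeps everything in memory.
#' @param threshold Main CPM retention threshold (default 15).
#' @param sensitivity_thresholds Additional thresholds for the sensitivity
#'   table (default 7 and 21).
#' @param axes Number of ordination axes (default 2).
#' @param seed Optional seed overriding the config seed.
#' @return A list of class `epirad_report`; see the `$` components
#'   (`proportions`, `summaries`, `t_tests`, `models`, `shared`,
#'   `concordance`, `ordination`, `sensitivity`, `provenance`, ...).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_loci = 400,
#'                   mean_library_size = c(RAD = 2e5, EpiRAD = 2e5))
#' rep <- run_epirad_pipeline(cfg)
#' rep$summaries
#' }
#' @export
run_epirad_pipeline <- function(config = NULL, input = NULL, out_dir = NULL,
                                threshold = 15,
                                sensitivity_thresholds = c(7, 21),
                                axes = 2, seed = NULL) {
  if (is.null(config) == is.null(input)) {
    abort("supply exactly one of `config` (synthetic) or `input` (file paths)")
  }
  if (threshold <= 0) abort("`threshold` must be > 0")

  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    if (!is.null(seed)) config$seed <- as.integer(seed)
    stage("simulate", {
      sim <- simulate_epirad_experiment(config)
    })
    meta <- sim$meta; counts <- sim$counts; telomeres <- sim$telomeres
  } else {
    needed <- c("rad", "epirad", "meta")
    if (!all(needed %in% names(input))) {
      abort("`input` needs paths named rad, epirad and meta")
    }
    stage("load", {
      meta <- read_sample_meta(input$meta)
      counts <- list(rad = read_count_matrix(input$rad),
                     epirad = read_count_matrix(input$epirad))
      telomeres <- if (!is.null(input$telomeres)) {
        read_telomere_table(input$telomeres)
      }
    })
    sim <- NULL
  }

  stage("call-methylation", {
    cpm_rad <- cpm_normalize(counts$rad)
    filt <- filter_loci(cpm_rad, threshold = threshold)
    calls <- call_methylation(counts$epirad, filt, meta)
    proportions <- methylation_proportion(calls, meta)
  })

  stage("sensitivity", {
    sens <- threshold_sensitivity(
      counts$rad, counts$epirad, meta,
      thresholds = sort(unique(c(sensitivity_thresholds, threshold))))
  })

  stage("summaries", {
    summaries <- summarize_proportions(proportions, telomeres, meta)
    prop_wide <- tidyr::pivot_wider(
      dplyr::select(proportions, "individual_id", "sex", "age_group",
                    "tissue", "proportion_pct"),
      names_from = "tissue", values_from = "proportion_pct",
      names_glue = "{tissue}_pct")
    t_tests <- list(
      methylation_fin_vs_gonad = welch_t_test(
        proportions$proportion_pct[proportions$tissue == "fin"],
        proportions$proportion_pct[proportions$tissue == "gonad"])
    )
    if (!is.null(telomeres)) {
      t_tests$telomere_fin_vs_gonad <- welch_t_test(
        telomeres$median_kb[telomeres$tissue == "fin"],
        telomeres$median_kb[telomeres$tissue == "gonad"])
    }
  })

  stage("models", {
    models <- list()
    ind_info <- dplyr::distinct(meta, .data$individual_id, .data$sex,
                                .data$age_group, .data$body_size_mm)
    for (tis in TISSUE_LEVELS) {
      d <- proportions[proportions$tissue == tis, ]
      models[[paste0("methylation_", tis)]] <-
        select_model(d, candidate_age_models("proportion_pct"))
    }
    models$methylation_fin_gonad <- select_model(
      prop_wide, candidate_fin_gonad_models("gonad_pct", "fin_pct"))
    if (!is.null(telomeres)) {
      tel <- dplyr::left_join(telomeres, ind_info, by = "individual_id",
                              suffix = c("", ".meta"))
      has_body <- "body_size_mm" %in% names(tel) && !anyNA(tel$body_size_mm)
      for (tis in TISSUE_LEVELS) {
        d <- tel[tel$tissue == tis, ]
        models[[paste0("telomere_", tis)]] <-
          select_model(d, candidate_age_models("median_kb",
                                               body_size = has_body))
      }
      tel_wide <- dplyr::left_join(telomere_pairs(telomeres),
                                   dplyr::distinct(ind_info,
                                                   .data$individual_id,
                                                   .data$sex),
                                   by = "individual_id",
                                   suffix = c("", ".meta"))
      models$telomere_fin_gonad <- select_model(
        tel_wide, candidate_fin_gonad_models("gonad_kb", "fin_kb"))
    }
    f_tests <- purrr::map(models, function(rank) {
      fits <- attr(rank, "fits")
      add <- fits[[which(rank$model == "additive")]]
      term_f_tests(add)
    })
  })

  stage("shared-loci", {
    locus_status <- differential_loci(calls)
    universe <- locus_status$locus_id[locus_status$status == "differential"]
    shared <- shared_status_counts(calls, tissue_sex_groups(meta), universe)
    concordance <- fin_gonad_concordance(calls, meta, universe)
  })

  stage("ordination", {
    ord <- classical_mds(binary_distance(calls, universe), k = axes)
  })

  report <- structure(
    list(
      meta = meta,
      telomeres = telomeres,
      filter = filt,
      calls = calls,
      proportions = proportions,
      sensitivity = sens,
      summaries = summaries,
      t_tests = t_tests,
      models = models,
      f_tests = f_tests,
      locus_status = locus_status,
      shared = shared,
      concordance = concordance,
      ordination = ord,
      truth = if (!is.null(sim)) sim$states,
      provenance = list(
        package_version = as.character(utils::packageVersion("epiradkit")),
        r_version = R.version.string,
        seed = if (!is.null(config)) config$seed,
        threshold = threshold,
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "epirad_report"
  )
  if (!is.null(out_dir)) write_report(report, counts, out_dir, config)
  report
}

stage <- function(name, code) {
  env <- parent.frame()
  res <- withCallingHandlers(
    eval(substitute(code), envir = env),
    error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    }
  )
  inform(paste0("[stage ", name, "] done (hash ",
                substr(rlang::hash(res %||% "ok"), 1, 8), ")"))
  invisible(res)
}

write_report <- function(report, counts, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_csv(report$meta, p("meta.csv"))
  write_count_matrix(counts$rad, p("rad_counts.tsv"))
  write_count_matrix(counts$epirad, p("epirad_counts.tsv"))
  if (!is.null(report$telomeres)) {
    readr::write_csv(report$telomeres, p("telomeres.csv"))
  }
  readr::write_tsv(report$filter, p("retained_loci.tsv"))
  write_count_matrix(report$calls, p("methylation_calls.tsv"))
  readr::write_csv(report$proportions, p("proportions.csv"))
  readr::write_csv(report$sensitivity, p("threshold_sensitivity.csv"))
  readr::write_csv(report$summaries, p("group_summaries.csv"))
  readr::write_csv(report$shared, p("shared_status.csv"))
  readr::write_csv(report$concordance$individuals, p("concordance.csv"))
  readr::write_csv(dplyr::bind_rows(
    purrr::imap(report$models, ~ dplyr::mutate(.x, analysis = .y))),
    p("model_selection.csv"))
  readr::write_csv(dplyr::bind_rows(
    purrr::imap(report$f_tests, ~ dplyr::mutate(.x, analysis = .y))),
    p("term_f_tests.csv"))
  readr::write_csv(report$ordination$points, p("mds_coordinates.csv"))
  readr::write_csv(
    tibble(axis = seq_along(report$ordination$percent_variance),
           percent_variance = report$ordination$percent_variance),
    p("mds_variance.csv"))
  if (!is.null(report$truth)) {
    readr::write_tsv(report$truth, p("true_states.tsv"))
  }
  if (!is.null(config)) write_sim_config(config, p("sim_config.yaml"))
  json <- list(
    provenance = report$provenance,
    summaries = report$summaries,
    t_tests = report$t_tests,
    model_selection = purrr::map(report$models, ~ .x),
    f_tests = report$f_tests,
    shared_status = report$shared,
    concordance = report$concordance$individuals,
    concordance_sex_intersection = report$concordance$sex_intersection,
    mds_percent_variance = report$ordination$percent_variance
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.epirad_report <- function(x, ...) {
  cat("<epirad_report>\n")
  cat(sprintf("  %d libraries, %d retained loci (threshold %s CPM)\n",
              nrow(x$meta), sum(x$filter$retained),
              format(x$provenance$threshold)))
  ts <- x$summaries[x$summaries$grouping == "tissue" &
                      x$summaries$measure == "methylation_pct", ]
  cat(sprintf("  methylation %% (mean +/- s.e.): %s\n",
              paste(sprintf("%s %.2f +/- %.2f", ts$tissue, ts$mean, ts$se),
                    collapse = ", ")))
  cat(sprintf("  differential loci: %d\n",
              sum(x$locus_status$status == "differential")))
  cat(sprintf("  MDS axes 1/2: %.1f%% / %.1f%%\n",
              x$ordination$percent_variance[1],
              x$ordination$percent_variance[2]))
  invisible(x)
}
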