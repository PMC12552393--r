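#' Simulate library metadata for a paired RAD/EpiRAD design
#'
#' Lays out the cross-sectional design described by a [sim_config()]: each
#' individual is assigned a sex and an age group, contributes two tissues
#' (fin, gonad), and each tissue yields one methylation-insensitive (RAD) and
#' one methylation-sensitive (EpiRAD) library.  Body sizes are drawn Normal
#' per sex and library sizes log-normal at the configured mean and coefficient
#' of variation.  All draws flow from the config seed, so the output is
#' reproducible.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per library: `library_id`, `sample_id`,
#'   `individual_id`, `sex`, `age_group`, `tissue`, `library_type`,
#'   `body_size_mm`, `library_size`.
#' @examples
#' meta <- simulate_metadata(sim_config())
#' nrow(meta)  # 128 libraries
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "meta"), {
    ages <- rep(AGE_LEVELS, times = config$age_group_sizes)
    sex <- unlist(lapply(seq_along(AGE_LEVELS), function(i) {
      nf <- config$females_by_age[i]
      n <- config$age_group_sizes[i]
      rep(SEX_LEVELS, times = c(nf, n - nf))
    }), use.names = FALSE)
    ind <- tibble(
      individual_id = sprintf("ind%02d", seq_len(config$n_individuals)),
      sex = sex,
      age_group = ages
    )
    ind$body_size_mm <- round(stats::rnorm(
      nrow(ind),
      mean = unname(config$body_mean_mm[ind$sex]),
      sd = config$body_sd_mm
    ), 1)

    meta <- tidyr::expand_grid(ind,
                               tissue = TISSUE_LEVELS,
                               library_type = c("RAD", "EpiRAD"))
    meta$sample_id <- paste(meta$individual_id, meta$tissue, sep = "_")
    meta$library_id <- paste(meta$sample_id, meta$library_type, sep = "_")

    mu <- unname(config$mean_library_size[meta$library_type])
    cv <- config$library_size_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      meta$library_size <- pmax(1, round(stats::rlnorm(
        nrow(meta), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)))
    } else {
      meta$library_size <- round(mu)
    }
    dplyr::select(meta, "library_id", "sample_id", "individual_id", "sex",
                  "age_group", "tissue", "library_type", "body_size_mm",
                  "library_size")
  })
}

#' Simulate ground-truth methylation states
#'
#' For every sample (individual x tissue) each locus is independently
#' designated methylated with the probability configured for the sample's
#' tissue, sex and age group; a methylated-designated locus then becomes only
#' partially methylated with probability `partial_frac`, its methylated cell
#' fraction `f` drawn uniformly on (0, 1).  States are 0 (unmethylated), 1
#' (fully methylated) or `f` in (0, 1) (partial).
#'
#' @param config A [sim_config()].
#' @param meta Metadata from [simulate_metadata()].
#' @return Wide tibble: `locus_id` plus one column per sample with the true
#'   state in \[0, 1\].
#' @export
simulate_methylation_states <- function(config, meta) {
  stopifnot(inherits(config, "sim_config"))
  samples <- dplyr::distinct(meta, .data$sample_id, .data$individual_id,
                             .data$sex, .data$age_group, .data$tissue)
  probs <- dplyr::left_join(samples, config$meth_prob,
                            by = c("tissue", "sex", "age_group"))
  if (anyNA(probs$prob)) {
    abort("no methylation probability configured for some (tissue, sex, age_group) combination")
  }
  n <- config$n_loci
  with_seed(stage_seed(config$seed, "states"), {
    cols <- lapply(seq_len(nrow(probs)), function(i) {
      full <- stats::rbinom(n, 1L, probs$prob[i])
      state <- as.numeric(full)
      idx <- which(full == 1L)
      if (length(idx) && config$partial_frac > 0) {
        conv <- idx[stats::runif(length(idx)) < config$partial_frac]
        state[conv] <- stats::runif(length(conv))
      }
      state
    })
    names(cols) <- probs$sample_id
    dplyr::bind_cols(tibble(locus_id = locus_ids(n)), as_tibble(cols))
  })
}

locus_ids <- function(n) sprintf("L%05d", seq_len(n))

#' Simulate paired RAD/EpiRAD read counts
#'
#' Per-locus capture propensities are drawn once from a Gamma distribution
#' (mean 1) and shared between a sample's RAD and EpiRAD libraries, emulating
#' the common capture bias of two digests of one DNA aliquot.  RAD reads are a
#' multinomial draw of the library size over the propensities; in the EpiRAD
#' library a fully methylated locus contributes zero propensity (the
#' methylation-sensitive enzyme cannot cut) and a partially methylated locus
#' retains `partial_retention * (1 - f)` of its propensity, proportional to
#' its unmethylated cell fraction.
#'
#' @param states Truth matrix from [simulate_methylation_states()].
#' @param meta Metadata from [simulate_metadata()].
#' @param config The same [sim_config()].
#' @return A list with wide count tibbles `rad` and `epirad` (`locus_id` plus
#'   one column per library), and `propensity`, the per-locus base propensity.
#' @export
simulate_read_counts <- function(states, meta, config) {
  stopifnot(inherits(config, "sim_config"))
  smat <- wide_to_matrix(states)
  if (nrow(smat) != config$n_loci) {
    abort("`states` does not match `config$n_loci`")
  }
  with_seed(stage_seed(config$seed, "counts"), {
    shape <- config$locus_propensity_shape
    q <- stats::rgamma(config$n_loci, shape = shape, rate = shape)

    draw <- function(lib) {
      s <- smat[, lib$sample_id]
      w <- if (lib$library_type == "RAD") {
        q
      } else {
        keep <- ifelse(s >= 1, 0,
                       ifelse(s > 0, config$partial_retention * (1 - s), 1))
        q * keep
      }
      if (sum(w) <= 0) {
        abort(paste0("library '", lib$library_id,
                     "' has no unmethylated loci to sequence; ",
                     "cannot draw EpiRAD reads"))
      }
      stats::rmultinom(1, size = lib$library_size, prob = w)[, 1]
    }

    # RAD libraries are drawn before EpiRAD ones so the RAD stream is
    # bit-identical whatever the methylation states
    ord <- order(meta$library_type != "RAD")
    cols <- lapply(ord, function(i) draw(meta[i, ]))
    names(cols) <- meta$library_id[ord]
    cols <- cols[meta$library_id]
    counts <- dplyr::bind_cols(tibble(locus_id = rownames(smat)),
                               as_tibble(cols))
    rad_ids <- meta$library_id[meta$library_type == "RAD"]
    epi_ids <- meta$library_id[meta$library_type == "EpiRAD"]
    list(
      rad = counts[, c("locus_id", rad_ids)],
      epirad = counts[, c("locus_id", epi_ids)],
      propensity = tibble(locus_id = rownames(smat), propensity = q)
    )
  })
}

#' Simulate telomere-length medians with fin-gonad structure
#'
#' Fin telomere medians are Normal per sex and age group; gonad medians follow
#' `a + slope_b * fin + male_offset_kb * [male] + e` with Normal residuals,
#' the intercept `a` chosen so the expected female gonad mean equals the
#' female fin mean.  Non-positive draws are rejected and redrawn (bounded
#' retries).
#'
#' @param meta Metadata from [simulate_metadata()].
#' @param config A [sim_config()].
#' @return Tidy tibble: `individual_id`, `sex`, `age_group`, `tissue`,
#'   `median_kb` (two rows per individual).
#' @export
simulate_telomeres <- function(meta, config) {
  stopifnot(inherits(config, "sim_config"))
  ind <- dplyr::distinct(meta, .data$individual_id, .data$sex, .data$age_group)
  means <- dplyr::left_join(ind, config$fin_mean_kb, by = c("sex", "age_group"))
  if (anyNA(means$mean_kb)) {
    abort("no fin telomere mean configured for some (sex, age_group)")
  }
  mu_ref <- reference_fin_mean(config)
  a <- (1 - config$slope_b) * mu_ref

  draw_positive <- function(n, mean, sd, what) {
    x <- stats::rnorm(n, mean, sd)
    for (tries in seq_len(100)) {
      bad <- x <= 0
      if (!any(bad)) return(x)
      x[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
    }
    abort(paste0("could not draw positive ", what, " medians in 100 attempts"))
  }

  with_seed(stage_seed(config$seed, "telomeres"), {
    fin <- draw_positive(nrow(means), means$mean_kb, config$fin_sd_kb, "fin")
    gmean <- a + config$slope_b * fin +
      config$male_offset_kb * (means$sex == "M")
    gonad <- draw_positive(length(gmean), gmean, config$resid_sd_kb, "gonad")
    dplyr::bind_rows(
      dplyr::mutate(ind, tissue = "fin", median_kb = fin),
      dplyr::mutate(ind, tissue = "gonad", median_kb = gonad)
    ) |>
      dplyr::arrange(.data$individual_id, .data$tissue)
  })
}

# Expected female fin mean under the design (females-by-age weighting); falls
# back to the overall design mean in an all-male configuration.
reference_fin_mean <- function(config) {
  fm <- config$fin_mean_kb
  if (config$n_females > 0) {
    w <- config$females_by_age
    f <- fm[fm$sex == "F", ]
    f <- f[match(AGE_LEVELS, f$age_group), ]
    sum(w * f$mean_kb) / sum(w)
  } else {
    w_m <- config$age_group_sizes - config$females_by_age
    m <- fm[fm$sex == "M", ]
    m <- m[match(AGE_LEVELS, m$age_group), ]
    sum(w_m * m$mean_kb) / sum(w_m)
  }
}

#' Pivot a tidy telomere table to one row per individual
#'
#' @param telomeres Output of [simulate_telomeres()] (or any tidy table with
#'   `individual_id`, `tissue`, `median_kb`).
#' @return Tibble with `fin_kb` and `gonad_kb` columns.
#' @export
telomere_pairs <- function(telomeres) {
  tidyr::pivot_wider(telomeres,
                     names_from = "tissue", values_from = "median_kb",
                     names_glue = "{tissue}_kb")
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [simulate_metadata()],
#' [simulate_methylation_states()], [simulate_read_counts()] and
#' [simulate_telomeres()].
#'
#' @param config A [sim_config()].
#' @return List with `meta`, `states`, `counts` (list `rad`/`epirad`),
#'   `telomeres` and the `config` used.
#' @export
simulate_epirad_experiment <- function(config = sim_config()) {
  meta <- simulate_metadata(config)
  states <- simulate_methylation_states(config, meta)
  counts <- simulate_read_counts(states, meta, config)
  telomeres <- simulate_telomeres(meta, config)
  list(meta = meta, states = states, counts = counts, telomeres = telomeres,
       config = config)
}
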