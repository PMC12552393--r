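#' Configuration for the paired RAD/EpiRAD simulator
#'
#' Bundles every parameter of the synthetic-data generator: the cross-sectional
#' design (individuals, sexes, age groups), sequencing depth, the per-locus
#' capture-propensity model, the methylation-state model (full and partial
#' methylation), and the telomere fin-gonad model.  Defaults emulate a
#' cross-sectional killifish study: 32 individuals (15 females, 17 males)
#' sampled in three age groups (10/11/11, with females split 5/6/4 across
#' groups), two tissues (fin, gonad), one methylation-insensitive (RAD) and one
#' methylation-sensitive (EpiRAD) library per sample, and mean library sizes of
#' 3.76 and 4.45 million reads respectively.
#'
#' Methylation probabilities are supplied as the expected *called* proportion
#' (percent of loci with zero methylation-sensitive reads); the generator
#' converts them to full-methylation probabilities by dividing by
#' `1 - partial_frac`, so that downstream zero-read calling recovers the stated
#' values in expectation.  Defaults are fins 1.085/1.36/1.61 percent for
#' AGE1/AGE2/AGE3 (weighted mean exactly 1.36) and gonads 1.6 (females) and
#' 44.8/17 = 2.635 (males) percent (weighted mean exactly 2.15), matching the
#' tissue means the design targets.
#'
#' Telomere medians: fin ~ Normal(mean\[sex, age\], `fin_sd_kb`^2); gonad is an
#' affine function of fin with slope `slope_b`, an additive male offset
#' `male_offset_kb`, and Normal residual noise `resid_sd_kb`, with the
#' intercept chosen so the female gonad mean equals the female fin mean.
#'
#' @param n_individuals Number of individuals (each contributes 4 libraries).
#' @param n_females Number of females; the rest are males.
#' @param age_group_sizes Named integer vector (AGE1/AGE2/AGE3) summing to
#'   `n_individuals`.
#' @param females_by_age How the females split over age groups (sums to
#'   `n_females`); `NULL` spreads them proportionally.
#' @param n_loci Number of reference loci.
#' @param mean_library_size Named vector `c(RAD = , EpiRAD = )`, mean reads per
#'   library.
#' @param library_size_cv Coefficient of variation of library sizes.
#' @param locus_propensity_shape Gamma shape of the per-locus capture
#'   propensity (mean fixed at 1); smaller values give more uneven coverage.
#' @param meth_called_pct Tibble `(tissue, sex, age_group, called_pct)` of
#'   target called methylation proportions in percent; `NULL` uses the
#'   defaults described above.
#' @param partial_frac Probability a methylated-designated locus is only
#'   partially methylated (hemi-/non-uniformly methylated across cells).
#' @param partial_retention Fraction of EpiRAD capture propensity retained by
#'   a partially methylated locus, further scaled by its unmethylated cell
#'   fraction `1 - f`.
#' @param fin_mean_kb Tibble `(sex, age_group, mean_kb)` of fin telomere-median
#'   means; `NULL` uses defaults (F: 7.8/6.9/7.7, M: 7.4/6.5/7.3 kb).
#' @param fin_sd_kb Fin telomere-median standard deviation (kb).
#' @param slope_b Fin-to-gonad telomere slope.
#' @param male_offset_kb Additive male offset of gonad telomere length (kb).
#' @param resid_sd_kb Residual standard deviation of the gonad model (kb).
#' @param body_mean_mm,body_sd_mm Body-size (standard length) Normal
#'   parameters per sex; body size is an optional model covariate only.
#' @param seed Integer seed driving all stages deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_loci = 500, mean_library_size = c(RAD = 2e5, EpiRAD = 2e5))
#' cfg$n_individuals
#' @export
sim_config <- function(n_individuals = 32L,
                       n_females = 15L,
                       age_group_sizes = c(AGE1 = 10L, AGE2 = 11L, AGE3 = 11L),
                       females_by_age = NULL,
                       n_loci = 8000L,
                       mean_library_size = c(RAD = 3.76e6, EpiRAD = 4.45e6),
                       library_size_cv = 0.1,
                       locus_propensity_shape = 1.5,
                       meth_called_pct = NULL,
                       partial_frac = 0.1,
                       partial_retention = 0.8,
                       fin_mean_kb = NULL,
                       fin_sd_kb = 0.9,
                       slope_b = 0.97,
                       male_offset_kb = -1.36,
                       resid_sd_kb = 0.78,
                       body_mean_mm = c(F = 45, M = 50),
                       body_sd_mm = 4,
                       seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  n_females <- as.integer(n_females)
  if (n_individuals < 1L) abort("`n_individuals` must be >= 1")
  if (n_females < 0L || n_females > n_individuals) {
    abort("`n_females` must lie in [0, n_individuals]")
  }
  age_group_sizes <- as.integer(age_group_sizes)
  names(age_group_sizes) <- AGE_LEVELS
  if (any(age_group_sizes < 0L) || sum(age_group_sizes) != n_individuals) {
    abort("`age_group_sizes` must be non-negative and sum to `n_individuals`")
  }
  if (is.null(females_by_age)) {
    females_by_age <- default_females_by_age(n_individuals, n_females,
                                             age_group_sizes)
  }
  females_by_age <- as.integer(females_by_age)
  names(females_by_age) <- AGE_LEVELS
  if (sum(females_by_age) != n_females || any(females_by_age < 0L) ||
      any(females_by_age > age_group_sizes)) {
    abort("`females_by_age` must be non-negative, fit within the age groups, and sum to `n_females`")
  }
  if (n_loci < 1L) abort("`n_loci` must be >= 1")
  if (!all(c("RAD", "EpiRAD") %in% names(mean_library_size)) ||
      any(mean_library_size <= 0)) {
    abort("`mean_library_size` needs positive RAD and EpiRAD entries")
  }
  if (library_size_cv < 0) abort("`library_size_cv` must be >= 0")
  if (locus_propensity_shape <= 0) abort("`locus_propensity_shape` must be > 0")
  if (partial_frac < 0 || partial_frac >= 1) {
    abort("`partial_frac` must lie in [0, 1)")
  }
  if (partial_retention < 0 || partial_retention > 1) {
    abort("`partial_retention` must lie in [0, 1]")
  }
  if (is.null(meth_called_pct)) meth_called_pct <- default_meth_called_pct()
  meth_called_pct <- as_tibble(meth_called_pct)
  stopifnot(all(c("tissue", "sex", "age_group", "called_pct") %in%
                  names(meth_called_pct)))
  meth_prob <- meth_called_pct
  meth_prob$prob <- meth_prob$called_pct / 100 / (1 - partial_frac)
  if (any(meth_prob$prob < 0 | meth_prob$prob > 1)) {
    abort("methylation probabilities derived from `meth_called_pct` fall outside [0, 1]")
  }
  if (is.null(fin_mean_kb)) fin_mean_kb <- default_fin_mean_kb()
  fin_mean_kb <- as_tibble(fin_mean_kb)
  stopifnot(all(c("sex", "age_group", "mean_kb") %in% names(fin_mean_kb)))
  if (!is.finite(slope_b)) abort("`slope_b` must be finite")
  if (fin_sd_kb <= 0 || resid_sd_kb <= 0) {
    abort("`fin_sd_kb` and `resid_sd_kb` must be > 0")
  }

  structure(
    list(
      n_individuals = n_individuals,
      n_females = n_females,
      age_group_sizes = age_group_sizes,
      females_by_age = females_by_age,
      n_loci = as.integer(n_loci),
      mean_library_size = mean_library_size[c("RAD", "EpiRAD")],
      library_size_cv = library_size_cv,
      locus_propensity_shape = locus_propensity_shape,
      meth_called_pct = meth_called_pct,
      meth_prob = meth_prob,
      partial_frac = partial_frac,
      partial_retention = partial_retention,
      fin_mean_kb = fin_mean_kb,
      fin_sd_kb = fin_sd_kb,
      slope_b = slope_b,
      male_offset_kb = male_offset_kb,
      resid_sd_kb = resid_sd_kb,
      body_mean_mm = body_mean_mm,
      body_sd_mm = body_sd_mm,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Derive independent replicate seeds from one master seed
#'
#' For Monte-Carlo replicate studies, per-replicate seeds are drawn from a
#' single master-seeded stream rather than by arithmetic on consecutive
#' integers, so replicate RNG streams are as independent as the generator
#' allows.  Deterministic given `seed`.
#'
#' @param seed Master integer seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @examples
#' replicate_seeds(1, 3)
#' @export
replicate_seeds <- function(seed, n) {
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

default_females_by_age <- function(n_individuals, n_females, age_group_sizes) {
  if (n_individuals == 32L && n_females == 15L &&
      identical(unname(age_group_sizes), c(10L, 11L, 11L))) {
    # sacrifice schedule: 5+5, 6+5, 4+7 (females + males)
    return(c(AGE1 = 5L, AGE2 = 6L, AGE3 = 4L))
  }
  # proportional allocation with largest-remainder rounding, capped by group size
  raw <- n_females * age_group_sizes / n_individuals
  base <- pmin(floor(raw), age_group_sizes)
  left <- n_females - sum(base)
  ord <- order(raw - floor(raw), decreasing = TRUE)
  for (i in ord) {
    if (left == 0L) break
    room <- age_group_sizes[i] - base[i]
    add <- min(room, left)
    base[i] <- base[i] + add
    left <- left - add
  }
  stats::setNames(as.integer(base), AGE_LEVELS)
}

default_meth_called_pct <- function() {
  fins <- tidyr::expand_grid(tissue = "fin", sex = SEX_LEVELS,
                             age_group = AGE_LEVELS)
  fins$called_pct <- rep(c(1.085, 1.36, 1.61), times = 2)
  gonads <- tidyr::expand_grid(tissue = "gonad", sex = SEX_LEVELS,
                               age_group = AGE_LEVELS)
  gonads$called_pct <- rep(c(1.6, 44.8 / 17), each = 3)
  dplyr::bind_rows(fins, gonads)
}

default_fin_mean_kb <- function() {
  tibble(
    sex = rep(SEX_LEVELS, each = 3),
    age_group = rep(AGE_LEVELS, times = 2),
    mean_kb = c(7.8, 6.9, 7.7, 7.4, 6.5, 7.3)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  individuals: %d (%d F / %d M), age groups %s\n",
              x$n_individuals, x$n_females, x$n_individuals - x$n_females,
              paste(x$age_group_sizes, collapse = "/")))
  cat(sprintf("  loci: %d, mean library size RAD %.3g / EpiRAD %.3g (cv %.2f)\n",
              x$n_loci, x$mean_library_size[["RAD"]],
              x$mean_library_size[["EpiRAD"]], x$library_size_cv))
  cat(sprintf("  partial methylation: frac %.2f, retention %.2f\n",
              x$partial_frac, x$partial_retention))
  cat(sprintf("  telomeres: slope %.2f, male offset %.2f kb, resid sd %.2f kb\n",
              x$slope_b, x$male_offset_kb, x$resid_sd_kb))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read or write a simulator configuration as YAML
#'
#' Scalar fields map directly; the methylation and telomere tables are stored
#' as column lists.
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- config
  x$meth_prob <- NULL
  x$meth_called_pct <- as.list(config$meth_called_pct)
  x$fin_mean_kb <- as.list(config$fin_mean_kb)
  x$age_group_sizes <- as.list(config$age_group_sizes)
  x$females_by_age <- as.list(config$females_by_age)
  x$mean_library_size <- as.list(config$mean_library_size)
  x$body_mean_mm <- as.list(config$body_mean_mm)
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(
    n_individuals = x$n_individuals,
    n_females = x$n_females,
    age_group_sizes = unlist(x$age_group_sizes),
    females_by_age = unlist(x$females_by_age),
    n_loci = x$n_loci,
    mean_library_size = unlist(x$mean_library_size),
    library_size_cv = x$library_size_cv,
    locus_propensity_shape = x$locus_propensity_shape,
    meth_called_pct = as_tibble(x$meth_called_pct),
    partial_frac = x$partial_frac,
    partial_retention = x$partial_retention,
    fin_mean_kb = as_tibble(x$fin_mean_kb),
    fin_sd_kb = x$fin_sd_kb,
    slope_b = x$slope_b,
    male_offset_kb = x$male_offset_kb,
    resid_sd_kb = x$resid_sd_kb,
    body_mean_mm = unlist(x$body_mean_mm),
    body_sd_mm = x$body_sd_mm,
    seed = x$seed
  )
}
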