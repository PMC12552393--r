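test_that("CPM standardization matches its definition and conserves columns", {
  counts <- as_wide(matrix(c(15, 999985, 3, 199997), ncol = 2,
                           dimnames = list(c("La", "Lb"), c("lib1", "lib2"))))
  cpm <- cpm_normalize(counts)
  expect_equal(cpm$lib1[cpm$locus_id == "La"], 15)
  expect_equal(cpm$lib2[cpm$locus_id == "La"], 15)  # 3 / 200000 * 1e6

  # symmetry: equal counts give 1e6 / n_loci everywhere
  eq <- as_wide(matrix(7, nrow = 8, ncol = 3))
  expect_true(all(abs(as.matrix(cpm_normalize(eq)[-1]) - 1e6 / 8) < 1e-9))

  # conservation on arbitrary non-negative inputs
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(rpois(60, 20), nrow = 12)
    cs <- colSums(as.matrix(cpm_normalize(as_wide(m))[-1]))
    expect_equal(unname(cs), rep(1e6, 5), tolerance = 1e-9)
  }

  bad <- as_wide(matrix(c(1, 2, 0, 0), ncol = 2,
                        dimnames = list(NULL, c("ok", "empty_lib"))))
  expect_error(cpm_normalize(bad), "empty_lib")
  expect_error(cpm_normalize(as_wide(matrix(-1))), "non-negative")
})

test_that("retention filter applies the every-library CPM rule", {
  cpm <- as_wide(matrix(c(20, 14, 15, 16, 30, 15), ncol = 2,
                        dimnames = list(c("L1", "L2", "L3"), c("r1", "r2"))))
  filt <- filter_loci(cpm, threshold = 15)
  expect_equal(retained_loci(filt), c("L1", "L3"))

  expect_equal(length(retained_loci(filter_loci(cpm, threshold = 0))), 3)
  expect_warning(f_inf <- filter_loci(cpm, threshold = Inf), "no locus")
  expect_equal(length(retained_loci(f_inf)), 0)

  # threshold 0 still drops loci with zero reads in some library
  with_zero <- as_wide(matrix(c(0, 5, 10, 7), ncol = 2))
  expect_equal(length(retained_loci(filter_loci(with_zero, threshold = 0))), 1)
})

test_that("retained sets are monotone in the threshold on arbitrary inputs", {
  set.seed(99)
  suppressWarnings(for (i in 1:10) {
    cpm <- as_wide(matrix(rexp(200, rate = 1 / 15), nrow = 40))
    r7 <- retained_loci(filter_loci(cpm, 7))
    r15 <- retained_loci(filter_loci(cpm, 15))
    r21 <- retained_loci(filter_loci(cpm, 21))
    expect_true(all(r21 %in% r15))
    expect_true(all(r15 %in% r7))
  })
  # and invariant under library relabeling
  cpm <- as_wide(matrix(rexp(100, 1 / 20), nrow = 20))
  shuffled <- cpm[, c("locus_id", sample(names(cpm)[-1]))]
  suppressWarnings(
    expect_equal(retained_loci(filter_loci(cpm, 15)),
                 retained_loci(filter_loci(shuffled, 15))))
})

test_that("zero-read calling is strict and scale invariant", {
  counts <- as_wide(matrix(c(0, 1, 25, 0, 0, 3), ncol = 2,
                           dimnames = list(c("L1", "L2", "L3"),
                                           c("s1", "s2"))))
  calls <- call_methylation(counts, c("L1", "L2", "L3"))
  expect_equal(calls$s1, c(1L, 0L, 0L))  # a single read is unmethylated
  expect_equal(calls$s2, c(1L, 1L, 0L))

  # multiplying a library's counts by a positive integer changes nothing
  scaled <- counts
  scaled$s2 <- scaled$s2 * 7L
  expect_identical(call_methylation(scaled, c("L1", "L2", "L3")), calls)

  sub <- call_methylation(counts, c("L3", "L1"))
  expect_equal(sub$locus_id, c("L3", "L1"))
  expect_error(call_methylation(counts, c("L1", "L9")), "absent")
  expect_error(call_methylation(counts, character(0)), "empty retained")
})

test_that("calling requires paired RAD/EpiRAD libraries in the metadata", {
  cfg <- tiny_config()
  sim <- simulate_epirad_experiment(cfg)
  filt <- filter_loci(cpm_normalize(sim$counts$rad), 15)
  calls <- call_methylation(sim$counts$epirad, filt, sim$meta)
  expect_setequal(names(calls)[-1], unique(sim$meta$sample_id))

  broken <- sim$meta[!(sim$meta$sample_id == sim$meta$sample_id[1] &
                         sim$meta$library_type == "RAD"), ]
  expect_error(call_methylation(sim$counts$epirad, filt, broken), "paired")
})

test_that("calls match the generating truth when there is no partial methylation", {
  run_error_rate <- function(depth) {
    cfg <- sim_config(n_loci = 800, partial_frac = 0,
                      meth_called_pct = flat_called_pct(2),
                      mean_library_size = c(RAD = depth, EpiRAD = depth),
                      seed = 31)
    sim <- simulate_epirad_experiment(cfg)
    filt <- filter_loci(cpm_normalize(sim$counts$rad), 15)
    calls <- call_methylation(sim$counts$epirad, filt, sim$meta)
    truth <- as.matrix(sim$states[-1])[match(calls$locus_id, sim$states$locus_id), ]
    mean(as.matrix(calls[-1]) != truth[, names(calls)[-1]])
  }
  shallow <- run_error_rate(4e4)
  deep <- run_error_rate(4e5)
  expect_lte(deep, shallow)
  expect_lt(deep, 0.01)
})

test_that("methylation proportions are exact percentages of retained loci", {
  calls <- as_wide(matrix(0L, nrow = 7841, ncol = 2,
                          dimnames = list(sprintf("L%04d", 1:7841),
                                          c("sA", "sB"))))
  calls$sA[1:118] <- 1L
  prop <- methylation_proportion(calls)
  expect_equal(prop$proportion_pct[prop$sample_id == "sA"], 100 * 118 / 7841)
  expect_equal(round(prop$proportion_pct[prop$sample_id == "sA"], 3), 1.505)
  expect_equal(prop$proportion_pct[prop$sample_id == "sB"], 0)
  expect_equal(prop$n_retained, c(7841L, 7841L))

  all1 <- as_wide(matrix(1L, nrow = 10, ncol = 1))
  expect_equal(methylation_proportion(all1)$proportion_pct, 100)
  empty <- tibble::tibble(locus_id = character(0), s1 = numeric(0))
  expect_error(methylation_proportion(empty), "undefined")
})

test_that("differential loci are exactly those whose calls vary", {
  m <- matrix(c(0, 0, 0,
                1, 1, 1,
                0, 1, 0,
                1, 0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("L", 1:4), paste0("s", 1:3)))
  cls <- differential_loci(as_wide(m))
  expect_equal(cls$status,
               c("uniform_unmethylated", "uniform_methylated",
                 "differential", "differential"))
  expect_equal(differential_universe(as_wide(m)), c("L3", "L4"))

  # uniform + differential partition the call set
  set.seed(2)
  calls <- as_wide(matrix(rbinom(300, 1, 0.3), nrow = 30))
  cls <- differential_loci(calls)
  expect_equal(nrow(cls), 30)
  expect_true(all(table(cls$status) >= 0))
})

test_that("shared-status counting enumerates uniform loci within groups", {
  m <- matrix(c(0, 0, 0,
                1, 1, 1,
                0, 1, 0,
                1, 0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("L", 1:4), paste0("s", 1:3)))
  calls <- as_wide(m)
  out <- shared_status_counts(calls, list(g12 = c("s1", "s2")))
  expect_equal(out$n_universe, 2)
  expect_equal(out$n_uniform_unmethylated, 0)
  expect_equal(out$n_uniform_methylated, 0)

  # a single-sample group is uniform at every universe locus
  out1 <- shared_status_counts(calls, list(solo = "s1"))
  expect_equal(out1$n_uniform_unmethylated + out1$n_uniform_methylated,
               out1$n_universe)

  expect_error(shared_status_counts(calls, list(bad = c("s1", "nope"))),
               "unknown samples")
  expect_error(shared_status_counts(calls, list(empty = character(0))), "empty")
})

test_that("fin-gonad concordance counts loci methylated in both tissues", {
  m <- matrix(c(1, 1,
                1, 0,
                0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3),
                              c("ind01_fin", "ind01_gonad")))
  # add a second individual so all three loci are differential
  m <- cbind(m, ind02_fin = c(0, 1, 1), ind02_gonad = c(0, 0, 1))
  calls <- as_wide(m)
  meta <- tidyr::expand_grid(individual_id = c("ind01", "ind02"),
                             tissue = c("fin", "gonad"))
  meta$sex <- ifelse(meta$individual_id == "ind01", "F", "M")
  meta$sample_id <- paste(meta$individual_id, meta$tissue, sep = "_")

  conc <- fin_gonad_concordance(calls, meta)
  i1 <- conc$individuals[conc$individuals$individual_id == "ind01", ]
  expect_equal(i1$n_shared_methylated, 1L)
  expect_equal(round(i1$pct_of_universe, 1), 33.3)
  expect_equal(conc$individuals$n_shared_methylated[2], 1L)  # ind02 shares L3

  # fin calls all zero give zero shared
  zero <- calls
  zero$ind01_fin <- 0L
  conc0 <- fin_gonad_concordance(zero, meta,
                                 universe = differential_universe(calls))
  expect_equal(conc0$individuals$n_shared_methylated[1], 0L)

  # a missing tissue is skipped with a warning
  expect_warning(
    fin_gonad_concordance(calls[, 1:4], meta[meta$sample_id != "ind02_gonad", ],
                          universe = c("L1", "L2", "L3")),
    "skipping")
})

test_that("threshold sensitivity reports per-sample deltas across thresholds", {
  cfg <- small_config()
  sim <- simulate_epirad_experiment(cfg)
  sens <- threshold_sensitivity(sim$counts$rad, sim$counts$epirad, sim$meta)
  expect_setequal(names(sens),
                  c("sample_id", "pct_at_7", "pct_at_15", "pct_at_21",
                    "max_abs_delta"))
  expect_equal(nrow(sens), 64)
  expect_true(all(sens$max_abs_delta >= 0))
  expect_equal(sens$max_abs_delta,
               pmax(sens$pct_at_7, sens$pct_at_15, sens$pct_at_21) -
                 pmin(sens$pct_at_7, sens$pct_at_15, sens$pct_at_21))
})
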