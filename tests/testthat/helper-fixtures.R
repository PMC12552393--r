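# Small configurations and hand-built matrices used across tests.

# A fast, shallow configuration for unit tests: the design is the full
# 32-individual layout but with few loci and small libraries.
small_config <- function(..., seed = 42L) {
  sim_config(
    n_loci = 400L,
    mean_library_size = c(RAD = 1.5e5, EpiRAD = 1.8e5),
    seed = seed,
    ...
  )
}

# A tiny two-individual design for structural tests.
tiny_config <- function(..., seed = 7L) {
  sim_config(
    n_individuals = 2L, n_females = 1L,
    age_group_sizes = c(AGE1 = 1L, AGE2 = 1L, AGE3 = 0L),
    n_loci = 50L,
    mean_library_size = c(RAD = 2e4, EpiRAD = 2e4),
    seed = seed,
    ...
  )
}

# Wide count/call tibble from a plain matrix with default ids.
as_wide <- function(m, prefix = "s") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out$locus_id <- rownames(m)
  out[, c("locus_id", setdiff(names(out), "locus_id"))]
}

# Uniform methylation probability across tissues/sexes/ages, expressed as the
# called percentage the generator targets.
flat_called_pct <- function(pct) {
  g <- tidyr::expand_grid(tissue = c("fin", "gonad"), sex = c("F", "M"),
                          age_group = c("AGE1", "AGE2", "AGE3"))
  g$called_pct <- pct
  g
}
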