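# Internal helpers shared across modules.

AGE_LEVELS <- c("AGE1", "AGE2", "AGE3")
SEX_LEVELS <- c("F", "M")
TISSUE_LEVELS <- c("fin", "gonad")

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic per-stage seed derived from one global seed, so a stage can be
# regenerated independently.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(meta = 1L, states = 2L, counts = 3L, telomeres = 4L, extra = 5L)
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown seed stage '", stage, "'"))
  }
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]] * 104729) %%
               (.Machine$integer.max - 1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Wide count/call tibble (locus_id + one numeric column per library/sample)
# to plain matrix with locus_id rownames.
wide_to_matrix <- function(tbl, id_col = "locus_id") {
  stopifnot(is.data.frame(tbl), id_col %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- as.character(tbl[[id_col]])
  storage.mode(m) <- "double"
  m
}

matrix_to_wide <- function(m, id_col = "locus_id") {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[, c(id_col, setdiff(names(out), id_col))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
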