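#' Read and write pipeline tables
#'
#' Count matrices travel as tab-separated files whose first column is
#' `locus_id` and whose remaining columns are one library (or sample) each;
#' metadata and telomere tables as CSV.  These wrap readr with the column
#' types the pipeline expects.
#'
#' @param path File path.
#' @return A tibble in the layout the corresponding stage consumes.
#' @export
read_count_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(locus_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' @rdname read_count_matrix
#' @param x Table to write.
#' @export
write_count_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname read_count_matrix
#' @export
read_sample_meta <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_count_matrix
#' @export
read_telomere_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
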