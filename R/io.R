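#' Write a count matrix as TSV (feature ids in the first column)
#' @param counts Matrix or data frame of counts.
#' @param path Output path.
#' @param id_name Name for the feature-id column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_count_matrix_tsv <- function(counts, path, id_name = "feature_id") {
  m <- as_count_matrix(counts)
  df <- tibble::as_tibble(m, rownames = id_name)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path TSV path; first column = feature ids, remaining columns =
#'   samples.
#' @return Integer matrix with feature-id rownames.
#' @export
read_count_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_count_matrix(as.data.frame(df))
}

#' Read a two-column sample-to-group table from TSV
#' @param path TSV with columns `sample_id` and `group`.
#' @return Tibble.
#' @export
read_groups_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read a miRNA-to-target map from TSV
#' @param path TSV with columns `mirna_id` and `gene_id`.
#' @return Tibble.
#' @export
read_target_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read a clinical table from TSV
#' @param path TSV with columns `sample_id`, `label`, `expression`, `time`,
#'   `event` (extra columns kept).
#' @return Tibble.
#' @export
read_clinical_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
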