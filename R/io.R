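#' Write a cohort to plain-text files
#'
#' Writes the feature table (`features.csv`: sample id index column, one column
#' per VOC feature, empty cell = not detected), sample metadata
#' (`metadata.csv`: sample id, class, batch), feature metadata
#' (`feature_meta.csv`), and ground truth (`truth.json`). The set round-trips
#' losslessly through [read_cohort()].
#'
#' @param cohort A `breath_cohort` (or a bare feature-table tibble, in which
#'   case no truth/feature files are written).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  table <- if (inherits(cohort, "breath_cohort")) cohort$table else cohort
  feats <- feature_cols(table)
  readr::write_csv(table[c("sample_id", feats)], file.path(dir, "features.csv"),
                   na = "")
  readr::write_csv(table[META_COLS], file.path(dir, "metadata.csv"))
  if (inherits(cohort, "breath_cohort")) {
    readr::write_csv(cohort$features, file.path(dir, "feature_meta.csv"))
    truth <- cohort$truth
    truth$marker_signs <- as.list(truth$marker_signs)  # keep names in JSON
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Empty cells in the feature CSV are read back as missing (not detected),
#' never as zero.
#'
#' @param dir Directory containing `features.csv` and `metadata.csv`
#'   (optionally `feature_meta.csv`, `truth.json`).
#' @return A `breath_cohort` if ground truth is present, otherwise a feature
#'   table tibble.
#' @export
read_cohort <- function(dir) {
  values <- readr::read_csv(file.path(dir, "features.csv"), na = "",
                            show_col_types = FALSE)
  meta <- readr::read_csv(file.path(dir, "metadata.csv"), show_col_types = FALSE)
  meta$class <- check_classes(meta$class)
  meta$batch <- factor(meta$batch)
  table <- dplyr::left_join(meta, values, by = "sample_id")
  attr(table, "spec") <- NULL
  attr(table, "problems") <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(truth_path)) return(table)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  truth$marker_signs <- setNames(as.numeric(truth$marker_signs),
                                 names(truth$marker_signs))
  truth$effect_sizes <- as.matrix(truth$effect_sizes)
  features <- readr::read_csv(file.path(dir, "feature_meta.csv"),
                              show_col_types = FALSE)
  structure(list(table = table, features = features, truth = truth, spec = NULL),
            class = "breath_cohort")
}
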