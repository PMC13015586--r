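#' Bundled demographic summaries from a four-cohort tobacco/opioid study
#'
#' Printed per-group summary statistics and categorical counts from a
#' published four-cohort (never / former / current tobacco use, and combined
#' tobacco + opioid use) effort-task study, bundled so the summary-statistics
#' stage can be exercised and checked without raw participant data.
#'
#' `demo_group_sizes()` gives analyzed sample sizes per cohort;
#' `demo_age_summaries()` gives age mean/SD/n per cohort (means and SDs as
#' printed, to one decimal); `demo_sex_counts()` and `demo_race_counts()` give
#' the categorical count tables (rows = category, columns = cohort).
#'
#' @return See each function's description.
#' @name bundled_tables
NULL

cohort_labels <- function() c("NeverTUD", "FormerTUD", "CurrentTUD", "TUD_OUD")

#' @rdname bundled_tables
#' @export
demo_group_sizes <- function() {
  setNames(c(23L, 22L, 26L, 29L), cohort_labels())
}

#' @rdname bundled_tables
#' @export
demo_age_summaries <- function() {
  data.frame(label = cohort_labels(), n = c(23L, 22L, 26L, 29L),
             mean = c(28.7, 38.5, 41.8, 30.5), sd = c(8.9, 8.3, 10.2, 6.0))
}

#' @rdname bundled_tables
#' @export
demo_sex_counts <- function() {
  m <- rbind(F = c(12, 11, 18, 11), M = c(11, 11, 8, 18))
  colnames(m) <- cohort_labels()
  m
}

#' @rdname bundled_tables
#' @export
demo_race_counts <- function() {
  m <- rbind(Asian = c(5, 1, 0, 0),
             AmericanIndian = c(0, 0, 0, 1),
             Black = c(8, 4, 16, 1),
             White = c(10, 17, 10, 26),
             Other = c(0, 0, 0, 1))
  colnames(m) <- cohort_labels()
  m
}

#' Published LOOCV LDA confusion matrix
#'
#' The leave-one-out cross-validated LDA confusion matrix (predicted rows,
#' actual columns) reported for the four cohorts, bundled as input for the
#' classification-metric stage.
#'
#' @return A 4 x 4 count matrix.
#' @export
published_confusion_matrix <- function() {
  m <- rbind(c(13, 0, 3, 0),
             c(0, 20, 2, 1),
             c(10, 1, 21, 0),
             c(0, 1, 0, 28))
  dimnames(m) <- list(predicted = cohort_labels(), actual = cohort_labels())
  m
}
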