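#' Confusion-matrix vocabularies
#'
#' Truth rows follow the biopsy grading vocabulary (Group 1 non-neoplastic
#' through Group 5 carcinoma, Group X inadequate, plus the non-epithelial
#' lymphoma and carcinoid rows); prediction columns are the system classes
#' P (Positive), A (Adenoma), N (Negative), X (Unclassifiable).
#'
#' @name confusion_vocab
#' @export
truth_groups <- function() c("Group5", "lymphoma", "carcinoid", "Group4",
                             "Group3", "Group2", "Group1", "GroupX")

#' @rdname confusion_vocab
#' @export
prediction_classes <- function() c("P", "A", "N", "X")

#' Build a truth-by-prediction confusion matrix
#'
#' @param truth character vector of diagnosis labels (see [truth_groups()]).
#' @param predictions character vector of system classes (`P/A/N/X`, or the
#'   long forms `Positive/Adenoma/Negative/Unclassifiable`).
#' @return object of class `confusion_matrix`: integer `counts`
#'   (8 truth rows x 4 prediction columns) and `n_all`.
#' @export
build_matrix <- function(truth, predictions) {
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length")
  long <- c(Positive = "P", Adenoma = "A", Negative = "N",
            Unclassifiable = "X")
  predictions <- ifelse(predictions %in% names(long),
                        long[predictions], predictions)
  bad <- setdiff(unique(truth), truth_groups())
  if (length(bad)) stop("unknown truth label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(predictions), prediction_classes())
  if (length(bad)) stop("unknown prediction(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(truth, levels = truth_groups()),
                  factor(predictions, levels = prediction_classes()))
  counts <- matrix(as.integer(counts), nrow = 8, ncol = 4,
                   dimnames = list(truth_groups(), prediction_classes()))
  structure(list(counts = counts, n_all = length(truth)),
            class = "confusion_matrix")
}

#' Assemble a confusion matrix directly from counts
#' @param counts 8 x 4 matrix with [truth_groups()] rows and
#'   [prediction_classes()] columns (reordered if named).
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  if (!is.null(rownames(counts))) counts <- counts[truth_groups(), , drop = FALSE]
  if (!is.null(colnames(counts))) counts <- counts[, prediction_classes(), drop = FALSE]
  stopifnot(nrow(counts) == 8, ncol(counts) == 4, all(counts >= 0))
  m <- matrix(as.integer(counts), 8, 4,
              dimnames = list(truth_groups(), prediction_classes()))
  structure(list(counts = m, n_all = sum(m)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat("n_all =", x$n_all, "\n")
  invisible(x)
}

#' Read / write a confusion matrix as CSV
#'
#' CSV layout: a `group` column plus `P,A,N,X` count columns, one row per
#' truth group.
#'
#' @param path CSV file.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, prediction_classes()])
  rownames(m) <- df$group
  as_confusion_matrix(m)
}

#' @rdname read_confusion_csv
#' @param cm a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(group = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged two-hospital evaluation confusion matrices
#'
#' The published confusion matrices of a two-hospital routine-practice
#' evaluation of an automated colorectal biopsy screening system, shipped
#' as fixtures (`hospital`: `"tokyo"`, n = 1077, or `"east"`, n = 251).
#'
#' @param hospital which cohort.
#' @return a `confusion_matrix`.
#' @export
hospital_confusion <- function(hospital = c("tokyo", "east")) {
  hospital <- match.arg(hospital)
  read_confusion_csv(system.file("extdata",
                                 paste0("confusion_", hospital, ".csv"),
                                 package = "glandscreen", mustWork = TRUE))
}

# Shared denominator guard.
index_pct <- function(num, den, strict, what) {
  num <- as.numeric(num); den <- as.numeric(den)
  if (den == 0) {
    if (strict) stop("undefined index: no ", what, " tissues (zero denominator)")
    return(NA_real_)
  }
  round_half_up(num / den * 100, 1)
}

#' Screening error indices
#'
#' The three screening indices, reported as percentages rounded half-up to
#' one decimal:
#' \itemize{
#'   \item undetected rate of carcinoma = (n(A|G5) + n(N|G5)) / n(G5) x 100,
#'     with G5 the Group 5 row only (lymphoma/carcinoid are separate rows
#'     and excluded);
#'   \item undetected rate of adenoma = n(N|G3) / n(G3) x 100;
#'   \item over-detected proportion = (n(P|G3) + n(P|G1) + n(A|G1) +
#'     n(X|G3) + n(X|G1)) / n(ALL) x 100, where n(ALL) counts every row.
#' }
#'
#' @param cm a `confusion_matrix`.
#' @param strict error on a zero denominator (default); otherwise `NA`.
#' @return percentage in `[0, 100]` (or `NA` when undefined and
#'   `strict = FALSE`).
#' @export
undetected_rate_carcinoma <- function(cm, strict = TRUE) {
  g5 <- cm$counts["Group5", ]
  index_pct(g5["A"] + g5["N"], sum(g5), strict, "Group5")
}

#' @rdname undetected_rate_carcinoma
#' @export
undetected_rate_adenoma <- function(cm, strict = TRUE) {
  g3 <- cm$counts["Group3", ]
  index_pct(g3["N"], sum(g3), strict, "Group3")
}

#' @rdname undetected_rate_carcinoma
#' @export
over_detected_proportion <- function(cm, strict = TRUE) {
  ct <- cm$counts
  num <- ct["Group3", "P"] + ct["Group1", "P"] + ct["Group1", "A"] +
    ct["Group3", "X"] + ct["Group1", "X"]
  index_pct(num, cm$n_all, strict, "")
}

#' All three screening indices of a confusion matrix
#' @param cm a `confusion_matrix`.
#' @return named numeric vector (`NA` where a denominator is zero):
#'   `undetected_carcinoma_pct`, `undetected_adenoma_pct`,
#'   `over_detected_pct`.
#' @export
screening_indices <- function(cm) {
  c(undetected_carcinoma_pct = undetected_rate_carcinoma(cm, strict = FALSE),
    undetected_adenoma_pct = undetected_rate_adenoma(cm, strict = FALSE),
    over_detected_pct = over_detected_proportion(cm, strict = FALSE))
}

#' Evaluate a prediction run against a truth table
#'
#' Joins truth (`tissue_id,group`) and predictions
#' (`tissue_id,final_class`) by tissue id, builds the confusion matrix and
#' computes the three screening indices; indices with a zero denominator
#' are reported as `NA` (undefined), never as 0.
#'
#' @param truth data.frame or CSV path with `tissue_id`, `group`.
#' @param predictions data.frame or CSV path with `tissue_id`,
#'   `final_class`.
#' @param matrix_csv,report_json optional output paths.
#' @return list with `confusion` and `indices`.
#' @export
evaluate_run <- function(truth, predictions, matrix_csv = NULL,
                         report_json = NULL) {
  if (is.character(truth)) truth <- utils::read.csv(truth)
  if (is.character(predictions)) predictions <- utils::read.csv(predictions)
  stopifnot(all(c("tissue_id", "group") %in% names(truth)),
            all(c("tissue_id", "final_class") %in% names(predictions)))
  if (!setequal(truth$tissue_id, predictions$tissue_id) ||
      nrow(truth) != nrow(predictions))
    stop("tissue_id mismatch between truth and predictions")
  m <- merge(truth, predictions, by = "tissue_id")
  cm <- build_matrix(m$group, m$final_class)
  idx <- screening_indices(cm)
  if (!is.null(matrix_csv)) write_confusion_csv(cm, matrix_csv)
  if (!is.null(report_json))
    jsonlite::write_json(as.list(idx), report_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
  list(confusion = cm, indices = idx)
}
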