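#' Overall annotation accuracy
#'
#' @param truth,pred row-aligned character vectors of per-cell labels.
#' @return fraction of exact matches in \code{[0, 1]}.
#' @export
overall_accuracy <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("`truth` and `pred` lengths differ")
  if (!length(truth)) stop("empty label vectors")
  mean(as.character(truth) == as.character(pred))
}

#' Collapse all out-of-reference labels to a single "unseen" token
#'
#' Labels among the known reference types are kept; every other label —
#' ground-truth types absent from the reference, \code{novel_*} predictions,
#' and \code{unassigned} — maps to \code{"unseen"}. This is the label space in
#' which open-set accuracy and the unseen-type F1 are computed.
#'
#' @param labels per-cell labels (truth or predictions).
#' @param known character vector of reference cell-type names.
#' @return character vector over \code{known} plus \code{"unseen"}.
#' @export
map_to_unseen <- function(labels, known) {
  if (!length(known)) stop("`known` must be nonempty")
  labels <- as.character(labels)
  ifelse(labels %in% known, labels, "unseen")
}

#' Precision, recall and F1 for detecting unseen cells
#'
#' Binary evaluation with \code{"unseen"} as the positive class, applied to
#' label vectors already collapsed by [map_to_unseen()].
#'
#' @param truth_mapped,pred_mapped row-aligned collapsed label vectors.
#' @return named numeric vector \code{c(precision, recall, f1)}; zeros (with a
#'   warning) when there are neither positive truths nor positive predictions.
#' @export
unseen_f1 <- function(truth_mapped, pred_mapped) {
  if (length(truth_mapped) != length(pred_mapped)) stop("length mismatch")
  tpos <- truth_mapped == "unseen"
  ppos <- pred_mapped == "unseen"
  tp <- sum(tpos & ppos)
  fp <- sum(!tpos & ppos)
  fn <- sum(tpos & !ppos)
  if (tp + fp + fn == 0L) {
    warning("no unseen cells in truth or predictions; returning zeros")
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Confusion matrix with Hungarian-aligned columns
#'
#' Builds the raw truth-by-prediction count matrix, then reorders predicted
#' columns by the optimal injective assignment of predicted labels to true
#' labels (maximizing total matched cell count, solved as a linear sum
#' assignment problem), so that correct and corresponding novel annotations
#' concentrate on the diagonal. Predicted labels left unmatched are appended
#' to the right, largest first.
#'
#' @param truth,pred row-aligned per-cell label vectors.
#' @return a \code{"hicat_confusion"}: list with \code{counts} (rows = truth,
#'   columns = predictions in aligned order) and \code{alignment} (named
#'   character vector, predicted label -> true label).
#' @export
aligned_confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (!length(truth)) stop("empty label vectors")
  counts <- unclass(table(truth = as.character(truth), pred = as.character(pred)))
  nr <- nrow(counts)
  nc <- ncol(counts)
  # pad to square so the assignment is over max(nr, nc) slots
  m <- max(nr, nc)
  pad <- matrix(0, m, m)
  pad[seq_len(nr), seq_len(nc)] <- counts
  sol <- as.integer(clue::solve_LSAP(pad, maximum = TRUE))
  rows <- seq_len(nr)
  cols <- sol[rows]                      # truth row i -> predicted column
  # keep only real assignments: inside the matrix and carrying cells
  ok <- cols <= nc & counts[cbind(rows, pmin(cols, nc))] > 0
  rows <- rows[ok]
  cols <- cols[ok]
  rest <- setdiff(seq_len(nc), cols)
  rest <- rest[order(-colSums(counts)[rest], rest)]
  alignment <- stats::setNames(rownames(counts)[rows], colnames(counts)[cols])
  counts <- counts[, c(cols, rest), drop = FALSE]
  structure(list(counts = counts, alignment = alignment),
            class = "hicat_confusion")
}

#' @export
print.hicat_confusion <- function(x, ...) {
  cat("<hicat_confusion> truth x aligned predictions\n")
  print(x$counts)
  invisible(x)
}

#' Recall, precision and F1 for one true class in an aligned confusion matrix
#'
#' Uses the predicted column aligned to \code{class}: recall is the matched
#' count over the class's row total, precision the matched count over that
#' column's total. (In open-set reports these are sometimes called sensitivity
#' and — loosely — specificity; arithmetically they are recall and precision.)
#'
#' @param confusion a \code{"hicat_confusion"} from [aligned_confusion()].
#' @param class a true-label name present in the confusion rows.
#' @return named numeric vector \code{c(recall, precision, f1)}.
#' @export
per_class_metrics <- function(confusion, class) {
  stopifnot(inherits(confusion, "hicat_confusion"))
  counts <- confusion$counts
  if (!class %in% rownames(counts)) stop("class not present: ", class)
  col <- names(confusion$alignment)[confusion$alignment == class]
  if (!length(col))
    stop("no predicted column aligned to class: ", class)
  matched <- counts[class, col[1L]]
  recall <- matched / sum(counts[class, ])
  precision <- matched / sum(counts[, col[1L]])
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Full open-set evaluation of an annotation against ground truth
#'
#' @param annotation a \code{"hicat_annotation"} (or data.frame with
#'   \code{cell_id}, \code{final_label}).
#' @param truth data.frame with \code{cell_id} and the true label in the
#'   second column.
#' @param known character vector of reference cell-type names.
#' @return list with \code{accuracy_unseen} (unseen-collapsed overall
#'   accuracy), \code{unseen} (precision/recall/F1), \code{confusion}
#'   (aligned, on raw labels), and \code{per_class} metrics for each aligned
#'   true class.
#' @export
evaluate_annotation <- function(annotation, truth, known) {
  truth <- data.frame(cell_id = as.character(truth[[1L]]),
                      label = as.character(truth[[2L]]),
                      stringsAsFactors = FALSE)
  idx <- match(annotation$cell_id, truth$cell_id)
  if (anyNA(idx))
    stop("cells missing from truth: ",
         paste(utils::head(annotation$cell_id[is.na(idx)], 5L), collapse = ", "))
  tr <- truth$label[idx]
  pr <- annotation$final_label
  tr_m <- map_to_unseen(tr, known)
  pr_m <- map_to_unseen(pr, known)
  conf <- aligned_confusion(tr, pr)
  per_class <- lapply(stats::setNames(nm = unname(conf$alignment)), function(cl)
    per_class_metrics(conf, cl))
  list(accuracy_unseen = overall_accuracy(tr_m, pr_m),
       unseen = unseen_f1(tr_m, pr_m),
       confusion = conf,
       per_class = per_class)
}
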