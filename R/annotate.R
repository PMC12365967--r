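#' Train the multiclass gradient-boosted tree classifier
#'
#' Fits an xgboost multiclass model (softmax probabilities) on the
#' multi-resolution features of the labeled reference cells. The categorical
#' cluster column is one-hot encoded over the cluster levels observed when the
#' feature table was built; cluster IDs absent from that schema at prediction
#' time map to the all-zero encoding (an "unknown category").
#'
#' @param features a \code{"multires_features"} object restricted to (or
#'   containing) the reference cells.
#' @param labels a label table (data.frame with \code{cell_id}, \code{label});
#'   feature rows without a label are dropped with a warning.
#' @param iterations number of boosting rounds (default 500).
#' @param depth tree depth (default 6).
#' @param learning_rate shrinkage per round (default 0.1).
#' @param colsample_bynode fraction of features drawn at random for each
#'   split (default 0.5). Without it a strongly separable training set is
#'   fitted through a handful of greedy splits and the rest of the ensemble
#'   never contributes; per-split feature randomization spreads the model
#'   across the redundant resolutions, the same role the per-split score
#'   randomization plays in CatBoost's defaults.
#' @param min_cells_per_class warn when a class has fewer cells than this.
#' @param seed integer seed; fitting is single-threaded and deterministic.
#' @return a \code{"hicat_classifier"} with the fitted booster, ordered
#'   \code{class_names}, and the feature schema.
#' @export
train_classifier <- function(features, labels, iterations = 500L, depth = 6L,
                             learning_rate = 0.1, colsample_bynode = 0.5,
                             min_cells_per_class = 5L, seed = 0L) {
  stopifnot(inherits(features, "multires_features"))
  labels <- label_table(labels)
  idx <- match(features$cell_ids, labels$cell_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " cell(s) lack a label and are excluded from training")
    keep <- !is.na(idx)
    features <- subset_features(features, keep)
    idx <- idx[keep]
  }
  y <- labels$label[idx]
  class_names <- sort(unique(y))
  if (length(class_names) < 2L) stop("need >=2 reference cell types")
  small <- table(y)[table(y) < min_cells_per_class]
  if (length(small))
    warning("classes with fewer than ", min_cells_per_class, " cells: ",
            paste(names(small), collapse = ", "))
  cluster_levels <- levels(features$table$cluster)
  x <- encode_features(features$table, cluster_levels)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(class_names),
                  max_depth = as.integer(depth),
                  eta = learning_rate,
                  colsample_bynode = colsample_bynode,
                  nthread = 1L,
                  seed = as.integer(seed),
                  verbosity = 0L),
    data = xgboost::xgb.DMatrix(x, label = match(y, class_names) - 1L,
                                nthread = 1L),
    nrounds = as.integer(iterations),
    verbose = 0L
  )
  structure(list(booster = booster,
                 class_names = class_names,
                 numeric_features = setdiff(colnames(features$table), "cluster"),
                 cluster_levels = cluster_levels,
                 resolution_tags = features$resolution_tags,
                 params = list(iterations = as.integer(iterations),
                               depth = as.integer(depth),
                               learning_rate = learning_rate,
                               colsample_bynode = colsample_bynode,
                               seed = as.integer(seed)),
                 n_train = length(y)),
            class = "hicat_classifier")
}

# numeric block + one-hot cluster columns over a fixed level schema;
# values outside the schema encode as all zeros
encode_features <- function(table, cluster_levels) {
  num <- as.matrix(table[, setdiff(colnames(table), "cluster"), drop = FALSE])
  cl <- as.character(table$cluster)
  oh <- matrix(0, nrow(table), length(cluster_levels),
               dimnames = list(NULL, paste0("cluster=", cluster_levels)))
  hit <- match(cl, cluster_levels)
  ok <- !is.na(hit)
  oh[cbind(which(ok), hit[ok])] <- 1
  cbind(num, oh)
}

#' @export
print.hicat_classifier <- function(x, ...) {
  cat(sprintf("<hicat_classifier> %d classes, %d boosting rounds, depth %d, trained on %d cells\n",
              length(x$class_names), x$params$iterations, x$params$depth, x$n_train))
  invisible(x)
}

#' Per-cell class probabilities from a trained classifier
#'
#' @param model a \code{"hicat_classifier"}.
#' @param features a \code{"multires_features"} object with the training
#'   schema; cluster IDs unseen at training are tolerated.
#' @return list with \code{prob} (cells x K matrix, rows summing to 1),
#'   \code{label} (argmax class per cell) and \code{pmax} (max probability).
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "hicat_classifier"),
            inherits(features, "multires_features"))
  miss <- setdiff(model$numeric_features, colnames(features$table))
  if (length(miss))
    stop("feature schema mismatch; missing columns: ", paste(miss, collapse = ", "))
  x <- encode_features(features$table, model$cluster_levels)
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1L))
  if (is.null(dim(p)))
    p <- matrix(p, ncol = length(model$class_names), byrow = TRUE)
  colnames(p) <- model$class_names
  rownames(p) <- features$cell_ids
  k <- max.col(p, ties.method = "first")
  list(prob = p, label = model$class_names[k],
       pmax = p[cbind(seq_len(nrow(p)), k)])
}

#' Data-driven confidence threshold from the largest probability drop
#'
#' Pools the per-cell maximum class probabilities of reference and query
#' cells, sorts them in decreasing order, and places the threshold at the
#' midpoint of the largest consecutive drop (first such drop on ties). The
#' threshold is clipped into \code{[1/K, 1)}, the interval between the
#' low-confidence anchor (a flat K-class posterior) and certainty. When no
#' drop exceeds \code{min_gap} the threshold falls back to \code{1/K}.
#'
#' @param pmax_all numeric vector of max-class probabilities in (0, 1], pooled
#'   from reference and query cells with equal weight.
#' @param K number of reference classes.
#' @param min_gap smallest drop considered meaningful (default 1e-6).
#' @return a \code{"hicat_threshold"}: list with \code{threshold}, \code{K},
#'   \code{gap_location} (the bracketing probabilities), \code{gap},
#'   \code{fallback_used}.
#' @export
select_confidence_threshold <- function(pmax_all, K, min_gap = 1e-6) {
  if (!length(pmax_all)) stop("`pmax_all` must be nonempty")
  if (any(is.na(pmax_all)) || any(pmax_all <= 0) || any(pmax_all > 1))
    stop("`pmax_all` values must lie in (0, 1]")
  if (!is.numeric(K) || length(K) != 1L || K < 2) stop("`K` must be >= 2")
  p <- sort(pmax_all, decreasing = TRUE)
  n <- length(p)
  if (n >= 2L) {
    d <- p[-n] - p[-1L]
    i <- which.max(d)   # first index on ties = toward higher probabilities
    gap <- d[i]
  } else {
    gap <- 0
    i <- NA_integer_
  }
  if (is.na(i) || gap < min_gap) {
    return(structure(list(threshold = 1 / K, K = as.integer(K),
                          gap_location = c(NA_real_, NA_real_), gap = 0,
                          fallback_used = TRUE),
                     class = "hicat_threshold"))
  }
  thr <- (p[i] + p[i + 1L]) / 2
  thr <- min(max(thr, 1 / K), 1 - .Machine$double.eps)
  structure(list(threshold = thr, K = as.integer(K),
                 gap_location = c(p[i], p[i + 1L]), gap = gap,
                 fallback_used = FALSE),
            class = "hicat_threshold")
}

#' @export
print.hicat_threshold <- function(x, ...) {
  cat(sprintf("<hicat_threshold> %.4f (K = %d, largest drop %.4f%s)\n",
              x$threshold, x$K, x$gap,
              if (x$fallback_used) ", fallback to 1/K" else ""))
  invisible(x)
}

#' Fuse supervised predictions with cluster labels
#'
#' Applies the per-cell discrepancy-resolution rule: when the classifier's max
#' probability clears the confidence threshold its label is kept; otherwise the
#' cell takes its density cluster as a novel label (\code{novel_<id>}), or
#' \code{unassigned} if it is a noise point.
#'
#' @param classifier_labels per-cell argmax class from [predict_proba()].
#' @param pmax per-cell max probability.
#' @param spec a \code{"hicat_threshold"}.
#' @param cluster per-cell integer cluster label (\code{-1} = noise).
#' @param cell_ids per-cell identifiers.
#' @param confident_op \code{"ge"} (default: cells exactly at the threshold are
#'   confident) or \code{"gt"}.
#' @param params optional list of run parameters stored for the metadata
#'   sidecar.
#' @return a \code{"hicat_annotation"} data.frame with columns \code{cell_id},
#'   \code{final_label}, \code{classifier_label}, \code{max_probability},
#'   \code{cluster_id}, \code{confident}; the threshold spec is attached as an
#'   attribute.
#' @export
resolve_labels <- function(classifier_labels, pmax, spec, cluster,
                           cell_ids = NULL, confident_op = c("ge", "gt"),
                           params = NULL) {
  confident_op <- match.arg(confident_op)
  stopifnot(inherits(spec, "hicat_threshold"))
  n <- length(classifier_labels)
  if (length(pmax) != n || length(cluster) != n)
    stop("inputs are not row-aligned")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  confident <- if (confident_op == "ge") pmax >= spec$threshold else pmax > spec$threshold
  cluster <- as.integer(cluster)
  final <- ifelse(confident, classifier_labels,
                  ifelse(cluster >= 0L, paste0("novel_", cluster), "unassigned"))
  structure(data.frame(cell_id = cell_ids, final_label = final,
                       classifier_label = classifier_labels,
                       max_probability = pmax, cluster_id = cluster,
                       confident = confident, stringsAsFactors = FALSE),
            class = c("hicat_annotation", "data.frame"),
            threshold = spec, params = params)
}

#' Feature importances by resolution level
#'
#' Normalized gain importances of the fitted tree ensemble, with the one-hot
#' cluster columns aggregated back into the single \code{cluster} feature, so
#' the contribution of each resolution level (PC, UMAP, cluster) is directly
#' readable. Sorted decreasing with cumulative shares, so statements like "the
#' top five features account for X of the total" can be read off.
#'
#' @param model a fitted \code{"hicat_classifier"}.
#' @return data.frame with columns \code{feature}, \code{resolution},
#'   \code{importance} (sums to 1), \code{cumulative}.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "hicat_classifier") || is.null(model$booster))
    stop("`model` must be a fitted hicat_classifier")
  imp <- xgboost::xgb.importance(model = model$booster)
  feat <- imp$Feature
  feat[startsWith(feat, "cluster=")] <- "cluster"
  gain <- tapply(imp$Gain, feat, sum)
  all_feats <- c(model$numeric_features, "cluster")
  share <- stats::setNames(numeric(length(all_feats)), all_feats)
  share[names(gain)] <- gain
  if (sum(share) > 0) share <- share / sum(share)
  ord <- order(-share, names(share))
  share <- share[ord]
  res <- ifelse(names(share) == "cluster", "cluster",
                ifelse(startsWith(names(share), "umap"), "umap", "pc"))
  data.frame(feature = names(share), resolution = res,
             importance = as.numeric(share),
             cumulative = cumsum(as.numeric(share)),
             row.names = NULL, stringsAsFactors = FALSE)
}
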