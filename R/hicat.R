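#' Control parameters for a hicat run
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the conventions of the underlying tools: library-size normalization to
#' 10,000 counts then log1p; 2,000 variable genes; 50 PCs; UMAP with 15
#' neighbors and min_dist 0.1; DBSCAN with eps 0.5 and min_samples 5 on the
#' UMAP coordinates (eps is scale-sensitive — revisit it if you change the
#' embedding); 500 boosting rounds of depth-6 trees at learning rate 0.1.
#'
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components (50 gives the 53-D feature
#'   space).
#' @param scale_factor library-size normalization target.
#' @param min_shared_genes minimum reference/query gene intersection.
#' @param backend batch-correction backend, \code{"mnn_shift"} (default),
#'   \code{"center_fallback"} or \code{"harmony"} (see
#'   [remove_batch_effects()]).
#' @param umap_n_neighbors,umap_min_dist UMAP parameters.
#' @param dbscan_eps,dbscan_min_samples DBSCAN parameters, in UMAP units.
#' @param iterations,depth,learning_rate,colsample_bynode classifier
#'   parameters (see [train_classifier()]).
#' @param min_cells_per_class warn below this per-class reference count.
#' @param min_gap smallest probability drop treated as a real threshold.
#' @param confident_op \code{"ge"} or \code{"gt"} threshold comparison.
#' @param seed master seed for PCA/UMAP/classifier.
#' @param verbose print per-stage progress messages.
#' @return a \code{"hicat_control"} list.
#' @export
hicat_control <- function(n_hvg = 2000L, n_pcs = 50L, scale_factor = 1e4,
                          min_shared_genes = 200L,
                          backend = "mnn_shift",
                          umap_n_neighbors = 15L, umap_min_dist = 0.1,
                          dbscan_eps = 0.5, dbscan_min_samples = 5L,
                          iterations = 500L, depth = 6L, learning_rate = 0.1,
                          colsample_bynode = 0.5,
                          min_cells_per_class = 5L,
                          min_gap = 1e-6, confident_op = "ge",
                          seed = 0L, verbose = FALSE) {
  ctl <- list(n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
              scale_factor = scale_factor,
              min_shared_genes = as.integer(min_shared_genes),
              backend = backend,
              umap_n_neighbors = as.integer(umap_n_neighbors),
              umap_min_dist = umap_min_dist,
              dbscan_eps = dbscan_eps,
              dbscan_min_samples = as.integer(dbscan_min_samples),
              iterations = as.integer(iterations), depth = as.integer(depth),
              learning_rate = learning_rate,
              colsample_bynode = colsample_bynode,
              min_cells_per_class = as.integer(min_cells_per_class),
              min_gap = min_gap, confident_op = confident_op,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  structure(ctl, class = "hicat_control")
}

#' Semi-supervised cell-type annotation with novel type discovery
#'
#' Fits the full pipeline on a labeled reference and an unlabeled query:
#' shared-gene intersection, normalization, variable-gene selection on the
#' combined data, PCA, batch correction, 2-D UMAP, DBSCAN clustering,
#' concatenation into the multi-resolution feature space, gradient-boosted
#' classifier training on the reference, probability prediction for all
#' cells, largest-drop confidence thresholding over the pooled maximum
#' probabilities, and per-cell fusion of supervised and cluster labels for
#' the query cells. Query cells confidently classified keep the supervised
#' label; low-confidence cells take their density cluster as \code{novel_<id>}
#' or become \code{unassigned} when they are noise points.
#'
#' @param ref reference counts: an [expression_matrix()] or genes-x-cells
#'   matrix with dimnames.
#' @param ref_labels label table for the reference cells (data.frame
#'   \code{cell_id}, \code{label}); reference cells without labels are dropped
#'   from training with a warning.
#' @param query query counts, same formats as \code{ref}.
#' @param control a [hicat_control()].
#' @return an object of class \code{"hicat"}: list with \code{annotation}
#'   (per-query-cell \code{"hicat_annotation"} data.frame), \code{threshold},
#'   \code{classifier}, \code{features}, \code{bundle}, \code{hvgs},
#'   \code{pca}, \code{proba} (all-cell probabilities), \code{control},
#'   \code{call}.
#' @seealso [summary.hicat()], [plot.hicat()], [write_annotation()],
#'   [evaluate_annotation()]
#' @export
hicat <- function(ref, ref_labels, query, control = hicat_control()) {
  cl <- match.call()
  stopifnot(inherits(control, "hicat_control"))
  if (!inherits(ref, "expr_matrix")) ref <- expression_matrix(ref, batch = "reference")
  if (!inherits(query, "expr_matrix")) query <- expression_matrix(query, batch = "query")
  if (identical(ref$batch, query$batch))
    stop("reference and query must carry distinct batch tags")
  ref_labels <- label_table(ref_labels)
  say <- function(...) if (control$verbose) message(...)

  shared <- intersect_genes(ref, query, control$min_shared_genes)
  say("shared genes: ", length(shared$ref$gene_ids))
  combined <- combine_matrices(shared$ref, shared$query)

  n_hvg <- min(control$n_hvg, length(combined$gene_ids))
  hvgs <- select_hvgs(combined, n_hvg)
  say("highly variable genes: ", length(hvgs))

  norm <- normalize_counts(combined, control$scale_factor)
  norm_hvg <- structure(list(values = norm$values[hvgs, , drop = FALSE],
                             gene_ids = hvgs, cell_ids = norm$cell_ids,
                             batch = norm$batch),
                        class = "norm_matrix")
  n_pcs <- min(control$n_pcs, length(hvgs), length(norm$cell_ids) - 1L)
  set.seed(control$seed)
  pcs <- pca_embed(norm_hvg, n_pcs = n_pcs)
  say("PCs: ", pcs$n_pcs)

  corrected <- remove_batch_effects(pcs, norm$batch, backend = control$backend)
  um <- umap_embed(corrected, n_neighbors = control$umap_n_neighbors,
                   min_dist = control$umap_min_dist, seed = control$seed)
  clu <- dbscan_cluster(um, eps = control$dbscan_eps,
                        min_samples = control$dbscan_min_samples)
  say("DBSCAN clusters: ", length(unique(clu[clu >= 0L])),
      " (+", sum(clu == -1L), " noise cells)")

  bundle <- embedding_bundle(corrected, um, clu, norm$batch, norm$cell_ids)
  feats <- concatenate_features(bundle)

  is_ref <- feats$batch == ref$batch
  model <- train_classifier(subset_features(feats, is_ref), ref_labels,
                            iterations = control$iterations,
                            depth = control$depth,
                            learning_rate = control$learning_rate,
                            colsample_bynode = control$colsample_bynode,
                            min_cells_per_class = control$min_cells_per_class,
                            seed = control$seed)
  pp <- predict_proba(model, feats)
  thr <- select_confidence_threshold(pp$pmax, K = length(model$class_names),
                                     min_gap = control$min_gap)
  say(sprintf("confidence threshold: %.4f", thr$threshold))

  qi <- which(!is_ref)
  annotation <- resolve_labels(pp$label[qi], pp$pmax[qi], thr,
                               bundle$cluster[qi],
                               cell_ids = feats$cell_ids[qi],
                               confident_op = control$confident_op,
                               params = unclass(control))
  say("annotated ", length(qi), " query cells; ",
      sum(!annotation$confident), " low-confidence")

  structure(list(annotation = annotation, threshold = thr, classifier = model,
                 features = feats, bundle = bundle, hvgs = hvgs, pca = pcs,
                 proba = pp, control = control, call = cl),
            class = "hicat")
}

#' @export
print.hicat <- function(x, ...) {
  ann <- x$annotation
  n_novel <- length(unique(ann$final_label[startsWith(ann$final_label, "novel_")]))
  cat("Semi-supervised cell-type annotation (hicat)\n")
  cat(sprintf("  reference classes : %d (%s)\n", length(x$classifier$class_names),
              paste(utils::head(x$classifier$class_names, 5L), collapse = ", ")))
  cat(sprintf("  query cells       : %d\n", nrow(ann)))
  cat(sprintf("  confidence thresh : %.4f%s\n", x$threshold$threshold,
              if (x$threshold$fallback_used) " (fallback 1/K)" else ""))
  cat(sprintf("  confident (known) : %d\n", sum(ann$confident)))
  cat(sprintf("  novel labels      : %d distinct (%d cells)\n", n_novel,
              sum(startsWith(ann$final_label, "novel_"))))
  cat(sprintf("  unassigned        : %d\n", sum(ann$final_label == "unassigned")))
  invisible(x)
}

#' Summarize a hicat fit
#'
#' @param object a \code{"hicat"} fit.
#' @param ... unused.
#' @return a \code{"summary.hicat"} with the final label table, the threshold,
#'   and the top feature importances.
#' @export
summary.hicat <- function(object, ...) {
  ann <- object$annotation
  lab <- sort(table(ann$final_label), decreasing = TRUE)
  imp <- feature_importance(object$classifier)
  structure(list(labels = lab, threshold = object$threshold,
                 importance = utils::head(imp, 5L),
                 n_query = nrow(ann),
                 n_clusters = length(unique(object$bundle$cluster[object$bundle$cluster >= 0L])),
                 class_names = object$classifier$class_names),
            class = "summary.hicat")
}

#' @export
print.summary.hicat <- function(x, ...) {
  cat("hicat annotation summary\n")
  cat(sprintf("  %d query cells, %d reference classes, %d density clusters\n",
              x$n_query, length(x$class_names), x$n_clusters))
  print(x$threshold)
  cat("final labels:\n")
  print(x$labels)
  cat("top features by importance (resolution in brackets):\n")
  for (i in seq_len(nrow(x$importance)))
    cat(sprintf("  %-10s [%s] %.3f (cumulative %.3f)\n",
                x$importance$feature[i], x$importance$resolution[i],
                x$importance$importance[i], x$importance$cumulative[i]))
  invisible(x)
}

#' Transductive annotations of the query cells
#'
#' The pipeline is transductive — the embedding is computed jointly on
#' reference and query — so \code{predict} returns the annotations of the
#' query cells the model was fitted with; it does not accept new data.
#'
#' @param object a \code{"hicat"} fit.
#' @param ... unused; supplying \code{newdata} is an error.
#' @return the \code{"hicat_annotation"} data.frame.
#' @export
predict.hicat <- function(object, ...) {
  dots <- list(...)
  if (!is.null(dots$newdata))
    stop("hicat is transductive: refit with the new query via hicat()")
  object$annotation
}

#' Plot the joint UMAP embedding of a hicat fit
#'
#' Left: all cells colored by batch. Right: query cells colored by final
#' label (novel labels and unassigned included).
#'
#' @param x a \code{"hicat"} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.hicat <- function(x, ...) {
  um <- x$bundle$umap2d
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  bcol <- ifelse(x$bundle$batch == x$bundle$batch[1L], "#1b9e77", "#d95f02")
  graphics::plot(um, col = bcol, pch = 16, cex = 0.4,
                 xlab = "umap_1", ylab = "umap_2", main = "batch", ...)
  qi <- match(x$annotation$cell_id, x$bundle$cell_ids)
  labs <- factor(x$annotation$final_label)
  pal <- grDevices::hcl.colors(max(3L, nlevels(labs)), "Dark 3")
  graphics::plot(um[qi, , drop = FALSE], col = pal[as.integer(labs)], pch = 16,
                 cex = 0.4, xlab = "umap_1", ylab = "umap_2",
                 main = "query annotation", ...)
  graphics::legend("topright", legend = levels(labs),
                   col = pal[seq_len(nlevels(labs))], pch = 16, cex = 0.6,
                   bty = "n")
  invisible(x)
}
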