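#' Concatenate the multi-resolution feature table
#'
#' Joins the three resolution levels row-by-row into the classifier input:
#' the batch-corrected PCs (broad transcriptional programs), the 2-D UMAP
#' coordinates (local manifold structure), and the DBSCAN cluster membership as
#' a single categorical column (unsupervised grouping, noise kept as level
#' \code{-1}). With the default 50 PCs this is the 53-column feature space.
#' The numeric block is passed through unchanged — no rescaling across
#' resolutions, since the downstream tree ensemble is per-feature
#' scale-invariant.
#'
#' @param bundle an [embedding_bundle()].
#' @return a \code{"multires_features"} list: \code{table} (data.frame, columns
#'   \code{pc_1..pc_k}, \code{umap_1}, \code{umap_2}, \code{cluster} as factor),
#'   \code{resolution_tags} (per-column tag in pc/umap/cluster), \code{batch},
#'   \code{cell_ids}.
#' @export
concatenate_features <- function(bundle) {
  stopifnot(inherits(bundle, "embedding_bundle"))
  n <- nrow(bundle$corrected_pcs)
  if (nrow(bundle$umap2d) != n || length(bundle$cluster) != n)
    stop("bundle components are not row-aligned")
  n_pcs <- ncol(bundle$corrected_pcs)
  pcs <- bundle$corrected_pcs
  colnames(pcs) <- paste0("pc_", seq_len(n_pcs))
  um <- bundle$umap2d
  colnames(um) <- c("umap_1", "umap_2")
  lev <- sort(unique(bundle$cluster))
  tab <- data.frame(pcs, um,
                    cluster = factor(bundle$cluster, levels = lev),
                    check.names = FALSE)
  rownames(tab) <- bundle$cell_ids
  tags <- c(rep("pc", n_pcs), "umap", "umap", "cluster")
  names(tags) <- colnames(tab)
  structure(list(table = tab, resolution_tags = tags,
                 batch = bundle$batch, cell_ids = bundle$cell_ids),
            class = "multires_features")
}

#' @export
print.multires_features <- function(x, ...) {
  cat(sprintf("<multires_features> %d cells x %d features (%d pc + 2 umap + 1 cluster)\n",
              nrow(x$table), ncol(x$table), sum(x$resolution_tags == "pc")))
  invisible(x)
}

# subset rows of a feature object, keeping alignment metadata
subset_features <- function(features, idx) {
  structure(list(table = features$table[idx, , drop = FALSE],
                 resolution_tags = features$resolution_tags,
                 batch = features$batch[idx],
                 cell_ids = features$cell_ids[idx]),
            class = "multires_features")
}

#' Write the feature table to TSV (debugging aid)
#'
#' @param features a \code{"multires_features"} object.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(cell_id = features$cell_ids, features$table,
                   batch = features$batch, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
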