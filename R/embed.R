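#' Remove batch effects from a PC embedding
#'
#' Three backends are available. \code{"mnn_shift"} (the default) estimates a
#' single translation between the batches from mutual nearest neighbor pairs
#' — cells of one batch whose nearest cross-batch neighbors reciprocate —
#' and shifts the second batch by it. Because the offset is estimated only
#' from matched cells, it stays unbiased when the two batches contain
#' different mixtures of cell types (e.g. query-only novel types), where
#' global centering over-corrects. \code{"center_fallback"} subtracts each
#' batch's mean from every principal component: exact for constant offsets and
#' dependency-free, but composition-sensitive. \code{"harmony"} delegates to
#' the harmony package's iterative soft-clustering correction when that
#' package is installed, with its default configuration.
#'
#' @param pcs a \code{"pc_embedding"} from [pca_embed()], or a plain
#'   cells-x-PCs matrix.
#' @param batch per-cell batch tag; exactly two batches must be present and
#'   each needs at least two cells.
#' @param backend \code{"mnn_shift"}, \code{"center_fallback"} or
#'   \code{"harmony"}.
#' @param k neighbors per cell for the mutual-nearest-neighbor search.
#' @return corrected cells x n_pcs numeric matrix.
#' @export
remove_batch_effects <- function(pcs, batch,
                                 backend = c("mnn_shift", "center_fallback",
                                             "harmony"),
                                 k = 20L) {
  backend <- match.arg(backend)
  scores <- if (inherits(pcs, "pc_embedding")) pcs$scores else as.matrix(pcs)
  if (length(batch) != nrow(scores))
    stop("`batch` length must equal the number of cells")
  tb <- table(batch)
  if (length(tb) != 2L)
    stop("exactly two batches expected, got ", length(tb))
  if (any(tb < 2L))
    stop("each batch needs at least 2 cells")
  if (backend == "harmony") {
    if (!requireNamespace("harmony", quietly = TRUE))
      stop("backend \"harmony\" requires the harmony package; ",
           "use backend = \"center_fallback\" instead")
    out <- harmony::RunHarmony(scores, meta_data = data.frame(batch = batch),
                               vars_use = "batch", verbose = FALSE)
    out <- as.matrix(out)
    dimnames(out) <- dimnames(scores)
    return(out)
  }
  if (backend == "center_fallback") {
    out <- scores
    for (b in names(tb)) {
      i <- batch == b
      out[i, ] <- sweep(scores[i, , drop = FALSE], 2L,
                        colMeans(scores[i, , drop = FALSE]))
    }
    return(out)
  }
  mnn_shift(scores, batch, k = k)
}

# translate the second batch onto the first by the mean displacement over
# mutual nearest neighbor pairs (k nearest cross-batch cells each way).
# Iterated: MNN pairs sit on the facing edges of the clouds, so a single
# estimate undershoots large offsets; re-pairing after each partial shift
# converges to the full translation within a few rounds.
mnn_shift <- function(scores, batch, k = 20L, iterations = 4L) {
  b <- sort(unique(batch))
  i1 <- which(batch == b[1L])
  i2 <- which(batch == b[2L])
  k <- max(1L, min(k, length(i1) - 1L, length(i2) - 1L))
  x1 <- scores[i1, , drop = FALSE]
  x2 <- scores[i2, , drop = FALSE]
  total <- numeric(ncol(scores))
  for (it in seq_len(iterations)) {
    # cross-batch squared distances (desk-scale: n1 x n2 dense)
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
    nn12 <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))  # per b1 cell
    nn21 <- t(apply(d2, 2L, function(r) order(r)[seq_len(k)]))  # per b2 cell
    pairs1 <- rep(seq_len(nrow(x1)), each = k)
    pairs2 <- as.vector(t(nn12))
    mutual <- vapply(seq_along(pairs1), function(p)
      pairs1[p] %in% nn21[pairs2[p], ], logical(1))
    if (!any(mutual)) {
      if (it > 1L) break
      warning("no mutual nearest neighbor pairs found; falling back to per-batch centering")
      return(remove_batch_effects(scores, batch, backend = "center_fallback"))
    }
    p1 <- pairs1[mutual]
    p2 <- pairs2[mutual]
    delta <- colMeans(x1[p1, , drop = FALSE]) - colMeans(x2[p2, , drop = FALSE])
    x2 <- sweep(x2, 2L, delta, "+")
    total <- total + delta
    if (sqrt(sum(delta^2)) < 1e-8) break
  }
  out <- scores
  out[i2, ] <- sweep(scores[i2, , drop = FALSE], 2L, total, "+")
  out
}

#' Two-dimensional UMAP embedding
#'
#' Thin wrapper over \code{uwot::umap} pinned to a deterministic,
#' single-threaded configuration: with a fixed \code{seed} and fixed input the
#' output is bit-reproducible.
#'
#' @param corrected cells x d numeric matrix (typically batch-corrected PCs).
#' @param n_neighbors local neighborhood size (default 15).
#' @param min_dist minimum embedding distance (default 0.1).
#' @param seed integer seed.
#' @param n_threads worker threads; keep at 1 for reproducibility.
#' @return cells x 2 numeric matrix.
#' @export
umap_embed <- function(corrected, n_neighbors = 15L, min_dist = 0.1,
                       seed = 0L, n_threads = 1L) {
  corrected <- as.matrix(corrected)
  if (n_neighbors >= nrow(corrected))
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number of cells (",
         nrow(corrected), ")")
  out <- uwot::umap(corrected, n_components = 2L, n_neighbors = n_neighbors,
                    min_dist = min_dist, metric = "euclidean",
                    n_threads = n_threads, n_sgd_threads = 0L,
                    seed = as.integer(seed), verbose = FALSE)
  colnames(out) <- c("umap_1", "umap_2")
  rownames(out) <- rownames(corrected)
  out
}

#' Density-based clustering (DBSCAN) of a 2-D embedding
#'
#' Standard DBSCAN semantics: a core point has at least \code{min_samples}
#' points (itself included) within distance \code{eps}; clusters are the
#' connected components of core points together with their border points;
#' everything else is noise (label \code{-1}). For 2-D input, neighborhood
#' queries use an eps-sized grid; higher dimensions fall back to pairwise
#' distances. Cluster labels are renumbered \code{0..m-1} by decreasing size,
#' ties broken by the smallest member index, so labels are stable under point
#' permutation.
#'
#' @param points n x d numeric matrix (d = 2 for the pipeline).
#' @param eps positive neighborhood radius, in embedding units.
#' @param min_samples minimum neighborhood size for a core point.
#' @return integer vector of length n; \code{-1} marks noise.
#' @export
dbscan_cluster <- function(points, eps = 0.5, min_samples = 5L) {
  points <- as.matrix(points)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) stop("`eps` must be positive")
  if (min_samples < 1L) stop("`min_samples` must be >= 1")
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  neighbors <- if (ncol(points) == 2L) grid_neighbors(points, eps)
               else bruteforce_neighbors(points, eps)
  dbscan_from_neighbors(neighbors, min_samples, n)
}

# region queries via an eps-sized grid: candidates live in the 3x3 block of cells
grid_neighbors <- function(points, eps) {
  n <- nrow(points)
  gx <- floor(points[, 1L] / eps)
  gy <- floor(points[, 2L] / eps)
  key <- paste(gx, gy)
  cells <- split(seq_len(n), key)
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(gx[i] + dx, gy[i] + dy)
      hit <- cells[[k]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    d2 <- (points[cand, 1L] - points[i, 1L])^2 + (points[cand, 2L] - points[i, 2L])^2
    cand[d2 <= eps2]
  })
}

bruteforce_neighbors <- function(points, eps) {
  d <- as.matrix(stats::dist(points))
  lapply(seq_len(nrow(points)), function(i) which(d[i, ] <= eps))
}

# clusters = connected components of core points plus border points;
# a border point joins the cluster of its smallest-index core neighbor
# (deterministic tie-break; neighbors[[i]] includes i itself)
dbscan_from_neighbors <- function(neighbors, min_samples, n) {
  core <- vapply(neighbors, length, integer(1)) >= min_samples
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    stack <- i
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- cl
      nbu <- neighbors[[u]]
      stack <- c(stack, nbu[core[nbu] & is.na(comp[nbu])])
    }
    cl <- cl + 1L
  }
  label <- rep(-1L, n)
  label[core] <- comp[core]
  for (i in which(!core)) {
    hits <- neighbors[[i]][core[neighbors[[i]]]]
    if (length(hits)) label[i] <- comp[min(hits)]
  }
  renumber_clusters(label)
}

# relabel clusters 0..m-1 by decreasing size, ties by smallest member index
renumber_clusters <- function(label) {
  ids <- sort(unique(label[label >= 0L]))
  if (!length(ids)) return(label)
  size <- vapply(ids, function(k) sum(label == k), integer(1))
  first <- vapply(ids, function(k) which(label == k)[1L], integer(1))
  ord <- ids[order(-size, first)]
  out <- label
  for (r in seq_along(ord)) out[label == ord[r]] <- r - 1L
  out
}

#' Naive quadratic DBSCAN reference implementation
#'
#' Direct transcription of the DBSCAN definition from the full pairwise
#' distance matrix; identical semantics and renumbering as [dbscan_cluster()].
#' Intended as an independent cross-check for validation; refuses inputs with
#' more than 5000 points.
#'
#' @inheritParams dbscan_cluster
#' @return integer vector of cluster labels, \code{-1} for noise.
#' @export
dbscan_bruteforce_oracle <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n > 5000L) stop("oracle is quadratic; refusing n > 5000")
  if (n == 0L) return(integer(0))
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be positive")
  if (min_samples < 1L) stop("`min_samples` must be >= 1")
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  # connected components over core points (edge when within eps)
  label <- rep(-1L, n)
  comp <- rep(NA_integer_, n)
  cl <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    stack <- i
    while (length(stack)) {
      u <- stack[[1L]]
      stack <- stack[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cl
      nxt <- nb[[u]][core[nb[[u]]] & is.na(comp[nb[[u]]])]
      stack <- c(stack, nxt)
    }
    cl <- cl + 1L
  }
  label[core] <- comp[core]
  # border points: non-core within eps of a core point; the smallest-index
  # core neighbor's cluster wins (same tie-break as dbscan_cluster)
  for (i in which(!core)) {
    hits <- nb[[i]][core[nb[[i]]]]
    if (length(hits)) label[i] <- comp[min(hits)]
  }
  renumber_clusters(label)
}

#' Bundle the three embedding resolutions
#'
#' @param corrected_pcs cells x n_pcs matrix.
#' @param umap2d cells x 2 matrix.
#' @param cluster integer per-cell cluster label (\code{-1} = noise).
#' @param batch per-cell batch tag.
#' @param cell_ids per-cell identifiers.
#' @return an \code{"embedding_bundle"} list.
#' @export
embedding_bundle <- function(corrected_pcs, umap2d, cluster, batch, cell_ids) {
  n <- nrow(corrected_pcs)
  if (nrow(umap2d) != n || length(cluster) != n || length(batch) != n ||
      length(cell_ids) != n)
    stop("embedding components are not row-aligned")
  structure(list(corrected_pcs = corrected_pcs, umap2d = umap2d,
                 cluster = as.integer(cluster), batch = batch,
                 cell_ids = cell_ids),
            class = "embedding_bundle")
}
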