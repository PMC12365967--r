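#' Restrict reference and query to their shared genes
#'
#' Both matrices are subset to the sorted intersection of their gene IDs, in
#' identical order, so downstream normalization and variable-gene selection see
#' one common gene space.
#'
#' @param ref,query [expression_matrix()] objects.
#' @param min_genes minimum size of the intersection (default 200) below which
#'   an error is raised.
#' @return list with elements \code{ref} and \code{query}.
#' @export
intersect_genes <- function(ref, query, min_genes = 200L) {
  stopifnot(inherits(ref, "expr_matrix"), inherits(query, "expr_matrix"))
  shared <- sort(intersect(ref$gene_ids, query$gene_ids))
  if (length(shared) < min_genes)
    stop("insufficient shared genes: ", length(shared), " < ", min_genes)
  list(ref = expression_matrix(ref$counts[shared, , drop = FALSE], batch = ref$batch),
       query = expression_matrix(query$counts[shared, , drop = FALSE], batch = query$batch))
}

#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are scaled to a common library size (\code{scale_factor},
#' default 10,000) and log1p-transformed:
#' \code{value = log1p(count / libsize * scale_factor)}. Cells with zero total
#' counts are dropped with a warning. Sparse input stays sparse (zeros map to
#' zero).
#'
#' @param x an [expression_matrix()].
#' @param scale_factor positive target library size.
#' @return a \code{"norm_matrix"}: list with \code{values} (genes x cells),
#'   \code{gene_ids}, \code{cell_ids}, \code{batch}.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L || scale_factor <= 0)
    stop("`scale_factor` must be a positive number")
  libsize <- Matrix::colSums(x$counts)
  keep <- libsize > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " cell(s) with zero total counts")
  }
  m <- x$counts[, keep, drop = FALSE]
  libsize <- libsize[keep]
  if (methods::is(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    v <- m
    v@x <- log1p(m@x / rep.int(libsize, diff(m@p)) * scale_factor)
  } else {
    v <- log1p(sweep(m, 2L, libsize, "/") * scale_factor)
  }
  batch <- if (length(x$batch) == length(x$cell_ids)) x$batch[keep]
           else rep(x$batch, sum(keep))
  structure(list(values = v, gene_ids = x$gene_ids,
                 cell_ids = x$cell_ids[keep], batch = batch),
            class = "norm_matrix")
}

#' Bind reference and query into one matrix over a shared gene space
#'
#' @param ref,query [expression_matrix()] objects restricted to the same genes
#'   (see [intersect_genes()]).
#' @return an [expression_matrix()]-like object whose \code{batch} is a
#'   per-cell vector.
#' @export
combine_matrices <- function(ref, query) {
  stopifnot(identical(ref$gene_ids, query$gene_ids))
  overlap <- intersect(ref$cell_ids, query$cell_ids)
  if (length(overlap))
    stop("reference and query share cell IDs: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  counts <- cbind(ref$counts, query$counts)
  out <- expression_matrix(counts, batch = "combined")
  out$batch <- c(rep(ref$batch, length(ref$cell_ids)),
                 rep(query$batch, length(query$cell_ids)))
  out
}

# per-gene mean and variance of a genes-x-cells matrix without densifying
row_mean_var <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  if (methods::is(m, "sparseMatrix")) {
    ex2 <- Matrix::rowSums(m^2) / n
  } else {
    ex2 <- rowSums(m^2) / n
  }
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection on raw counts: a loess curve of
#' log10(variance) against log10(mean) predicts each gene's expected standard
#' deviation; counts are standardized with the observed mean and that expected
#' SD, clipped at \code{sqrt(n_cells)}, and genes are ranked by the variance of
#' the clipped standardized values. Ranking is deterministic: score descending,
#' then gene ID ascending.
#'
#' @param combined an [expression_matrix()] holding the raw counts of reference
#'   and query cells over the shared gene space (see [combine_matrices()]).
#' @param n_hvg number of genes to select (default 2000).
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of gene IDs, highest standardized variance first.
#' @export
select_hvgs <- function(combined, n_hvg = 2000L, loess_span = 0.3) {
  stopifnot(inherits(combined, "expr_matrix"))
  m <- combined$counts
  n <- ncol(m)
  if (n_hvg > nrow(m)) stop("n_hvg exceeds the number of genes")
  mv <- row_mean_var(m)
  sv <- standardized_variance(m, mv$mean, mv$var, loess_span)
  pos <- sv > 0
  if (sum(pos) < n_hvg) {
    warning("only ", sum(pos), " genes with nonzero standardized variance; returning all of them")
    n_hvg <- sum(pos)
  }
  ids <- combined$gene_ids
  ord <- order(-sv, ids)
  ids[ord][seq_len(n_hvg)]
}

# variance of clipped standardized counts per gene (vst-style score)
standardized_variance <- function(m, mu, v, loess_span = 0.3) {
  n <- ncol(m)
  sv <- numeric(nrow(m))
  use <- v > 0 & mu > 0
  if (!any(use)) return(sv)
  lv <- log10(v[use])
  lm_ <- log10(mu[use])
  # local trend needs enough genes to be well conditioned; small inputs get
  # a global quadratic polynomial trend instead
  pred <- if (sum(use) >= 30L) tryCatch({
    stats::fitted(stats::loess(lv ~ lm_, span = loess_span, degree = 2))
  }, error = function(e) NULL) else NULL
  if (is.null(pred) || any(!is.finite(pred))) {
    deg <- min(2L, length(unique(lm_)) - 1L)
    pred <- if (deg < 1L) rep(mean(lv), length(lv))
            else stats::fitted(stats::lm(lv ~ stats::poly(lm_, deg)))
  }
  exp_sd <- sqrt(10^pred)
  clip <- sqrt(n)
  mu_u <- mu[use]
  if (methods::is(m, "sparseMatrix")) {
    mg <- methods::as(m[use, , drop = FALSE], "CsparseMatrix")
    tg <- methods::as(Matrix::t(mg), "CsparseMatrix")  # cells x genes, column slices per gene
    ssq <- numeric(length(mu_u))
    szero <- pmin(pmax((0 - mu_u) / exp_sd, -clip), clip)
    nnz <- diff(tg@p)
    for (j in seq_along(mu_u)) {
      if (nnz[j] == 0L) { ssq[j] <- n * szero[j]^2; next }
      xs <- tg@x[(tg@p[j] + 1L):tg@p[j + 1L]]
      z <- pmin(pmax((xs - mu_u[j]) / exp_sd[j], -clip), clip)
      ssq[j] <- sum(z^2) + (n - nnz[j]) * szero[j]^2
    }
  } else {
    z <- (m[use, , drop = FALSE] - mu_u) / exp_sd
    z <- pmin(pmax(z, -clip), clip)
    ssq <- rowSums(z^2)
  }
  sv[use] <- ssq / (n - 1)
  sv
}

#' Principal-component embedding of scaled expression
#'
#' Genes are z-scored across cells (zero-variance genes contribute zeros) with
#' values clipped at \code{clip} standard deviations, then cells are projected
#' onto the top principal components. The decomposition is computed exactly
#' from the eigendecomposition of the gene-space Gram matrix, and each
#' component's sign is fixed by making its largest-magnitude gene loading
#' positive, so results are deterministic.
#'
#' @param normalized a \code{"norm_matrix"} restricted to the selected
#'   highly variable genes.
#' @param n_pcs number of components (default 50); reduced with a warning when
#'   it exceeds the matrix rank.
#' @param clip symmetric z-score clip applied before the decomposition.
#' @return a \code{"pc_embedding"}: list with \code{scores} (cells x n_pcs),
#'   \code{n_pcs}, \code{explained_variance} (non-increasing), \code{loadings},
#'   \code{batch}, \code{cell_ids}.
#' @export
pca_embed <- function(normalized, n_pcs = 50L, clip = 10) {
  stopifnot(inherits(normalized, "norm_matrix"))
  v <- normalized$values
  n_cells <- ncol(v)
  mv <- row_mean_var(v)
  sdv <- sqrt(mv$var)
  sdv[sdv == 0] <- 1
  a <- (as.matrix(v) - mv$mean) / sdv     # genes x cells, z-scored per gene
  a <- pmin(pmax(a, -clip), clip)
  a <- t(a)                               # cells x genes
  a <- sweep(a, 2L, colMeans(a))          # re-center after clipping
  max_rank <- min(nrow(a) - 1L, ncol(a))
  if (n_pcs > max_rank) {
    warning("n_pcs reduced from ", n_pcs, " to rank ", max_rank)
    n_pcs <- max_rank
  }
  if (ncol(a) <= nrow(a)) {
    g <- crossprod(a)                     # genes x genes
    eg <- eigen(g, symmetric = TRUE)
    k <- seq_len(n_pcs)
    load <- eg$vectors[, k, drop = FALSE]
    scores <- a %*% load
    lambda <- pmax(eg$values[k], 0)
  } else {
    g <- tcrossprod(a)                    # cells x cells
    eg <- eigen(g, symmetric = TRUE)
    k <- seq_len(n_pcs)
    lambda <- pmax(eg$values[k], 0)
    u <- eg$vectors[, k, drop = FALSE]
    d <- sqrt(lambda)
    d[d == 0] <- 1
    load <- crossprod(a, u) %*% diag(1 / d, n_pcs)
    scores <- u %*% diag(sqrt(pmax(eg$values[k], 0)), n_pcs)
  }
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("pc_", seq_len(n_pcs))
  rownames(scores) <- normalized$cell_ids
  structure(list(scores = scores, n_pcs = n_pcs,
                 explained_variance = lambda / (n_cells - 1L),
                 loadings = load, batch = normalized$batch,
                 cell_ids = normalized$cell_ids),
            class = "pc_embedding")
}
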