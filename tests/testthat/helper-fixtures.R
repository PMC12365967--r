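# Shared fixtures and independent test oracles.

# small expression matrix with explicit values
toy_expr <- function(values, genes = NULL, cells = NULL, batch = "reference",
                     sparse = FALSE) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  if (sparse) m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  expression_matrix(m, batch = batch)
}

# a small but realistic simulated pair, memoised per session
mini_cache <- new.env(parent = emptyenv())

mini_sim <- function() {
  if (is.null(mini_cache$sim)) {
    cfg <- sim_config(
      n_genes = 400L,
      known_types = data.frame(name = c("alpha", "beta", "gamma"),
                               n_ref = 60L, n_query = 60L),
      novel_types = data.frame(name = "nova", n_query = 40L),
      n_markers = 20L, seed = 42L)
    mini_cache$sim <- simulate_pair(cfg)
  }
  mini_cache$sim
}

mini_fit <- function() {
  if (is.null(mini_cache$fit)) {
    sim <- mini_sim()
    mini_cache$fit <- hicat(sim$ref, sim$ref_labels, sim$query,
                            control = hicat_control(n_hvg = 200L, n_pcs = 20L,
                                                    iterations = 100L,
                                                    seed = 7L))
  }
  mini_cache$fit
}

# hand-built feature table: two (or more) Gaussian blobs in PC space
blob_features <- function(n_per = 100L, centers = list(c(8, rep(0, 9)),
                                                       c(-8, rep(0, 9))),
                          cluster = NULL, seed = 11L, batch = "reference") {
  set.seed(seed)
  k <- length(centers)
  pcs <- do.call(rbind, lapply(centers, function(ctr)
    sweep(matrix(rnorm(n_per * length(ctr)), n_per), 2L, ctr, "+")))
  um <- pcs[, 1:2] / 4
  if (is.null(cluster)) cluster <- rep(seq_len(k) - 1L, each = n_per)
  ids <- paste0("b", seq_len(nrow(pcs)))
  bundle <- embedding_bundle(pcs, um, cluster,
                             batch = rep(batch, nrow(pcs)), cell_ids = ids)
  concatenate_features(bundle)
}

# --- independent oracles -----------------------------------------------------

# exhaustive consecutive-gap scan for the confidence threshold
threshold_oracle <- function(pmax_all, K, min_gap = 1e-6) {
  p <- sort(pmax_all, decreasing = TRUE)
  best_gap <- -Inf
  best_i <- NA_integer_
  if (length(p) >= 2L) {
    for (i in seq_len(length(p) - 1L)) {
      gap <- p[i] - p[i + 1L]
      if (gap > best_gap) { best_gap <- gap; best_i <- i }
    }
  }
  if (is.na(best_i) || best_gap < min_gap)
    return(list(threshold = 1 / K, fallback_used = TRUE))
  thr <- (p[best_i] + p[best_i + 1L]) / 2
  list(threshold = min(max(thr, 1 / K), 1 - .Machine$double.eps),
       fallback_used = FALSE)
}

# best injective predicted->true assignment by exhaustive permutation search
alignment_mass_oracle <- function(counts) {
  nr <- nrow(counts)
  nc <- ncol(counts)
  cols <- seq_len(nc)
  best <- -Inf
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  k <- min(nr, nc)
  for (rows_sel in utils::combn(seq_len(nr), k, simplify = FALSE))
    for (cols_perm in perms(cols)) {
      sel <- cbind(rows_sel, cols_perm[seq_len(k)])
      best <- max(best, sum(counts[sel]))
    }
  best
}

# adjusted Rand index between two partitions (independent of any fit)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
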