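make_two_batches <- function(n = 80L, d = 10L, offset = 0, seed = 21L) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * d), 2 * n, d)
  batch <- rep(c("reference", "query"), each = n)
  x[batch == "query", ] <- x[batch == "query", ] + offset
  list(x = x, batch = batch)
}

test_that("center_fallback removes constant offsets exactly and is symmetric", {
  tb <- make_two_batches(offset = 7)
  out <- remove_batch_effects(tb$x, tb$batch, backend = "center_fallback")
  m_ref <- colMeans(out[tb$batch == "reference", ])
  m_qry <- colMeans(out[tb$batch == "query", ])
  expect_equal(m_ref, m_qry, tolerance = 1e-12)
  expect_equal(max(abs(m_ref)), 0, tolerance = 1e-12)

  # swapping batch names changes nothing
  swapped <- ifelse(tb$batch == "reference", "query", "reference")
  expect_equal(remove_batch_effects(tb$x, swapped, backend = "center_fallback"),
               out)
})

test_that("correction displaces cells less when no offset was injected", {
  tb0 <- make_two_batches(offset = 0)
  tb7 <- make_two_batches(offset = 7)
  for (bk in c("center_fallback", "mnn_shift")) {
    d0 <- sqrt(mean((remove_batch_effects(tb0$x, tb0$batch, backend = bk) - tb0$x)^2))
    d7 <- sqrt(mean((remove_batch_effects(tb7$x, tb7$batch, backend = bk) - tb7$x)^2))
    expect_lt(d0, d7)
  }
})

test_that("mnn_shift recovers a pure translation and resists composition shift", {
  tb <- make_two_batches(offset = 5)
  out <- remove_batch_effects(tb$x, tb$batch, backend = "mnn_shift")
  expect_equal(colMeans(out[tb$batch == "query", ]),
               colMeans(out[tb$batch == "reference", ]), tolerance = 0.5)

  # query carries an extra population far away; the shift for the shared
  # population must not be dragged toward it (global centering would be)
  set.seed(31)
  d <- 5L
  ref <- matrix(rnorm(150 * d), 150, d)
  shared <- matrix(rnorm(100 * d), 100, d) + 3   # same population, offset 3 on all dims
  novel <- matrix(rnorm(80 * d, mean = 25), 80, d) + 3
  x <- rbind(ref, shared, novel)
  batch <- rep(c("reference", "query"), c(150, 180))
  out <- remove_batch_effects(x, batch, backend = "mnn_shift")
  resid_mnn <- sqrt(sum((colMeans(out[151:250, ]) - colMeans(out[1:150, ]))^2))
  ctr <- remove_batch_effects(x, batch, backend = "center_fallback")
  resid_ctr <- sqrt(sum((colMeans(ctr[151:250, ]) - colMeans(ctr[1:150, ]))^2))
  expect_lt(resid_mnn, 1)
  expect_gt(resid_ctr, 5)
})

test_that("batch-correction input validation", {
  tb <- make_two_batches()
  expect_error(remove_batch_effects(tb$x, rep("a", nrow(tb$x))), "two batches")
  expect_error(remove_batch_effects(tb$x, tb$batch[-1]), "length")
  expect_error(remove_batch_effects(tb$x, c("a", rep("b", nrow(tb$x) - 1L))),
               "at least 2 cells")
})

test_that("umap embedding is shaped, deterministic, and separates far blobs", {
  set.seed(1)
  n <- 250L
  blob <- rbind(matrix(rnorm(n * 50), n, 50),
                matrix(rnorm(n * 50, mean = 20), n, 50))
  um <- umap_embed(blob, seed = 0L)
  expect_equal(dim(um), c(2L * n, 2L))
  expect_identical(um, umap_embed(blob, seed = 0L))

  km <- stats::kmeans(um, centers = 2L, nstart = 10L)
  expect_gte(ari(km$cluster, rep(1:2, each = n)), 0.95)

  expect_error(umap_embed(blob[1:10, ], n_neighbors = 15L), "n_neighbors")
})

test_that("duplicated input rows land at nearly identical embedding positions", {
  set.seed(2)
  x <- matrix(rnorm(120 * 20), 120, 20)
  x[61:120, ] <- x[1:60, ]
  um <- umap_embed(x, seed = 0L)
  diam <- max(stats::dist(um))
  gaps <- sqrt(rowSums((um[1:60, ] - um[61:120, ])^2))
  # the stochastic layout separates exact duplicates slightly; they must stay
  # far closer together than typical point pairs
  expect_lt(stats::median(gaps), 0.05 * diam)
  expect_lt(stats::median(gaps), 0.1 * stats::median(stats::dist(um[1:60, ])))
})

test_that("dbscan handles degenerate and textbook cases", {
  pts <- matrix(0, 10, 2)
  expect_equal(dbscan_cluster(pts, eps = 0.5, min_samples = 5L), rep(0L, 10))

  set.seed(4)
  blob <- matrix(rnorm(40, sd = 0.05), 20, 2)
  far <- c(100, 100)
  lab <- dbscan_cluster(rbind(blob, far), eps = 1, min_samples = 5L)
  expect_equal(lab[1:20], rep(0L, 20))
  expect_equal(lab[21], -1L)

  expect_equal(dbscan_cluster(matrix(numeric(0), 0, 2), eps = 1, min_samples = 1L),
               integer(0))
  # min_samples = 1: every point is core, no noise
  set.seed(5)
  r <- matrix(runif(60), 30, 2)
  expect_true(all(dbscan_cluster(r, eps = 0.05, min_samples = 1L) >= 0L))

  expect_error(dbscan_cluster(r, eps = 0), "positive")
  expect_error(dbscan_bruteforce_oracle(matrix(0, 5001, 2), 1, 1), "refusing")
})

test_that("dbscan matches the quadratic oracle on crescents with outliers", {
  set.seed(7)
  t1 <- seq(0, pi, length.out = 30)
  t2 <- seq(pi, 2 * pi, length.out = 30)
  cres <- rbind(cbind(cos(t1), sin(t1)),
                cbind(1 + cos(t2), 0.5 + sin(t2))) +
    matrix(rnorm(120, sd = 0.02), 60, 2)
  pts <- rbind(cres, matrix(5 + runif(6) * 3, 3, 2))
  got <- dbscan_cluster(pts, eps = 0.3, min_samples = 4L)
  expect_identical(got, dbscan_bruteforce_oracle(pts, eps = 0.3, min_samples = 4L))
  expect_equal(sort(unique(got[1:60])), c(0L, 1L))
  expect_equal(got[61:63], rep(-1L, 3))
})

test_that("dbscan equals the oracle across random instances and parameter grids", {
  set.seed(11)
  for (rep in 1:10) {
    pts <- matrix(runif(2 * 120), 120, 2)
    for (eps in c(0.03, 0.08, 0.15)) for (ms in c(2L, 4L, 8L)) {
      expect_identical(dbscan_cluster(pts, eps, ms),
                       dbscan_bruteforce_oracle(pts, eps, ms))
    }
  }
})

test_that("dbscan labels are permutation-invariant and eps-monotone on separated blobs", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(80, sd = 0.1), 40, 2),
               matrix(rnorm(80, sd = 0.1), 40, 2) + 3,
               matrix(rnorm(40, sd = 0.1), 20, 2) + c(0, 6))
  base <- dbscan_cluster(pts, eps = 0.5, min_samples = 5L)
  perm <- sample(nrow(pts))
  permuted <- dbscan_cluster(pts[perm, ], eps = 0.5, min_samples = 5L)
  expect_identical(permuted, base[perm])

  n_clusters <- vapply(c(0.2, 0.5, 1, 4, 8), function(e)
    length(unique(setdiff(dbscan_cluster(pts, e, 5L), -1L))), integer(1))
  expect_true(all(diff(n_clusters) <= 0L))
})
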