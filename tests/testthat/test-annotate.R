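test_that("threshold selection reproduces worked examples", {
  # largest drop 0.95 -> 0.60, midpoint 0.775
  sp <- select_confidence_threshold(c(0.98, 0.97, 0.95, 0.60, 0.55, 0.50), K = 4)
  expect_equal(sp$threshold, 0.775)
  expect_equal(unname(sp$gap_location), c(0.95, 0.60))
  expect_false(sp$fallback_used)

  # no gap at all: fall back to the 1/K anchor
  flat <- select_confidence_threshold(rep(0.5, 6), K = 2)
  expect_true(flat$fallback_used)
  expect_equal(flat$threshold, 0.5)

  # single gap, midpoint not clipped
  one <- select_confidence_threshold(c(0.9, 0.3), K = 3)
  expect_equal(one$threshold, 0.6)

  # clipping into [1/K, 1)
  low <- select_confidence_threshold(c(0.30, 0.10, 0.09, 0.08), K = 4)
  expect_equal(low$threshold, 0.25)

  expect_error(select_confidence_threshold(numeric(0), K = 2), "nonempty")
  expect_error(select_confidence_threshold(c(0.5, 1.2), K = 2), "0, 1")
  expect_error(select_confidence_threshold(c(0.5, 0), K = 2), "0, 1")
})

test_that("threshold equals the exhaustive-scan oracle on random vectors", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(10:500, 1L)
    p <- switch(1L + (i %% 3),
                runif(n, 1e-6, 1),
                pmin(1, pmax(1e-6, rbeta(n, 5, 1))),
                sample(seq(0.1, 1, by = 0.1), n, replace = TRUE))
    K <- sample(2:10, 1L)
    got <- select_confidence_threshold(p, K)
    want <- threshold_oracle(p, K)
    expect_equal(got$threshold, want$threshold)
    expect_identical(got$fallback_used, want$fallback_used)
    expect_gte(got$threshold, 1 / K)
    expect_lt(got$threshold, 1)
  }
})

test_that("classifier separates well-separated classes and normalizes probabilities", {
  f <- blob_features(n_per = 100L,
                     centers = list(c(8, rep(0, 9)), c(-8, rep(0, 9))))
  labels <- data.frame(cell_id = f$cell_ids,
                       label = rep(c("alpha", "beta"), each = 100L))
  m <- train_classifier(f, labels, iterations = 60L, seed = 1L)
  pp <- predict_proba(m, f)
  expect_gte(mean(pp$label == labels$label), 0.99)
  expect_true(all(abs(rowSums(pp$prob) - 1) < 1e-6))
  expect_identical(colnames(pp$prob), c("alpha", "beta"))

  # deterministic refit
  m2 <- train_classifier(f, labels, iterations = 60L, seed = 1L)
  expect_equal(predict_proba(m2, f)$prob, pp$prob)

  expect_error(train_classifier(f, data.frame(cell_id = f$cell_ids,
                                              label = "same")),
               ">=2 reference cell types")
})

test_that("four-class probabilities respect the simplex floor on the argmax", {
  f <- blob_features(n_per = 60L,
                     centers = list(c(6, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                                    c(-6, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                                    c(0, 6, 0, 0, 0, 0, 0, 0, 0, 0),
                                    c(0, -6, 0, 0, 0, 0, 0, 0, 0, 0)))
  labels <- data.frame(cell_id = f$cell_ids,
                       label = rep(c("a", "b", "c", "d"), each = 60L))
  m <- train_classifier(f, labels, iterations = 40L, seed = 2L)
  pp <- predict_proba(m, f)
  expect_true(all(pp$pmax >= 0.25))
})

test_that("cluster IDs unseen at training are tolerated at prediction", {
  f <- blob_features(n_per = 50L, cluster = rep(c(0L, 1L), each = 50L))
  labels <- data.frame(cell_id = f$cell_ids,
                       label = rep(c("alpha", "beta"), each = 50L))
  m <- train_classifier(f, labels, iterations = 30L, seed = 3L)
  f_new <- f
  f_new$table$cluster <- factor(rep(c(7L, -1L), 50L), levels = c(-1L, 7L))
  pp <- expect_silent(predict_proba(m, f_new))
  expect_true(all(abs(rowSums(pp$prob) - 1) < 1e-6))

  f_bad <- f
  f_bad$table <- f_bad$table[, -1]
  expect_error(predict_proba(m, f_bad), "schema")
})

test_that("unlabeled reference cells are dropped with a warning", {
  f <- blob_features(n_per = 40L)
  labels <- data.frame(cell_id = f$cell_ids[1:70],
                       label = rep(c("alpha", "beta"), c(40, 30)))
  expect_warning(m <- train_classifier(f, labels, iterations = 20L, seed = 4L),
                 "lack a label")
  expect_equal(m$n_train, 70L)
})

test_that("label resolution applies the confidence rule cell by cell", {
  sp <- structure(list(threshold = 0.775, K = 4L,
                       gap_location = c(0.95, 0.6), gap = 0.35,
                       fallback_used = FALSE), class = "hicat_threshold")
  ann <- resolve_labels(c("beta", "beta", "beta"),
                        pmax = c(0.9, 0.5, 0.5), spec = sp,
                        cluster = c(2L, 6L, -1L))
  expect_equal(ann$final_label, c("beta", "novel_6", "unassigned"))
  expect_equal(ann$confident, c(TRUE, FALSE, FALSE))

  # exactly at threshold: "ge" keeps the supervised label, "gt" does not
  at <- function(op) resolve_labels("beta", 0.775, sp, 3L, confident_op = op)$final_label
  expect_equal(at("ge"), "beta")
  expect_equal(at("gt"), "novel_3")

  expect_error(resolve_labels(c("a", "b"), 0.5, sp, 1L), "row-aligned")
})

test_that("raising the threshold never makes a cell confident, and labels partition", {
  set.seed(19)
  n <- 300L
  pmax <- runif(n, 0.26, 1)
  cl <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE)
  labs <- sample(c("a", "b"), n, replace = TRUE)
  mk <- function(t) structure(list(threshold = t, K = 4L,
                                   gap_location = c(NA, NA), gap = 0,
                                   fallback_used = FALSE),
                              class = "hicat_threshold")
  lo <- resolve_labels(labs, pmax, mk(0.5), cl)
  hi <- resolve_labels(labs, pmax, mk(0.8), cl)
  expect_true(all(hi$confident <= lo$confident))  # confident set shrinks
  for (ann in list(lo, hi)) {
    is_known <- ann$confident
    is_novel <- startsWith(ann$final_label, "novel_")
    is_unass <- ann$final_label == "unassigned"
    expect_true(all(is_known + is_novel + is_unass == 1L))
  }
})

test_that("feature importance is normalized and finds a cluster-determined signal", {
  set.seed(23)
  n <- 240L
  cl <- rep(c(0L, 1L, 2L), each = n / 3)
  # PCs pure noise; the label is a function of the cluster ID alone
  bundle <- embedding_bundle(matrix(rnorm(n * 10), n, 10),
                             matrix(rnorm(n * 2), n, 2), cl,
                             batch = rep("reference", n),
                             cell_ids = paste0("c", seq_len(n)))
  f <- concatenate_features(bundle)
  labels <- data.frame(cell_id = f$cell_ids,
                       label = c("x", "y", "x")[cl + 1L])
  m <- train_classifier(f, labels, iterations = 50L, seed = 5L)
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-6)
  expect_identical(imp$feature[1], "cluster")
  expect_identical(imp$resolution[1], "cluster")
  # cumulative shares are monotone and bracketed
  expect_true(all(diff(imp$cumulative) >= -1e-12))
  top5 <- imp$cumulative[5]
  expect_gte(top5, imp$importance[1])
  expect_lte(top5, 1 + 1e-12)

  expect_error(feature_importance(list()), "fitted")
})
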