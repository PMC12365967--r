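test_that("overall accuracy is the exact match fraction", {
  expect_equal(overall_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(overall_accuracy(rep(c("a", "b"), 5), rep(c("a", "a"), 5)), 0.5)
  expect_error(overall_accuracy(character(0), character(0)), "empty")
  expect_error(overall_accuracy("a", c("a", "b")), "differ")
})

test_that("unseen mapping collapses everything outside the reference label set", {
  known <- c("alpha", "beta")
  expect_equal(map_to_unseen(c("acinar", "novel_3", "unassigned", "alpha"), known),
               c("unseen", "unseen", "unseen", "alpha"))
  expect_error(map_to_unseen("a", character(0)), "nonempty")
})

test_that("unseen F1 follows the binary precision/recall formulas", {
  truth <- rep(c("unseen", "alpha"), c(10, 10))
  pred <- c(rep("unseen", 9), "alpha", "unseen", rep("alpha", 9))
  got <- unseen_f1(truth, pred)  # TP 9, FP 1, FN 1
  expect_equal(got, c(precision = 0.9, recall = 0.9, f1 = 0.9))

  expect_equal(unseen_f1(truth, truth)[["f1"]], 1)

  all_neg <- rep("alpha", 5)
  expect_equal(unseen_f1(all_neg, c("unseen", rep("alpha", 4)))[["f1"]], 0)
  expect_warning(z <- unseen_f1(all_neg, all_neg), "no unseen")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("confusion alignment undoes a label swap and appends unmatched columns", {
  truth <- rep(c("a", "b"), each = 10)
  swapped <- rep(c("b", "a"), each = 10)
  conf <- aligned_confusion(truth, swapped)
  expect_equal(sum(diag(conf$counts)), 20)
  expect_equal(conf$alignment, c(b = "a", a = "b"))

  ident <- aligned_confusion(truth, truth)
  expect_identical(colnames(ident$counts), rownames(ident$counts))

  # with a single truth class, the surplus predicted label stays unaligned
  # and is appended after the aligned block
  conf2 <- aligned_confusion(rep("a", 20), c(rep("a", 12), rep("x", 8)))
  expect_identical(colnames(conf2$counts), c("a", "x"))
  expect_equal(conf2$alignment, c(a = "a"))
})

test_that("Hungarian alignment equals exhaustive permutation search", {
  set.seed(29)
  for (i in 1:20) {
    nr <- sample(2:4, 1L)
    nc <- sample(2:4, 1L)
    truth <- sample(letters[1:nr], 60, replace = TRUE)
    pred <- sample(LETTERS[1:nc], 60, replace = TRUE)
    conf <- aligned_confusion(truth, pred)
    got_mass <- sum(conf$counts[cbind(conf$alignment,
                                      names(conf$alignment))])
    want_mass <- alignment_mass_oracle(unclass(table(truth, pred)))
    expect_equal(got_mass, want_mass)
  }
})

test_that("per-class metrics reproduce printed worked examples", {
  # 444 ductal cells, 441 in the aligned novel column; one intruder there
  truth <- c(rep("ductal", 444), rep("alpha", 300))
  pred <- c(rep("novel_6", 441), rep("alpha", 3),
            "novel_6", rep("alpha", 299))
  conf <- aligned_confusion(truth, pred)
  m <- per_class_metrics(conf, "ductal")
  expect_equal(round(m[["recall"]], 3), 0.993)     # 441/444
  expect_equal(round(m[["precision"]], 3), 0.998)  # 441/442

  # 252 of 255 mast cells mapped to their novel column
  truth2 <- c(rep("mast", 255), rep("beta", 100))
  pred2 <- c(rep("novel_10", 252), rep("beta", 3), rep("beta", 100))
  m2 <- per_class_metrics(aligned_confusion(truth2, pred2), "mast")
  expect_equal(round(m2[["recall"]], 3), 0.988)
  expect_equal(m2[["precision"]], 1)              # column holds only matched cells

  expect_error(per_class_metrics(conf, "nope"), "not present")
})

test_that("per-class metrics are invariant under simultaneous label permutation", {
  set.seed(33)
  truth <- sample(c("a", "b", "c"), 90, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 90, replace = TRUE)
  base <- per_class_metrics(aligned_confusion(truth, pred), "b")
  relab <- c(a = "z1", b = "z2", c = "z3")
  perm <- per_class_metrics(aligned_confusion(relab[truth], relab[pred]), "z2")
  expect_equal(unname(base), unname(perm))
})

test_that("collapsing novel IDs to unseen can only help accuracy", {
  set.seed(37)
  known <- c("a", "b")
  truth <- sample(c("a", "b", "nov1", "nov2"), 200, replace = TRUE)
  pred <- sample(c("a", "b", "novel_0", "novel_1", "unassigned"), 200, replace = TRUE)
  acc_exact <- overall_accuracy(truth, pred)
  acc_unseen <- overall_accuracy(map_to_unseen(truth, known),
                                 map_to_unseen(pred, known))
  expect_gte(acc_unseen, acc_exact)
})

test_that("evaluate_annotation ties the metrics together", {
  fit <- mini_fit()
  sim <- mini_sim()
  truth <- sim$truth$cells[sim$truth$cells$batch == "query",
                           c("cell_id", "true_type")]
  res <- evaluate_annotation(fit$annotation, truth, unique(sim$ref_labels$label))
  expect_true(res$accuracy_unseen >= 0 && res$accuracy_unseen <= 1)
  expect_named(res$unseen, c("precision", "recall", "f1"))
  expect_equal(sum(res$confusion$counts), nrow(fit$annotation))
  expect_error(evaluate_annotation(fit$annotation, truth[-1, ],
                                   unique(sim$ref_labels$label)),
               "missing from truth")
})
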