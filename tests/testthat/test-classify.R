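test_that("stratified splits have the requested arithmetic and are seed-reproducible", {
  lab <- random_labels(30, 30, 9, seed = 91)
  sp <- split_train_test(lab, n_per_class = 25, seed = 1)
  expect_length(sp$train, 225)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(lab))
  counts <- table(lab[sp$train])
  expect_true(all(counts == 25))
  sp2 <- split_train_test(lab, n_per_class = 25, seed = 1)
  expect_identical(sp2$train, sp$train)
  # fractional request
  lab100 <- label_map(matrix(rep(1:2, each = 100), 10, 20))
  spf <- split_train_test(lab100, fraction = 0.03, seed = 2)
  expect_equal(as.vector(table(lab100[spf$train])), c(3, 3))
  # exact total via largest remainder
  spt <- split_train_test(lab, total = 309, seed = 3)
  expect_length(spt$train, 309)
  # over-request falls back to all-but-one with a warning
  tiny <- label_map(matrix(c(rep(1L, 95), rep(2L, 5)), 10, 10))
  expect_warning(sp3 <- split_train_test(tiny, n_per_class = 10, seed = 4),
                 "all but one")
  expect_equal(sum(tiny[sp3$train] == 2), 4)
})

test_that("both classifiers separate piecewise-constant scenes perfectly", {
  sc <- generate_scene(scene_spec(N = 4, Dmax = 0.1, rmax = 0, smin = 0.25,
                                  smax = 0.6, height = 24, width = 24, seed = 95))
  sp <- split_train_test(sc$labels, n_per_class = 5, seed = 5)
  for (kind in c("centroid", "svm")) {
    pred <- classify_pixels(sc$image, sc$labels, sp$train,
                            classifier_spec(kind, C = 10, gamma = 1, seed = 6))
    expect_equal(accuracy(pred, sc$labels, sp$test)$OA, 100)
  }
  # single training class gives a constant map
  one <- split_train_test(sc$labels, n_per_class = 5, seed = 7)
  train1 <- one$train[sc$labels[one$train] == 1]
  pred1 <- classify_pixels(sc$image, sc$labels, train1, classifier_spec("centroid"))
  expect_true(all(pred1 == 1))
})

test_that("label maps read from separate files re-align by their persisted levels", {
  truth <- random_labels(9, 9, 4, seed = 120)
  pred <- truth
  pred[1, 1] <- (pred[1, 1] %% 4L) + 1L  # different first pixel: re-reading
  tp <- file.path(tempdir(), "truth_align.png")
  pp <- file.path(tempdir(), "pred_align.png")
  write_labels(truth, tp)
  write_labels(pred, pp)
  t2 <- read_labels(tp); p2 <- read_labels(pp)
  # canonical ids permute across the two files, alignment restores them
  aligned <- align_labels(p2, t2)
  expect_equal(accuracy(aligned, t2)$OA, accuracy(pred, truth)$OA)
  expect_identical(matrix(as.integer(aligned), 9, 9), matrix(as.integer(pred), 9, 9))
})

test_that("accuracy metrics reproduce hand-computed confusion cases", {
  # perfect agreement
  lab <- random_labels(10, 10, 3, seed = 99)
  r <- accuracy(lab, lab)
  expect_equal(c(r$OA, r$AA, r$kappa), c(100, 100, 100))
  # confusion [[50, 0], [10, 40]]: OA 90, AA 90, kappa 80 (pe = 0.5)
  truth <- label_map(matrix(rep(1:2, each = 50), 10, 10))
  pred <- truth
  flip <- which(truth == 2)[1:10]
  pred[flip] <- 1L
  r <- accuracy(pred, truth)
  expect_equal(unname(r$confusion[1, 1]), 50)
  expect_equal(unname(r$confusion[2, 1]), 10)
  expect_equal(r$OA, 90); expect_equal(r$AA, 90); expect_equal(r$kappa, 80)
  expect_equal(unname(r$per_class), c(100, 80))
  # constant prediction on a balanced truth: chance-level agreement
  const <- truth; const[] <- 1L
  expect_equal(accuracy(const, truth)$kappa, 0)
  # kappa never exceeds OA when chance agreement is positive
  set.seed(100)
  for (i in 1:10) {
    p <- random_labels(8, 8, 3)
    t <- random_labels(8, 8, 3)
    rr <- accuracy(p, t)
    expect_lte(rr$kappa, rr$OA + 1e-9)
  }
  expect_error(accuracy(lab, lab, mask = integer(0)), "empty")
})
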