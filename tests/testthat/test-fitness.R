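test_that("ground-truth derivation yields consistent border/interior partitions", {
  hp <- halfplane_scene(8, 10)
  gt <- derive_ground_truth(hp$labels)
  # the two abutting columns are the border; cross-border sets non-empty
  expect_equal(sort(gt$border[[1]]), which(col(hp$labels) == 5))
  expect_equal(sort(gt$border[[2]]), which(col(hp$labels) == 6))
  expect_true(length(gt$pair_border[[1, 2]]) > 0)
  expect_true(length(gt$pair_border[[2, 1]]) > 0)
  # partitions: region = interior + border, disjoint
  for (k in 1:2) {
    expect_setequal(gt$region[[k]], c(gt$interior[[k]], gt$border[[k]]))
    expect_length(intersect(gt$interior[[k]], gt$border[[k]]), 0)
  }
  # single class: everything interior
  gt1 <- derive_ground_truth(label_map(matrix(1L, 6, 6)))
  expect_length(gt1$interior[[1]], 36)
  # one-pixel checkerboard: everything border, no interior anywhere
  cb <- label_map(outer(1:8, 1:8, function(r, c) ((r + c) %% 2) + 1L))
  gtc <- derive_ground_truth(cb)
  expect_true(all(lengths(gtc$interior) == 0))
  expect_true(all(lengths(gtc$border) > 0))
})

test_that("intra-class errors are zero on piecewise-constant scenes and match constant-angle layouts", {
  hp <- halfplane_scene(10, 12)
  gt <- derive_ground_truth(hp$labels)
  expect_equal(local_intra_error(hp$image, gt), 0)
  expect_equal(class_homogeneity(hp$image, gt, 1), 0)
  expect_equal(nonlocal_intra_error(hp$image, gt, fitness_config(seed = 1)), 0)
})

test_that("all fitness components match naive oracles on random instances with a shared sample stream", {
  set.seed(19)
  for (i in 1:20) {
    img <- random_image(12, 12, 3)
    lab <- random_labels(12, 12, 3)
    gt <- derive_ground_truth(lab)
    cfg <- fitness_config(V = 25, U = 25)
    expect_equal(local_intra_error(img, gt), oracle_local_intra(img, gt),
                 tolerance = 1e-12)
    for (k in 1:3)
      expect_equal(class_homogeneity(img, gt, k), oracle_homogeneity(img, gt, k),
                   tolerance = 1e-12)
    intra_pairs <- mgca:::draw_intra_pairs(gt, cfg)
    expect_equal(nonlocal_intra_error(img, gt, cfg, pairs = intra_pairs),
                 oracle_nonlocal_intra(img, gt, intra_pairs), tolerance = 1e-12)
    Hk <- vapply(1:3, function(k) class_homogeneity(img, gt, k), 0)
    inter_pairs <- mgca:::draw_inter_pairs(gt, cfg)
    expect_equal(inter_error(img, gt, Hk = Hk, config = cfg, pairs = inter_pairs),
                 oracle_inter(img, gt, Hk, inter_pairs), tolerance = 1e-12)
    rep <- total_cost(img, gt, fitness_config(V = 25, U = 25, seed = 100 + i))
    expect_equal(rep$e, max(rep$e_intra, rep$e_inter))
    expect_equal(rep$e_intra, max(rep$e_local_intra, rep$e_nonlocal_intra))
    expect_true(all(unlist(rep[1:5]) >= 0 & unlist(rep[1:5]) <= 1))
  }
})

test_that("the non-local term approaches its closed-form expectation for a two-spectrum class", {
  # one class whose interior takes two spectra at angle a with equal
  # frequency: a random pair has expected angle a / 2
  H <- 20; W <- 20
  lab <- label_map(matrix(1L, H, W))
  img <- array(0, c(H, W, 2))
  set.seed(23)
  pick <- matrix(sample(c(TRUE, FALSE), H * W, replace = TRUE), H, W)
  img[, , 1][pick] <- 1
  img[, , 2][!pick] <- 1
  a <- spectral_angle(c(1, 0), c(0, 1))  # = 1
  gt <- derive_ground_truth(lab)
  est <- nonlocal_intra_error(spectral_image(img), gt,
                              fitness_config(V = 10000, seed = 3))
  p <- mean(pick)  # P(angle = a) = 2 p (1 - p)
  expect_equal(est, 2 * p * (1 - p) * a, tolerance = 0.05)
})

test_that("fitness is invariant to band count padding-free rescaling and is seed-reproducible", {
  img <- random_image(12, 12, 4, seed = 29)
  lab <- random_labels(12, 12, 3, seed = 30)
  gt <- derive_ground_truth(lab)
  r1 <- total_cost(img, gt, fitness_config(seed = 7))
  r2 <- total_cost(img, gt, fitness_config(seed = 7))
  expect_identical(unlist(r1[1:5]), unlist(r2[1:5]))
  # global positive rescaling leaves every spectral angle unchanged
  scaled <- spectral_image(unclass(img) * 0.37)
  r3 <- total_cost(scaled, gt, fitness_config(seed = 7))
  expect_equal(unlist(r1[1:5]), unlist(r3[1:5]), tolerance = 1e-9)
})

test_that("cost extremes: ideal segmentations score 0, constant images with several classes score 1", {
  sc <- generate_scene(scene_spec(N = 4, Dmax = 0, rmax = 0, smin = 0.2,
                                  smax = 0.6, seed = 17))
  gt <- derive_ground_truth(sc$labels)
  expect_lt(total_cost(sc$image, gt, fitness_config(seed = 1))$e, 1e-6)
  const <- spectral_image(array(0.4, c(16, 16, 3)))
  lab2 <- label_map(cbind(matrix(1L, 16, 8), matrix(2L, 16, 8)))
  expect_equal(total_cost(const, derive_ground_truth(lab2),
                          fitness_config(seed = 1))$e, 1)
})
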