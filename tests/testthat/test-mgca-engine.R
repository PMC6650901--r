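test_that("gradient masks have the printed structure: antisymmetry, zero center column, unit positive sums", {
  mk <- gradient_masks()
  for (nm in c("mx3", "mx5", "mx7")) {
    m <- mk[[nm]]
    h <- (ncol(m) + 1) / 2
    expect_true(all(m[, h] == 0))
    expect_equal(m[, seq_len(h - 1)], -m[, ncol(m):(h + 1)])
  }
  expect_equal(mk$my3, t(mk$mx3))
  expect_equal(sum(mk$mx3[mk$mx3 > 0]), 1, tolerance = 1e-12)
  expect_equal(sum(mk$mx5[mk$mx5 > 0]), 1, tolerance = 1e-12)
  # the verbatim 361/1527 scale undershoots exact normalization by ~5.6e-7
  expect_equal(sum(mk$mx7[mk$mx7 > 0]), 1786589 / 1786590, tolerance = 1e-12)
  expect_equal(mk$mx7, oracle_masks()$mx7, tolerance = 1e-15)
})

test_that("gradients on a vertical step edge point across the edge", {
  # binary edge in spectral angle: left half orthogonal to right half
  img <- array(0, c(7, 7, 2)); img[, 1:3, 1] <- 1; img[, 4:7, 2] <- 1
  gf <- gradient_features(spectral_image(img))
  # cell just right of the edge: its three left 3x3-window cells sit at
  # angle 1, the rest at 0 -> GX3 = -1, GY3 = 0
  expect_equal(gf[4, 4, 1], 1, tolerance = 1e-12)        # |G3|
  expect_equal(gf[4, 4, 4], pi, tolerance = 1e-12)       # phi3
  # uniform image: all moduli zero, angles 0 by convention
  gu <- gradient_features(spectral_image(array(0.6, c(8, 8, 3))))
  expect_true(all(gu == 0))
})

test_that("gradient extraction matches the brute-force oracle to 1e-12", {
  set.seed(7)
  for (i in 1:20) {
    H <- sample(12:16, 1); W <- sample(12:16, 1)
    img <- random_image(H, W, 5)
    gf <- gradient_features(img)
    for (j in 1:4) {
      r <- sample(H, 1); c <- sample(W, 1)
      expect_equal(as.vector(gf[r, c, ]), oracle_gradients(img, r, c),
                   tolerance = 1e-12)
    }
  }
})

test_that("rule matching is exact on constructed matches and invariant to rotation and reflection", {
  set.seed(11)
  rules <- random_rule_set(12)
  k <- 5
  rl <- unclass(rules)[k, ]
  feat <- c(rl[1:3], 0, rl[4], rl[5])  # the rule's own vectors
  res <- match_rule(feat, rules)
  expect_equal(res$rule, k)
  expect_lt(res$distance, 1e-6)
  expect_lt(min(abs(c(res$phi, res$phi - 2 * pi))), 1e-3)
  # rotation by psi: distance still ~0 and recovered rotation ~psi
  psi <- 1.234
  feat_rot <- c(rl[1:3], (c(0, rl[4], rl[5]) + psi) %% (2 * pi))
  res_rot <- match_rule(feat_rot, rules)
  expect_equal(res_rot$rule, k)
  expect_lt(res_rot$distance, 1e-6)
  expect_lt(min(abs(res_rot$phi - psi + c(-2 * pi, 0, 2 * pi))), 1e-3)
  # reflection about the x axis: angles negate
  feat_ref <- c(rl[1:3], (-c(0, rl[4], rl[5])) %% (2 * pi))
  res_ref <- match_rule(feat_ref, rules)
  expect_equal(res_ref$rule, k)
  expect_lt(res_ref$distance, 1e-6)
})

test_that("rule matching agrees with a 4096-step rotation-grid oracle", {
  set.seed(13)
  rules <- random_rule_set(30)
  for (i in 1:20) {
    feat <- c(runif(3, 0, 2), runif(3, 0, 2 * pi))
    res <- match_rule(feat, rules)
    ora <- oracle_match(feat, rules)
    tol <- grid_tolerance(rules) + 1e-9
    expect_lt(abs(res$distance - ora$distance), 2 * tol)
    # the selected rule must achieve a grid distance within tolerance of
    # the oracle optimum (ties between near-equal rules are acceptable)
    expect_lt(ora$per_rule[res$rule] - ora$distance, 2 * tol)
  }
})

test_that("the state update reproduces the hand-evaluated weight layout", {
  img <- random_image(7, 7, 3, seed = 21)
  # phi + theta = 0: the target point lands exactly on the east neighbor;
  # contributors are that neighbor (weight f_th) and its three other axis
  # neighbors (weight 1); with f_th = 2 the weights are 2/7, 1/7 each, and
  # self 2/7
  s <- update_cell(img, 4, 4, 0, 0)
  expected <- 2 / 7 * img[4, 5, ] + 1 / 7 * (img[3, 5, ] + img[5, 5, ] + img[4, 6, ]) +
    2 / 7 * img[4, 4, ]
  expect_equal(as.vector(s), as.vector(expected), tolerance = 1e-12)
  # arbitrary direction: update stays a convex combination of neighborhood
  # spectra (bounded by the local min/max per band)
  for (dir in seq(0, 2 * pi, length.out = 9)) {
    s <- update_cell(img, 4, 4, dir, 0)
    for (b in 1:3) {
      win <- img[2:6, 2:6, b]
      expect_gte(s[b], min(win) - 1e-12)
      expect_lte(s[b], max(win) + 1e-12)
    }
  }
  # corner cell with the target outside the image: contributors drop out
  # but the result remains a valid convex combination
  s <- update_cell(img, 1, 1, pi, pi / 2)  # direction 3*pi/2: straight up, outside
  expect_true(all(is.finite(s)))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("the automaton preserves shape, stays in [0, 1] and fixes uniform images for any band count", {
  rules <- random_rule_set(8, seed = 31)
  for (B in c(3, 64, 115)) {
    img <- random_image(8, 8, B, seed = B)
    out <- run_mgca(img, rules, mgca_config(iterations = 1))
    expect_identical(dim(out), dim(img))
    expect_true(min(out) >= 0 && max(out) <= 1)
    u <- spectral_image(array(0.42, c(8, 8, B)))
    expect_equal(as.vector(run_mgca(u, rules, mgca_config(iterations = 3))),
                 as.vector(u), tolerance = 1e-12)
  }
})

test_that("K = 0 is the identity and repeated runs are bit-identical", {
  img <- random_image(10, 10, 3, seed = 5)
  rules <- random_rule_set(10, seed = 6)
  expect_identical(as.vector(run_mgca(img, rules, mgca_config(iterations = 0))),
                   as.vector(img))
  a <- run_mgca(img, rules, mgca_config())
  b <- run_mgca(img, rules, mgca_config())
  expect_identical(as.vector(a), as.vector(b))
})
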