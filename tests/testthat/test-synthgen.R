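test_that("generated scenes honor the class count, are deterministic under a seed and respect the angle window", {
  sp <- scene_spec(N = 5, seed = 71)
  sc <- generate_scene(sp)
  expect_equal(attr(sc$labels, "n_classes"), 5)
  expect_s3_class(sc$image, "spectral_image")
  expect_true(min(sc$image) >= 0 && max(sc$image) <= 1)
  sc2 <- generate_scene(sp)
  expect_identical(as.vector(sc2$image), as.vector(sc$image))
  expect_identical(as.vector(sc2$labels), as.vector(sc$labels))
  # adjacent-class base-spectrum angles inside [smin, smax] by construction
  ang <- sc$realized$adjacent_angles$angle
  expect_true(all(ang >= sp$smin - 1e-9 & ang <= sp$smax + 1e-9))
})

test_that("rmax = 0 gives piecewise-constant scenes that are ideal segmentations", {
  sc <- generate_scene(scene_spec(N = 4, Dmax = 0, rmax = 0, smin = 0.2,
                                  smax = 0.6, seed = 73))
  expect_equal(sc$realized$rmax, 0, tolerance = 1e-9)
  expect_lt(total_cost(sc$image, derive_ground_truth(sc$labels),
                       fitness_config(seed = 1))$e, 1e-6)
})

test_that("the realized intra-class angle lands within 10 percent of the request across a spec grid", {
  for (rmax in c(0.02, 0.05, 0.1)) {
    for (Dmax in c(0, 0.3)) {
      sc <- generate_scene(scene_spec(N = 4, Dmax = Dmax, rmax = rmax,
                                      smin = 0.2, smax = 0.6,
                                      seed = round(1000 * rmax + 10 * Dmax)))
      expect_lt(abs(sc$realized$rmax - rmax) / rmax, 0.10)
    }
  }
})

test_that("parameter estimation inverts the generator within 20 percent and reads trivial scenes exactly", {
  # trivial cases first
  hp <- halfplane_scene(12, 12)
  est <- estimate_params(hp$image, hp$labels, seed = 1)
  expect_equal(est$N, 2)
  expect_equal(est$rmax, 0, tolerance = 1e-9)
  a <- spectral_angle(c(1, 0, 0), c(0, 1, 0))
  expect_equal(est$by_class$s_i, c(a, a), tolerance = 1e-9)
  # 3 x 3 grid of scene specs: requested rmax and realized inter-class
  # distances recovered within 20 percent relative error
  for (rmax in c(0.02, 0.05, 0.08)) {
    for (smin in c(0.12, 0.22, 0.32)) {
      sp <- scene_spec(N = 5, Dmax = 0.3, rmax = rmax, smin = smin,
                       smax = smin + 0.25, height = 40, width = 40,
                       seed = round(1000 * rmax + 100 * smin))
      sc <- generate_scene(sp)
      est <- estimate_params(sc$image, sc$labels, seed = 2)
      expect_equal(est$N, 5)
      expect_lt(abs(est$rmax - rmax) / rmax, 0.20)
      # mean estimated inter-class distance vs the value implied by the
      # realized base spectra (other classes weighted by pixel count)
      S <- sc$realized$base_spectra
      implied <- vapply(1:5, function(k) {
        others <- setdiff(1:5, k)
        w <- vapply(others, function(j) sum(sc$labels == j), 0)
        a <- vapply(others, function(j) spectral_angle(S[k, ], S[j, ]), 0)
        sum(w * a) / sum(w)
      }, 0)
      expect_lt(abs(mean(est$by_class$s_i) - mean(implied)) / mean(implied), 0.20)
    }
  }
})

test_that("larger Dmax produces more tortuous borders", {
  tort <- vapply(c(0, 0.5), function(D) {
    mean(vapply(1:5, function(s) {
      sc <- generate_scene(scene_spec(N = 4, Dmax = D, rmax = 0, smin = 0.2,
                                      smax = 0.6, height = 40, width = 40,
                                      seed = 500 + s + round(100 * D)))
      sum(sc$borders == 0) / length(sc$borders)
    }, 0))
  }, 0)
  expect_gt(tort[2], tort[1])
})

test_that("multiband fixtures are deterministic, sized for the study and convex in mixture mode", {
  fx <- make_multiband_fixture("noise", seed = 81)
  expect_identical(dim(fx$image), c(80L, 80L, 64L))
  expect_equal(attr(fx$labels, "n_classes"), 5)
  fx2 <- make_multiband_fixture("noise", seed = 81)
  expect_identical(as.vector(fx$image), as.vector(fx2$image))
  # level 0: piecewise-constant cube
  fx0 <- make_multiband_fixture("noise", level = 0, seed = 82)
  expect_equal(fx0$realized$rmax, 0, tolerance = 1e-9)
  # mixture mode: every pixel lies in the convex hull of the base spectra
  mx <- make_multiband_fixture("mixture", seed = 83)
  S <- mx$realized$base_spectra
  for (b in c(1, 13, 40, 64)) {
    expect_gte(min(mx$image[, , b]), min(S[, b]) - 1e-9)
    expect_lte(max(mx$image[, , b]), max(S[, b]) + 1e-9)
  }
  expect_error(make_multiband_fixture("mixture", level = 1.4), "\\[0, 1\\]")
})
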