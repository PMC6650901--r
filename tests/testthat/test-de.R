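test_that("the initial population is uniform over the parameter space and seed-reproducible", {
  cfg <- de_config(NP = 60, n_rules = 30, seed = 101)
  pop <- init_population(cfg)
  expect_equal(dim(pop), c(60, 180))
  b <- mgca:::genome_bounds(30)
  expect_true(all(sweep(pop, 2, b$lower, ">=")))
  expect_true(all(sweep(pop, 2, b$upper, "<=")))
  expect_identical(init_population(cfg), pop)
  # empirical gene means near the interval midpoints (3 standard errors)
  mod <- pop[, !b$wrap]; ang <- pop[, b$wrap]
  se_mod <- (2 / sqrt(12)) / sqrt(length(mod))
  se_ang <- (2 * pi / sqrt(12)) / sqrt(length(ang))
  expect_lt(abs(mean(mod) - 1), 3 * se_mod)
  expect_lt(abs(mean(ang) - pi), 3 * se_ang)
})

test_that("mutation follows the weighted-difference formula and repairs bounds", {
  b <- mgca:::genome_bounds(1)
  x1 <- c(0.5, 0.5, 0.5, 1, 1, 1)
  x2 <- c(1.0, 1.0, 1.0, 2, 2, 2)
  x3 <- c(0.2, 0.2, 0.2, 1, 1, 1)
  v <- de_mutate(x1, x2, x3, F = 0.8, bounds = b)
  expect_equal(v[1], 0.5 + 0.8 * 0.8, tolerance = 1e-12)  # 1.14, within bounds
  # zero difference: mutant equals the base vector
  expect_equal(de_mutate(x1, x2, x2, F = 0.8, bounds = b), x1)
  # modulus genes clip, angle genes wrap
  v <- de_mutate(c(1.9, 0, 0, 6.0, 0, 0), c(1, 1, 1, 2, 2, 2),
                 c(0.5, 1, 1, 0.75, 2, 2), F = 0.8, bounds = b)
  expect_equal(v[1], 2)                      # 1.9 + 0.4 clipped
  expect_equal(v[4], 7.0 - 2 * pi, tolerance = 1e-12)  # 6 + 1 wrapped
})

test_that("binomial crossover honors CR extremes and the forced-gene expectation", {
  set.seed(31)
  target <- runif(180); mutant <- runif(180)
  expect_identical(de_crossover(target, mutant, CR = 1), mutant)
  tr0 <- de_crossover(target, mutant, CR = 0)
  expect_equal(sum(tr0 != target), 1)  # exactly the forced gene
  # inheritance rate over many trials ~ CR + (1 - CR) / D
  CR <- 0.7; D <- 180; n <- 400
  rate <- mean(replicate(n, mean(de_crossover(target, mutant, CR) == mutant)))
  expected <- CR + (1 - CR) / D
  se <- sqrt(expected * (1 - expected) / (n * D))
  expect_lt(abs(rate - expected), 5 * se)
})

test_that("the DE core minimizes a 10-D sphere below 1e-6 within 200 generations", {
  sphere <- function(x) sum(x^2)
  res <- de_optimize(sphere, lower = rep(-5, 10), upper = rep(5, 10),
                     NP = 50, F = 0.5, CR = 0.9, max_generations = 200,
                     min_cost = 1e-6, seed = 7)
  expect_lte(res$best_cost, 1e-6)
  expect_true(all(diff(res$trace$best) <= 0))  # greedy selection is monotone
})

test_that("fixed-image evolution has monotone non-increasing best cost over 20 generations", {
  sc <- generate_scene(scene_spec(N = 2, Dmax = 0.1, rmax = 0.06, smin = 0.3,
                                  smax = 0.7, height = 32, width = 32, seed = 55))
  cfg <- de_config(NP = 8, max_generations = 20, n_rules = 10, iterations = 5,
                   mode = "fixed-image", V = 30, U = 30, seed = 56)
  evo <- evolve_rules(cfg, list(sc))
  expect_equal(nrow(evo$trace), 20)
  expect_true(all(diff(evo$trace$best) <= 1e-12))
  expect_s3_class(evo$rules, "rule_set")
  expect_equal(nrow(evo$rules), 10)
  # bounds closure of the returned genome
  g <- mgca:::rules_to_genome(evo$rules)
  b <- mgca:::genome_bounds(10)
  expect_true(all(g >= b$lower - 1e-12 & g <= b$upper + 1e-12))
})

test_that("evolution stops after exactly max_generations when the cost floor is unreachable", {
  sc <- generate_scene(scene_spec(N = 2, height = 16, width = 16, seed = 60))
  cfg <- de_config(NP = 4, max_generations = 2, n_rules = 2, iterations = 1,
                   mode = "fixed-image", V = 10, U = 10, seed = 61)
  evo <- evolve_rules(cfg, list(sc))
  expect_equal(max(evo$trace$generation), 2)
})
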