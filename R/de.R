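# Differential evolution (rand/1/bin) over transition-rule genomes, and a
# generic bound-constrained DE core reused for self-checks.

#' Differential evolution configuration
#'
#' Defaults follow the standard parametrization for this problem family:
#' population `NP = 100`, differential weight `F = 0.8`, crossover rate
#' `CR = 0.7`, 30 rules (genome length 180), and stopping at
#' `max_generations` or when the best cost drops below `min_cost = 1e-6`.
#'
#' @param NP population size (>= 4; rand/1 mutation needs three distinct
#'   donors besides the target).
#' @param F differential weight in `(0, 2]`.
#' @param CR crossover rate in `[0, 1]`.
#' @param n_rules number of transition rules `M`; the genome has `6 * M`
#'   genes.
#' @param max_generations generation budget.
#' @param min_cost early-stopping cost threshold.
#' @param iterations automaton sweeps `K` per evaluation.
#' @param mode `"fresh-per-comparison"` scores every target/trial duel on
#'   one freshly generated scene (a fair paired comparison under fitness
#'   noise); `"fixed-image"` scores everything on one fixed scene, making
#'   the best cost monotone non-increasing.
#' @param V,U sampling sizes of the stochastic cost terms, see
#'   [fitness_config()].
#' @param seed master seed; the whole run is a pure function of
#'   (configuration, seed).
#' @return A list of class `de_config`.
#' @export
de_config <- function(NP = 100, F = 0.8, CR = 0.7, n_rules = 30,
                      max_generations = 500, min_cost = 1e-6,
                      iterations = 10,
                      mode = c("fresh-per-comparison", "fixed-image"),
                      V = 100, U = 100, seed = NULL) {
  stopifnot(NP >= 4, F > 0, F <= 2, CR >= 0, CR <= 1, n_rules >= 1,
            max_generations >= 1, iterations >= 0)
  structure(list(NP = as.integer(NP), F = F, CR = CR,
                 n_rules = as.integer(n_rules),
                 D = 6L * as.integer(n_rules),
                 max_generations = as.integer(max_generations),
                 min_cost = min_cost, iterations = as.integer(iterations),
                 mode = match.arg(mode), V = as.integer(V), U = as.integer(U),
                 seed = seed),
            class = "de_config")
}

# per-gene bounds of a rule genome: moduli in [0, 2], angles in [0, 2 * pi]
genome_bounds <- function(n_rules) {
  lower <- rep(0, 6 * n_rules)
  upper <- rep(c(2, 2, 2, 2 * pi, 2 * pi, 2 * pi), n_rules)
  wrap <- rep(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), n_rules)
  list(lower = lower, upper = upper, wrap = wrap)
}

#' Initial population, uniform over the parameter space
#'
#' @param config a [de_config()]; if `config$seed` is set it seeds the
#'   generator.
#' @return An `NP x D` matrix of genomes within bounds.
#' @export
init_population <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  b <- genome_bounds(config$n_rules)
  t(replicate(config$NP, runif(config$D, b$lower, b$upper)))
}

# clip non-circular genes to their bounds; wrap circular (angle) genes
repair_genome <- function(v, bounds) {
  w <- bounds$wrap
  v[!w] <- pmin(pmax(v[!w], bounds$lower[!w]), bounds$upper[!w])
  v[w] <- v[w] %% bounds$upper[w]
  v
}

#' rand/1 mutation
#'
#' `v = x_r1 + F * (x_r2 - x_r3)`, followed by bounds repair: moduli are
#' clipped to `[0, 2]`, angles wrapped modulo `2 * pi`.
#'
#' @param x_r1,x_r2,x_r3 three mutually distinct population members.
#' @param F differential weight.
#' @param bounds bounds as returned by the internal genome layout (when
#'   `NULL`, the rule-genome bounds matching the vector length are used).
#' @return The repaired mutant genome.
#' @export
de_mutate <- function(x_r1, x_r2, x_r3, F, bounds = NULL) {
  if (is.null(bounds)) {
    if (length(x_r1) %% 6 != 0) stop("genome length must be a multiple of 6")
    bounds <- genome_bounds(length(x_r1) %/% 6)
  }
  repair_genome(x_r1 + F * (x_r2 - x_r3), bounds)
}

#' Binomial crossover
#'
#' Gene `j` of the trial comes from the mutant iff a uniform draw is at
#' most `CR` or `j` equals one forced index (drawn uniformly), which
#' guarantees the trial inherits at least one mutant gene.
#'
#' @param target,mutant genomes of equal length.
#' @return The trial genome.
#' @param CR crossover rate.
#' @export
de_crossover <- function(target, mutant, CR) {
  D <- length(target)
  stopifnot(length(mutant) == D)
  from_mutant <- runif(D) <= CR
  from_mutant[sample.int(D, 1)] <- TRUE
  ifelse(from_mutant, mutant, target)
}

#' Generic bound-constrained differential evolution
#'
#' The rand/1/bin core decoupled from the automaton, minimizing an
#' arbitrary objective.  Greedy selection: the trial replaces the target
#' only when strictly better, so the best cost is monotone non-increasing.
#'
#' @param objective function of one numeric vector returning a scalar cost.
#' @param lower,upper bounds (recycled to a common length `D`).
#' @param NP,F,CR,max_generations,min_cost as in [de_config()].
#' @param wrap logical vector: genes treated as circular (wrapped into
#'   `[lower, upper)`) instead of clipped.
#' @param seed optional integer seed.
#' @return A list: `best` (genome), `best_cost`, `trace` (data frame with
#'   `generation`, `best`, `mean`), `population`, `costs`.
#' @export
de_optimize <- function(objective, lower, upper, NP = 50, F = 0.8, CR = 0.7,
                        max_generations = 200, min_cost = -Inf, wrap = FALSE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- max(length(lower), length(upper))
  lower <- rep_len(lower, D); upper <- rep_len(upper, D)
  bounds <- list(lower = lower, upper = upper, wrap = rep_len(wrap, D))
  pop <- t(replicate(NP, runif(D, lower, upper)))
  costs <- apply(pop, 1, objective)
  trace <- data.frame(generation = 0L, best = min(costs), mean = mean(costs))
  for (g in seq_len(max_generations)) {
    for (i in seq_len(NP)) {
      r <- sample(seq_len(NP)[-i], 3)
      mutant <- de_mutate(pop[r[1], ], pop[r[2], ], pop[r[3], ], F, bounds)
      trial <- de_crossover(pop[i, ], mutant, CR)
      tc <- objective(trial)
      if (tc < costs[i]) { pop[i, ] <- trial; costs[i] <- tc }
    }
    trace <- rbind(trace, data.frame(generation = g, best = min(costs),
                                     mean = mean(costs)))
    if (min(costs) <= min_cost) break
  }
  i <- which.min(costs)
  list(best = pop[i, ], best_cost = costs[i], trace = trace,
       population = pop, costs = costs)
}

# score one genome on one scene: run the automaton K iterations, then the
# segmentation cost against the scene's ground truth
evaluate_genome <- function(genome, scene, cfg, pair_seed) {
  rules <- genome_to_rules(genome)
  out <- run_mgca(scene$image, rules, mgca_config(iterations = cfg$iterations))
  fit <- total_cost(out, scene$gt, fitness_config(V = cfg$V, U = cfg$U,
                                                  seed = pair_seed))
  fit$e
}

prepare_scene <- function(bundle) {
  list(image = bundle$image, gt = derive_ground_truth(bundle$labels))
}

#' Evolve a transition rule set
#'
#' Differential evolution over rule genomes.  Each evaluation decodes the
#' genome, runs the automaton for `config$iterations` sweeps on a training
#' scene and scores the output with [total_cost()] against the scene's
#' ground truth.  In `"fresh-per-comparison"` mode every target/trial duel
#' draws one fresh scene from `scenes` and both genomes are scored on it
#' (with a shared sampling seed for the stochastic cost terms); in
#' `"fixed-image"` mode the first scene is used throughout and costs are
#' cached, making the best cost monotone non-increasing.
#'
#' @param config a [de_config()].
#' @param scenes either a [scene_spec()] (scenes are generated on demand)
#'   or a list of scene bundles as returned by [generate_scene()].
#' @return A list of class `evolution_result`: `rules` (the best
#'   [rule_set()]), `best_cost`, `trace` (per-generation best and mean
#'   duel costs) and `config`.
#' @export
evolve_rules <- function(config, scenes) {
  if (!is.null(config$seed)) set.seed(config$seed)
  fresh <- config$mode == "fresh-per-comparison"
  draw_scene <- if (inherits(scenes, "scene_spec")) {
    function() {
      sp <- scenes
      sp$seed <- sample.int(.Machine$integer.max, 1)
      prepare_scene(generate_scene(sp))
    }
  } else if (is.list(scenes) && length(scenes)) {
    pool <- lapply(if (inherits(scenes, "scene_bundle")) list(scenes) else scenes,
                   prepare_scene)
    function() pool[[sample.int(length(pool), 1)]]
  } else stop("`scenes` must be a scene_spec or a non-empty list of scene bundles")

  bounds <- genome_bounds(config$n_rules)
  pop <- t(replicate(config$NP, runif(config$D, bounds$lower, bounds$upper)))
  NP <- config$NP

  if (!fresh) {
    fixed <- if (inherits(scenes, "scene_spec")) draw_scene() else
      prepare_scene(if (inherits(scenes, "scene_bundle")) scenes else scenes[[1]])
    pair_seed <- sample.int(.Machine$integer.max, 1)
    costs <- apply(pop, 1, evaluate_genome, scene = fixed, cfg = config,
                   pair_seed = pair_seed)
  }

  trace <- NULL
  best_genome <- pop[1, ]; best_cost <- Inf
  for (g in seq_len(config$max_generations)) {
    gen_costs <- numeric(NP)
    for (i in seq_len(NP)) {
      r <- sample(seq_len(NP)[-i], 3)
      mutant <- de_mutate(pop[r[1], ], pop[r[2], ], pop[r[3], ], config$F, bounds)
      trial <- de_crossover(pop[i, ], mutant, config$CR)
      if (fresh) {
        duel_scene <- draw_scene()
        pair_seed <- sample.int(.Machine$integer.max, 1)
        c_target <- evaluate_genome(pop[i, ], duel_scene, config, pair_seed)
        c_trial <- evaluate_genome(trial, duel_scene, config, pair_seed)
        if (c_trial < c_target) pop[i, ] <- trial
        gen_costs[i] <- min(c_target, c_trial)
      } else {
        c_trial <- evaluate_genome(trial, fixed, config, pair_seed)
        if (c_trial < costs[i]) { pop[i, ] <- trial; costs[i] <- c_trial }
        gen_costs[i] <- costs[i]
      }
    }
    gen_best <- min(gen_costs)
    if (gen_best <= best_cost) {
      best_cost <- gen_best
      best_genome <- pop[which.min(gen_costs), ]
    }
    trace <- rbind(trace, data.frame(generation = g, best = gen_best,
                                     mean = mean(gen_costs)))
    if (gen_best <= config$min_cost) break
  }
  if (fresh) {
    # duel costs are scene-specific and noisy, so pick the final genome by
    # re-scoring the last population on a small set of validation scenes
    val <- replicate(3, draw_scene(), simplify = FALSE)
    val_seeds <- sample.int(.Machine$integer.max, length(val))
    val_costs <- vapply(seq_len(NP), function(i) {
      mean(vapply(seq_along(val), function(s)
        evaluate_genome(pop[i, ], val[[s]], config, val_seeds[s]), 0))
    }, 0)
    best_genome <- pop[which.min(val_costs), ]
    best_cost <- min(val_costs)
  }
  structure(list(rules = genome_to_rules(best_genome), best_cost = best_cost,
                 trace = trace, config = config),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf("<evolution_result> %d rules, best cost %.5f after %d generations\n",
              nrow(x$rules), x$best_cost, max(x$trace$generation)))
  invisible(x)
}
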