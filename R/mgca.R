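# The multi-gradient cellular automaton: gradient masks, the transition
# rule table, rotation/reflection-invariant rule matching and the
# synchronous iteration loop.

#' Spectral-angle gradient masks
#'
#' The column-gradient masks for window sizes 3, 5 and 7.  Off-center
#' coefficients are `sign(dx) / (dx^2 + dy^2)` (the inverse squared
#' distance to the window center, signed by side); the central column is
#' zero.  Each mask carries a scale factor -- 1/2, 10/33 and 361/1527 --
#' so that its positive coefficients sum to (almost exactly) one.  The
#' printed factor 361/1527 for the 7x7 mask is kept verbatim; it differs
#' from the exact normalizer 1170/4949 only in the seventh decimal.  Row
#' gradients use the transposes.
#'
#' @return A list with matrices `mx3`, `mx5`, `mx7` and their transposes
#'   `my3`, `my5`, `my7`.
#' @export
gradient_masks <- function() {
  base <- function(n, scale) {
    h <- (n - 1) / 2
    m <- outer(-h:h, -h:h, function(dy, dx) ifelse(dx == 0, 0, sign(dx) / (dx^2 + dy^2)))
    scale * m
  }
  mx3 <- base(3, 1 / 2)
  mx5 <- base(5, 10 / 33)
  mx7 <- base(7, 361 / 1527)
  list(mx3 = mx3, mx5 = mx5, mx7 = mx7,
       my3 = t(mx3), my5 = t(mx5), my7 = t(mx7))
}

#' Transition rule set
#'
#' An `M x 6` table of transition rules.  Columns 1-3 are the condition
#' gradient moduli at window sizes 3/5/7 (in `[0, 2]`), columns 4-5 the
#' condition angles of the size-5 and size-7 gradients relative to the
#' size-3 gradient (whose angle is fixed at 0), and column 6 the action
#' angle `theta` (all angles in `[0, 2 * pi]`).  A rule set is the genome
#' the differential evolution operates on (genome length `6 * M`).
#'
#' @param x numeric `M x 6` matrix, or a numeric vector of length `6 * M`
#'   (row-wise rule blocks, the genome encoding).
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(x) {
  if (inherits(x, "rule_set")) return(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) %% 6 != 0) stop("genome length must be a multiple of 6")
    x <- matrix(x, ncol = 6, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 6) stop("`x` must be an M x 6 matrix")
  if (nrow(x) < 1) stop("a rule set needs at least one rule")
  if (any(x[, 1:3] < 0 - 1e-9) || any(x[, 1:3] > 2 + 1e-9))
    stop("gradient moduli must lie in [0, 2]")
  if (any(x[, 4:6] < 0 - 1e-9) || any(x[, 4:6] > 2 * pi + 1e-9))
    stop("rule angles must lie in [0, 2 * pi]")
  colnames(x) <- c("mod3", "mod5", "mod7", "phi5", "phi7", "theta")
  structure(x, class = c("rule_set", "matrix"))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules (genome length %d)\n", nrow(x), 6 * nrow(x)))
  invisible(x)
}

#' @rdname rule_set
#' @param m number of rules.
#' @param seed optional integer seed.
#' @export
random_rule_set <- function(m = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rule_set(cbind(matrix(runif(3 * m, 0, 2), m, 3),
                 matrix(runif(3 * m, 0, 2 * pi), m, 3)))
}

# genome vector <-> rule matrix (row-wise blocks of 6)
genome_to_rules <- function(g) rule_set(g)
rules_to_genome <- function(rules) as.vector(t(unclass(rule_set(rules))))

#' Automaton configuration
#'
#' @param iterations number of synchronous sweeps `K` (default 10).
#' @param f_th positive weight cap of the state update: a contributor at
#'   distance `r` from the target point weighs `min(1 / r, f_th)` and the
#'   updating cell itself weighs `f_th` (before normalization).
#' @param coarse_steps,golden_iters resolution of the rotation search in
#'   rule matching: number of coarse scan angles and golden-section polish
#'   iterations around the best candidate.
#' @return A list of class `mgca_config`.
#' @export
mgca_config <- function(iterations = 10, f_th = 2, coarse_steps = 64,
                        golden_iters = 16) {
  stopifnot(iterations >= 0, f_th > 0, coarse_steps >= 4, golden_iters >= 0)
  structure(list(iterations = as.integer(iterations), f_th = f_th,
                 coarse_steps = as.integer(coarse_steps),
                 golden_iters = as.integer(golden_iters)),
            class = "mgca_config")
}

#' Multi-scale gradient features of every cell
#'
#' For each cell, the spectral angles between its spectrum and every
#' spectrum in the centered 3x3, 5x5 and 7x7 windows (symmetric reflect
#' padding at the image frame) are combined with the [gradient_masks()] to
#' give three 2D gradient vectors.  Each is reported as modulus and angle
#' (`atan2(gy, gx)`, in `[0, 2 * pi)`; the angle of a zero-modulus
#' gradient is 0 by convention).
#'
#' @param img a [spectral_image()] (normalized intensities assumed).
#' @return An `H x W x 6` array: moduli `|G3| |G5| |G7|` then angles
#'   `phi3 phi5 phi7`.
#' @export
gradient_features <- function(img) {
  mk <- gradient_masks()
  .gradient_features_cpp(as_cube(spectral_image(img)), mk$mx3, mk$mx5, mk$mx7)
}

#' Match a gradient feature against a rule set
#'
#' Reconstructs each rule's three condition gradient vectors (size-3
#' vector at angle 0), then finds the rotation -- and optionally a
#' reflection about the x-axis -- that minimizes the sum of the (unsquared)
#' Euclidean norms of the three vector differences to the cell's gradient
#' vectors.  The rotation search evaluates the closed-form optimum of the
#' squared objective, the three per-pair alignment angles and a coarse
#' angular scan, then polishes the best candidate by golden-section
#' search.  The rule with the smallest aligned distance wins; exact ties
#' go to the smallest rule index.
#'
#' @param feature either a length-6 vector `(|G3|, |G5|, |G7|, phi3, phi5,
#'   phi7)` as produced by [gradient_features()], or a list with those
#'   fields.
#' @param rules a [rule_set()].
#' @param config an [mgca_config()] (only the rotation-search fields are
#'   used).
#' @return A list: `rule` (index), `phi` (optimal rotation, `[0, 2 * pi)`),
#'   `reflected` (logical), `distance`.
#' @export
match_rule <- function(feature, rules, config = mgca_config()) {
  f <- as.numeric(unlist(feature, use.names = FALSE))
  if (length(f) != 6) stop("`feature` must have 6 components")
  # convert modulus/angle form to vector components
  gx <- f[1:3] * cos(f[4:6]); gy <- f[1:3] * sin(f[4:6])
  res <- .match_rule_cpp(as.numeric(rbind(gx, gy)), unclass(rule_set(rules)),
                         config$coarse_steps, config$golden_iters)
  list(rule = as.integer(res[1]), phi = res[2],
       reflected = res[3] > 0, distance = res[4])
}

#' Update the state of one cell
#'
#' The new spectrum of a cell is a convex combination of its own spectrum
#' and those of the lattice pixels within Euclidean distance 1 of the
#' point one pixel away from the cell along direction `phi + theta`
#' (x = column rightward, y = row downward).  A contributor at distance
#' `r` from that point weighs `min(1 / r, f_th)`, the cell itself weighs
#' `f_th`, and all weights are normalized by their total.  Out-of-image
#' contributors are dropped; if none remain the state is unchanged.
#'
#' @param img a [spectral_image()].
#' @param row,col cell position (1-based).
#' @param phi matched rule rotation (radians).
#' @param theta action angle of the matched rule (radians).
#' @param config an [mgca_config()] (uses `f_th`).
#' @return The updated spectrum (length-`B` numeric vector).
#' @export
update_cell <- function(img, row, col, phi, theta, config = mgca_config()) {
  img <- spectral_image(img)
  d <- dim(img)
  stopifnot(row >= 1, row <= d[1], col >= 1, col <= d[2])
  .update_cell_cpp(as_cube(img), as.integer(row), as.integer(col),
                   phi + theta, config$f_th)
}

#' Run the multi-gradient cellular automaton
#'
#' Performs `config$iterations` synchronous sweeps: in each sweep every
#' cell extracts its three-scale gradient feature, matches it against the
#' rule table under rotation and reflection, and moves its spectrum toward
#' the directed neighborhood average prescribed by the matched rule's
#' action angle.  All new states are computed from the current image
#' before any is committed, so the result is order-independent and fully
#' deterministic.  States remain in `[0, 1]` (convex combinations only)
#' and a spectrally uniform image is a fixed point.
#'
#' @param img a [spectral_image()], normalized to `[0, 1]`.
#' @param rules a [rule_set()].
#' @param config an [mgca_config()].
#' @return The homogenized `spectral_image` (same dimensions).
#' @examples
#' img <- normalize_image(array(runif(10 * 10 * 3), c(10, 10, 3)))
#' out <- run_mgca(img, random_rule_set(5, seed = 1), mgca_config(iterations = 2))
#' @export
run_mgca <- function(img, rules, config = mgca_config()) {
  img <- spectral_image(img)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("`img` must be normalized to [0, 1]; see normalize_image()")
  if (config$iterations == 0) return(img)
  mk <- gradient_masks()
  out <- .run_mgca_cpp(as_cube(img), unclass(rule_set(rules)),
                       mk$mx3, mk$mx5, mk$mx7,
                       config$iterations, config$f_th,
                       config$coarse_steps, config$golden_iters)
  spectral_image(out)
}
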