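# Parametric generator of labeled training scenes, the parameter
# estimator, and the multiband test fixtures (base spectra corrupted by
# noise or spectral mixtures).

#' Scene specification
#'
#' The four knobs controlling the spectral and spatial character of a
#' synthetic labeled scene, plus its dimensions:
#' * `N` -- number of regions (= classes; one class per region),
#' * `Dmax` -- border ruggedness in `[0, 1]` (0 gives straight Voronoi
#'   borders, larger values give more tortuous ones),
#' * `rmax` -- target mean intra-class 8-neighbor spectral angle (the
#'   realized value is calibrated to within 10 percent),
#' * `smin`, `smax` -- admissible range of the spectral angle between the
#'   base spectra of adjacent classes.
#'
#' `rmax < smin` is recommended (regions should be separable); a spec
#' violating it is accepted with a warning.
#'
#' @param N number of regions/classes (>= 1).
#' @param Dmax border ruggedness in `[0, 1]`.
#' @param rmax target intra-class neighbor angle in `[0, 1)`.
#' @param smin,smax inter-class base-spectrum angle range,
#'   `0 <= smin <= smax <= 1`.
#' @param height,width,bands scene dimensions (3 bands by default:
#'   training scenes are cheap RGB-like images).
#' @param seed optional integer seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(N = 5, Dmax = 0.2, rmax = 0.05, smin = 0.15,
                       smax = 0.5, height = 32, width = 32, bands = 3,
                       seed = NULL) {
  stopifnot(N >= 1, Dmax >= 0, Dmax <= 1, rmax >= 0, rmax < 1,
            smin >= 0, smin <= smax, smax <= 1,
            height >= 4, width >= 4, bands >= 1)
  if (rmax >= smin && smin > 0)
    warning("rmax >= smin: intra-class variability reaches the inter-class ",
            "separation; regions may not be separable")
  structure(list(N = as.integer(N), Dmax = Dmax, rmax = rmax, smin = smin,
                 smax = smax, height = as.integer(height),
                 width = as.integer(width), bands = as.integer(bands),
                 seed = seed),
            class = "scene_spec")
}

# separable Gaussian blur with edge-replicated padding
blur2d <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(x, n) x[c(rep(1, n), seq_len(length(x)), rep(length(x), n))]
  conv1 <- function(x) as.numeric(stats::filter(pad(x, h), k, sides = 2))[(h + 1):(h + length(x))]
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

# region geometry: nearest-seed partition of a distance field perturbed by
# smoothed noise with amplitude proportional to Dmax
region_partition <- function(N, H, W, Dmax, max_tries = 50) {
  for (try in seq_len(max_tries)) {
    cx <- runif(N, 1, W); cy <- runif(N, 1, H)
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    amp <- Dmax * min(H, W) / 3
    D <- array(0, c(H, W, N))
    for (n in seq_len(N)) {
      d <- sqrt((rr - cy[n])^2 + (cc - cx[n])^2)
      if (amp > 0) {
        z <- blur2d(matrix(rnorm(H * W), H, W), sigma = 3)
        z <- z / max(sd(z), 1e-12)
        d <- d + amp * z
      }
      D[, , n] <- d
    }
    lab <- apply(D, c(1, 2), which.min)
    if (length(unique(as.vector(lab))) == N) return(matrix(as.integer(lab), H, W))
  }
  stop("could not realize ", N, " non-empty regions; lower Dmax or N")
}

# adjacency graph of a label map (classes sharing an 8-neighbor border)
class_adjacency <- function(lab) {
  gt <- derive_ground_truth(lab)
  M <- gt$n_classes
  adj <- matrix(FALSE, M, M)
  for (i in seq_len(M)) for (j in seq_len(M))
    adj[i, j] <- i != j && !is.null(gt$pair_border[[i, j]])
  adj | t(adj)
}

# base spectra by sequential rejection: each class's spectrum must form a
# spectral angle within [smin, smax] with every previously placed adjacent
# class
draw_base_spectra <- function(adj, bands, smin, smax, max_attempts = 1e4) {
  N <- nrow(adj)
  S <- matrix(NA_real_, N, bands)
  attempts <- 0
  k <- 1
  while (k <= N) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("could not draw base spectra with adjacent-class angles in [",
           smin, ", ", smax, "] after ", max_attempts, " attempts")
    cand <- runif(bands, 0.05, 0.95)
    prev <- which(adj[k, seq_len(k - 1)])
    ok <- all(vapply(prev, function(j) {
      a <- spectral_angle(cand, S[j, ])
      a >= smin && a <= smax
    }, TRUE))
    if (ok) { S[k, ] <- cand; k <- k + 1 }
    else if (attempts %% 400 == 0) { k <- 1 }  # periodic global restart
  }
  S
}

apply_scene_noise <- function(base_img, sigma_px) {
  # sigma_px: per-pixel noise scale (H x W), recycled across bands
  d <- dim(base_img)
  e1 <- pmin(pmax(rnorm(prod(d)), -2.5), 2.5)
  e2 <- pmin(pmax(rnorm(prod(d)), -2.5), 2.5)
  s <- as.vector(sigma_px)
  # multiplicative 70 / additive 30 split; only the realized intra-class
  # neighbor angle matters downstream
  out <- base_img * (1 + 0.7 * s * e1) + 0.3 * s * e2
  array(pmin(pmax(out, 0), 1), d)
}

#' Generate a synthetic labeled scene
#'
#' Builds a scene in four steps: (i) `N` seed points uniform in the grid;
#' (ii) regions as the nearest-seed partition of per-seed distance fields
#' perturbed by smoothed Gaussian noise with amplitude proportional to
#' `Dmax`; (iii) per-class base spectra drawn by rejection sampling so
#' every pair of adjacent classes has a base-spectrum angle in
#' `[smin, smax]`; (iv) per-pixel multiplicative-plus-additive truncated
#' Gaussian noise whose scale is calibrated by a closed loop so the
#' realized mean intra-class 8-neighbor spectral angle lands within 10
#' percent of `rmax` (measured on the final clipped, normalized image).
#'
#' @param spec a [scene_spec()].
#' @return A list of class `scene_bundle`: `image` (a [spectral_image()]),
#'   `labels` (a [label_map()]), `borders` (a [border_map()]), `spec`, and
#'   `realized` (realized parameter report: pooled and per-class intra
#'   angles, adjacent-pair base-spectrum angles, noise scale).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  # if the adjacency graph of a drawn geometry makes the base-spectrum
  # constraints unsatisfiable, redraw the geometry a few times first
  S <- NULL
  for (geom_try in 1:5) {
    lab <- label_map(region_partition(spec$N, spec$height, spec$width, spec$Dmax))
    adj <- if (spec$N > 1) class_adjacency(lab) else matrix(FALSE, 1, 1)
    S <- tryCatch(draw_base_spectra(adj, spec$bands, spec$smin, spec$smax),
                  error = function(e) NULL)
    if (!is.null(S)) break
  }
  if (is.null(S))
    stop("could not draw base spectra with adjacent-class angles in [",
         spec$smin, ", ", spec$smax, "] for any of 5 region geometries")
  base_img <- array(0, c(spec$height, spec$width, spec$bands))
  for (b in seq_len(spec$bands))
    base_img[, , b] <- matrix(S[lab, b], spec$height, spec$width)

  # clip-only: base spectra live in [0.05, 0.95] and the noise model clips,
  # so values are already in [0, 1].  A min-max rescale would subtract a
  # positive global minimum and distort the inter-class spectral angles the
  # base spectra were drawn to satisfy.
  finalize <- function(raw) spectral_image(array(pmin(pmax(raw, 0), 1), dim(raw)))
  gt0 <- derive_ground_truth(lab)
  class_realized <- function(img) {
    fld <- neighbor_angle_field(img)
    vapply(gt0$interior, function(i) if (length(i)) mean(fld[i]) else NA_real_, 0)
  }
  realized_rmax <- function(img) {
    r <- class_realized(img)
    if (all(is.na(r))) 0 else mean(neighbor_angle_field(img)[gt0$borders == 1L])
  }

  sigma <- rep(0, spec$N)
  img <- finalize(base_img)
  if (spec$rmax > 0) {
    # per-class noise scales: the angular response to a given noise level
    # depends on each class's base-spectrum magnitude and shape, so each
    # class is calibrated separately against the same rmax target
    sigma <- rep(spec$rmax, spec$N)
    noise_seed <- sample.int(.Machine$integer.max, 1)
    r <- NULL
    for (it in 1:15) {
      set.seed(noise_seed)  # same noise draw, rescaled, keeps the loop smooth
      img <- finalize(apply_scene_noise(base_img, matrix(sigma[lab], spec$height)))
      r <- class_realized(img)
      ok <- is.na(r) | abs(r - spec$rmax) / spec$rmax < 0.05
      if (all(ok)) break
      adj <- ifelse(is.na(r), 1, spec$rmax / pmax(r, 1e-9))
      sigma <- pmin(sigma * adj, 5)
    }
    if (any(!is.na(r) & abs(r - spec$rmax) / spec$rmax > 0.10))
      warning(sprintf("realized intra-class angles [%s] miss target %.4f by > 10%%",
                      paste(round(r, 4), collapse = ", "), spec$rmax))
  }

  pair_ang <- NULL
  if (spec$N > 1) {
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(idx))
      pair_ang <- data.frame(k = idx[, 1], kp = idx[, 2],
                             angle = apply(idx, 1, function(ij)
                               spectral_angle(S[ij[1], ], S[ij[2], ])))
  }
  structure(list(image = img, labels = lab, borders = border_map(lab),
                 spec = spec,
                 realized = list(rmax = realized_rmax(img),
                                 rmax_by_class = {
                                   fld <- neighbor_angle_field(img)
                                   gt <- derive_ground_truth(lab)
                                   vapply(gt$interior, function(i)
                                     if (length(i)) mean(fld[i]) else 0, 0)
                                 },
                                 adjacent_angles = pair_ang,
                                 noise_scale = sigma,
                                 base_spectra = S)),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<scene_bundle> %d x %d x %d, %d classes, realized rmax %.4f\n",
              d[1], d[2], d[3], attr(x$labels, "n_classes"), x$realized$rmax))
  invisible(x)
}

#' Estimate scene parameters from a labeled image
#'
#' The inverse of [generate_scene()]: given any labeled image, estimates
#' the spectral knobs a scene generator would need to emulate it.
#' `rmax_i` is the mean 8-neighbor spectral angle over the interior pixels
#' of class `i`; `s_i` the mean spectral angle over random pixel pairs
#' between class `i` and the other classes; `rmax = max_i rmax_i`;
#' `smin` / `smax` the range of the `s_i`.  `Dmax` is estimated from
#' border tortuosity: the ratio of the border-pixel count to that of a
#' label map smoothed with a 5x5 modal filter, rescaled so 1 maps to 0
#' (straight borders) and >= 2 maps to 1.
#'
#' @param img a [spectral_image()].
#' @param labels a [label_map()] of the same height and width.
#' @param pairs_per_class random pixel pairs per class for the `s_i`
#'   estimates (default 1000).
#' @param seed optional integer seed for the pair sampling.
#' @return A list: `N`, `Dmax`, `rmax`, `smin`, `smax`, and `by_class`
#'   (data frame with per-class `rmax_i` and `s_i`).
#' @export
estimate_params <- function(img, labels, pairs_per_class = 1000, seed = NULL) {
  img <- spectral_image(img); lab <- label_map(labels)
  if (!identical(dim(img)[1:2], dim(lab)[1:2]))
    stop("image and label dimensions differ")
  if (!is.null(seed)) set.seed(seed)
  gt <- derive_ground_truth(lab)
  M <- gt$n_classes
  fld <- neighbor_angle_field(img)
  rmax_i <- vapply(seq_len(M), function(k) {
    idx <- gt$interior[[k]]
    if (!length(idx)) { warning("class ", k, " has no interior pixels"); return(NA_real_) }
    mean(fld[idx])
  }, 0)
  px <- pixel_matrix(img)
  s_i <- vapply(seq_len(M), function(k) {
    own <- gt$region[[k]]
    oth <- unlist(gt$region[-k], use.names = FALSE)
    if (!length(oth)) return(NA_real_)
    a <- own[sample.int(length(own), pairs_per_class, replace = TRUE)]
    b <- oth[sample.int(length(oth), pairs_per_class, replace = TRUE)]
    mean(row_spectral_angle(px[a, , drop = FALSE], px[b, , drop = FALSE]))
  }, 0)
  n_border <- sum(gt$borders == 0L)
  smooth_lab <- modal_filter(lab, 2)
  n_border_s <- sum(border_map(label_map(smooth_lab)) == 0L)
  tort <- if (n_border_s > 0) n_border / n_border_s else 1
  Dmax <- min(1, max(0, tort - 1))
  list(N = M, Dmax = Dmax, rmax = max(rmax_i, na.rm = TRUE),
       smin = min(s_i, na.rm = TRUE), smax = max(s_i, na.rm = TRUE),
       by_class = data.frame(class = seq_len(M), rmax_i = rmax_i, s_i = s_i))
}

# modal (majority) filter on a label matrix, window half-width h
modal_filter <- function(lab, h) {
  H <- nrow(lab); W <- ncol(lab)
  M <- max(lab)
  counts <- array(0L, c(H, W, M))
  for (dr in -h:h) for (dc in -h:h) {
    r1 <- pmin(pmax(seq_len(H) + dr, 1), H)
    c1 <- pmin(pmax(seq_len(W) + dc, 1), W)
    shifted <- lab[r1, c1, drop = FALSE]
    for (m in seq_len(M)) counts[, , m] <- counts[, , m] + (shifted == m)
  }
  matrix(as.integer(apply(counts, c(1, 2), which.max)), H, W)
}

# deterministic built-in endmember-like base spectra: smooth mixtures of
# Gaussian bumps over the band axis, moderately separated in spectral angle
builtin_base_spectra <- function(bands = 64, n = 5) {
  x <- seq(0, 1, length.out = bands)
  bump <- function(mu, s, a) a * exp(-(x - mu)^2 / (2 * s^2))
  specs <- list(
    bump(0.20, 0.10, 0.85) + bump(0.70, 0.25, 0.30) + 0.05,
    bump(0.50, 0.12, 0.80) + bump(0.10, 0.08, 0.25) + 0.08,
    bump(0.80, 0.10, 0.90) + bump(0.35, 0.10, 0.35) + 0.05,
    0.15 + 0.65 * x,
    0.75 - 0.55 * x + bump(0.55, 0.07, 0.25)
  )
  S <- do.call(rbind, specs[seq_len(n)])
  pmin(pmax(S, 0), 1)
}

#' Multiband synthetic test fixture
#'
#' Builds an `height x width` scene with `n_classes` regions whose pixels
#' start from per-class base spectra (by default a built-in set of five
#' smooth 64-band endmember-like spectra) and are then corrupted either by
#' i.i.d. additive Gaussian noise (`mode = "noise"`, `level` = noise
#' standard deviation on the `[0, 1]` intensity scale) or by spectral
#' mixing (`mode = "mixture"`: each pixel becomes a convex combination of
#' its region's base spectrum and the base spectra of adjacent regions,
#' with total foreign abundance drawn uniformly in `[0, level]`).
#'
#' @param mode `"noise"` or `"mixture"`.
#' @param level noise standard deviation, or maximum total foreign
#'   abundance in `[0, 1]` for mixtures.  The defaults (0.45 and 0.85)
#'   are calibrated so that a pixel-wise classifier on the raw cube drops
#'   well below 90 percent overall accuracy, leaving visible headroom for
#'   the segmentation stage.
#' @param base_spectra optional `n_classes x bands` matrix of base
#'   spectra.
#' @param bands,height,width,n_classes fixture dimensions (defaults echo a
#'   6400-pixel five-class 64-band scene).
#' @param Dmax border ruggedness of the region geometry.
#' @param seed optional integer seed.
#' @return A `scene_bundle` (see [generate_scene()]).
#' @export
make_multiband_fixture <- function(mode = c("noise", "mixture"),
                                   level = NULL, base_spectra = NULL,
                                   bands = 64, height = 80, width = 80,
                                   n_classes = 5, Dmax = 0.2, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(level)) level <- switch(mode, noise = 0.45, mixture = 0.85)
  if (mode == "mixture" && (level < 0 || level > 1))
    stop("mixture `level` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  S <- if (is.null(base_spectra)) builtin_base_spectra(bands, n_classes) else {
    stopifnot(nrow(base_spectra) == n_classes, ncol(base_spectra) == bands)
    base_spectra
  }
  lab <- label_map(region_partition(n_classes, height, width, Dmax))
  img <- array(0, c(height, width, bands))
  for (b in seq_len(bands)) img[, , b] <- matrix(S[lab, b], height, width)
  if (mode == "noise") {
    if (level > 0) img <- img + array(rnorm(length(img), sd = level), dim(img))
    img <- pmin(pmax(img, 0), 1)
  } else if (level > 0) {
    adj <- class_adjacency(lab)
    n_px <- height * width
    a_tot <- runif(n_px, 0, level)
    px <- matrix(img, n_px, bands)
    for (k in seq_len(n_classes)) {
      others <- which(adj[k, ])
      if (!length(others)) others <- setdiff(seq_len(n_classes), k)
      idx <- which(as.vector(lab) == k)
      w <- matrix(runif(length(idx) * length(others)), ncol = length(others))
      w <- w / rowSums(w) * a_tot[idx]
      px[idx, ] <- (1 - a_tot[idx]) * px[idx, , drop = FALSE] +
        w %*% S[others, , drop = FALSE]
    }
    img <- array(px, c(height, width, bands))
  }
  img <- spectral_image(array(img, c(height, width, bands)))
  structure(list(image = img, labels = lab, borders = border_map(lab),
                 spec = list(mode = mode, level = level, bands = bands,
                             height = height, width = width,
                             n_classes = n_classes, Dmax = Dmax, seed = seed),
                 realized = list(rmax = {
                   gt_int <- border_map(lab) == 1L
                   fld <- neighbor_angle_field(img)
                   if (any(gt_int)) mean(fld[gt_int]) else 0
                 }, base_spectra = S)),
            class = "scene_bundle")
}
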