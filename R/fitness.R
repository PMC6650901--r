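# Segmentation cost: local/non-local intra-class homogeneity, per-class
# homogeneity, cross-border inter-class separability and their
# max-combination.  All spectral comparisons use the normalized spectral
# angle, so every component lies in [0, 1] and is invariant to the number
# of bands and to global positive rescaling of the image.

#' Ground-truth structure of a label map
#'
#' Derives, for each class `k`, the interior pixel set `I_k`, the border
#' set `F_k`, the region `B_k = I_k + F_k` and the pairwise border sets
#' `F_kk'` (border pixels of class `k` with at least one 8-neighbor of
#' class `k'`).  A pixel is a border pixel iff some in-image 8-neighbor
#' carries a different label.
#'
#' @param labels a [label_map()].
#' @return A list of class `ground_truth`: `labels`, `borders` (a
#'   [border_map()]), `interior` / `border` / `region` (lists of linear
#'   pixel indices per class) and `pair_border` (`M x M` list matrix).
#' @export
derive_ground_truth <- function(labels) {
  lab <- label_map(labels)
  M <- attr(lab, "n_classes")
  H <- nrow(lab); W <- ncol(lab)
  borders <- border_map(lab)
  idx_all <- seq_len(H * W)
  region <- split(idx_all, as.vector(lab))
  interior <- lapply(region, function(i) i[borders[i] == 1L])
  border <- lapply(region, function(i) i[borders[i] == 0L])
  # pairwise border sets via the 8 neighbor shifts
  pair <- matrix(vector("list", M * M), M, M)
  rr <- row(lab); cc <- col(lab)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r0 <- rr + dr; c0 <- cc + dc
    ok <- r0 >= 1 & r0 <= H & c0 >= 1 & c0 <= W
    p <- idx_all[ok]
    q <- (c0[ok] - 1L) * H + r0[ok]
    diff <- lab[p] != lab[q]
    p <- p[diff]; q <- q[diff]
    if (!length(p)) next
    key <- paste(lab[p], lab[q])
    for (kk in split(seq_along(p), key)) {
      k1 <- lab[p[kk[1]]]; k2 <- lab[q[kk[1]]]
      pair[[k1, k2]] <- c(pair[[k1, k2]], p[kk])
    }
  }
  for (i in seq_len(M)) for (j in seq_len(M))
    if (!is.null(pair[[i, j]])) pair[[i, j]] <- sort(unique(pair[[i, j]]))
  structure(list(labels = lab, borders = borders, n_classes = M,
                 region = region, interior = interior, border = border,
                 pair_border = pair),
            class = "ground_truth")
}

as_ground_truth <- function(x) {
  if (inherits(x, "ground_truth")) x else derive_ground_truth(x)
}

#' Sampling configuration of the stochastic cost terms
#'
#' @param V pixel pairs sampled per class for the non-local intra-class
#'   term (default 100).
#' @param U pixel pairs sampled per ordered class pair for the
#'   inter-class term (default 100).
#' @param seed optional integer seed consumed when pairs are drawn.
#' @return A list of class `fitness_config`.
#' @export
fitness_config <- function(V = 100, U = 100, seed = NULL) {
  stopifnot(V >= 1, U >= 1)
  structure(list(V = as.integer(V), U = as.integer(U), seed = seed),
            class = "fitness_config")
}

check_dims <- function(img, gt) {
  if (!identical(dim(img)[1:2], dim(gt$labels)[1:2]))
    stop("image and ground truth dimensions differ")
}

#' Local intra-class error
#'
#' Mean, over all interior pixels of all classes, of the average spectral
#' angle between the pixel and its in-image 8-neighbors.  Zero iff every
#' region is locally spectrally constant.
#'
#' @param img a [spectral_image()].
#' @param gt a [derive_ground_truth()] result (or a label map).
#' @return A number in `[0, 1]`.
#' @export
local_intra_error <- function(img, gt) {
  img <- spectral_image(img); gt <- as_ground_truth(gt)
  check_dims(img, gt)
  interior <- unlist(gt$interior, use.names = FALSE)
  if (!length(interior)) {
    warning("no interior pixels in any class; local intra-class error is 0")
    return(0)
  }
  fld <- neighbor_angle_field(img)
  mean(fld[interior])
}

#' Per-class local homogeneity
#'
#' The class-restricted version of [local_intra_error()]: the mean
#' 8-neighbor spectral angle over the interior pixels of class `k`.
#' Returns 0 for a class without interior pixels.
#'
#' @inheritParams local_intra_error
#' @param k class index (1-based canonical label).
#' @return A number in `[0, 1]`.
#' @export
class_homogeneity <- function(img, gt, k) {
  img <- spectral_image(img); gt <- as_ground_truth(gt)
  check_dims(img, gt)
  idx <- gt$interior[[k]]
  if (!length(idx)) return(0)
  mean(neighbor_angle_field(img)[idx])
}

all_class_homogeneity <- function(img, gt) {
  fld <- neighbor_angle_field(img)
  vapply(gt$interior, function(idx) if (length(idx)) mean(fld[idx]) else 0, 0)
}

pixel_matrix <- function(img) {
  d <- dim(img)
  matrix(img, d[1] * d[2], d[3])
}

# draw the non-local intra-class pair list: for each class (ascending) with
# at least one interior pixel, V index pairs uniform with replacement
draw_intra_pairs <- function(gt, cfg) {
  lapply(gt$interior, function(idx) {
    if (length(idx) < 1) return(NULL)
    cbind(idx[sample.int(length(idx), cfg$V, replace = TRUE)],
          idx[sample.int(length(idx), cfg$V, replace = TRUE)])
  })
}

# draw the inter-class pair list: for each ordered class pair (k, k') with
# pixels on both sides of the shared border, U pairs (x in F_kk', y in F_k'k)
draw_inter_pairs <- function(gt, cfg) {
  M <- gt$n_classes
  out <- matrix(vector("list", M * M), M, M)
  for (k in seq_len(M)) for (kp in seq_len(M)) {
    if (kp == k) next
    a <- gt$pair_border[[k, kp]]; b <- gt$pair_border[[kp, k]]
    if (is.null(a) || is.null(b) || !length(a) || !length(b)) next
    out[[k, kp]] <- cbind(a[sample.int(length(a), cfg$U, replace = TRUE)],
                          b[sample.int(length(b), cfg$U, replace = TRUE)])
  }
  out
}

#' Non-local intra-class error
#'
#' For each class, `V` interior pixel pairs are sampled uniformly with
#' replacement and their mean spectral angle computed; the class means are
#' combined as an interior-size-weighted average.  Classes without
#' interior pixels are skipped and excluded from the weighting.
#'
#' @inheritParams local_intra_error
#' @param config a [fitness_config()].
#' @param pairs optional precomputed pair list (one `V x 2` index matrix
#'   per class), overriding the internal sampling; used to share one
#'   random stream between implementations.
#' @return A number in `[0, 1]`.
#' @export
nonlocal_intra_error <- function(img, gt, config = fitness_config(), pairs = NULL) {
  img <- spectral_image(img); gt <- as_ground_truth(gt)
  check_dims(img, gt)
  if (is.null(pairs)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    pairs <- draw_intra_pairs(gt, config)
  }
  px <- pixel_matrix(img)
  w <- 0; acc <- 0
  for (k in seq_along(pairs)) {
    pk <- pairs[[k]]
    if (is.null(pk)) next
    nk <- length(gt$interior[[k]])
    acc <- acc + nk * mean(row_spectral_angle(px[pk[, 1], , drop = FALSE],
                                              px[pk[, 2], , drop = FALSE]))
    w <- w + nk
  }
  if (w == 0) {
    warning("no interior pixels in any class; non-local intra-class error is 0")
    return(0)
  }
  acc / w
}

#' Inter-class error
#'
#' For each ordered class pair `(k, k')` sharing a border, `U` pixel pairs
#' are sampled across the border and an indicator is set when their
#' spectral angle does not exceed `H_k + H_k'`, the sum of the two class
#' homogeneities -- i.e. when the classes are no better separated across
#' the border than they are internally homogeneous.  Indicator means are
#' combined by region-size-weighted averages, first over `k'` within `k`,
#' then over `k`.  Class pairs without a shared border are excluded and
#' the weights renormalize over the remaining ones; with no sharing pairs
#' at all the error is 0 (with a warning).
#'
#' @inheritParams nonlocal_intra_error
#' @param Hk optional precomputed per-class homogeneity vector (computed
#'   from `img` if missing).
#' @return A number in `[0, 1]`.
#' @export
inter_error <- function(img, gt, Hk = NULL, config = fitness_config(), pairs = NULL) {
  img <- spectral_image(img); gt <- as_ground_truth(gt)
  check_dims(img, gt)
  if (is.null(Hk)) Hk <- all_class_homogeneity(img, gt)
  if (is.null(pairs)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    pairs <- draw_inter_pairs(gt, config)
  }
  px <- pixel_matrix(img)
  M <- gt$n_classes
  sizes <- vapply(gt$region, length, 0L)
  outer_acc <- 0; outer_w <- 0; any_pair <- FALSE
  for (k in seq_len(M)) {
    inner_acc <- 0; inner_w <- 0
    for (kp in seq_len(M)) {
      pk <- pairs[[k, kp]]
      if (is.null(pk)) next
      any_pair <- TRUE
      ang <- row_spectral_angle(px[pk[, 1], , drop = FALSE],
                                px[pk[, 2], , drop = FALSE])
      inner_acc <- inner_acc + sizes[kp] * mean(ang <= Hk[k] + Hk[kp])
      inner_w <- inner_w + sizes[kp]
    }
    if (inner_w > 0) {
      outer_acc <- outer_acc + sizes[k] * inner_acc / inner_w
      outer_w <- outer_w + sizes[k]
    }
  }
  if (!any_pair) {
    warning("no class pair shares a border; inter-class error is 0")
    return(0)
  }
  outer_acc / outer_w
}

#' Total segmentation cost
#'
#' The cost minimized when evolving transition rules:
#' `e = max(e_intra, e_inter)` with
#' `e_intra = max(e_local_intra, e_nonlocal_intra)`.  It is 0 only when
#' every region is internally constant and every sampled cross-border pair
#' is better separated than the within-class homogeneities, and it is 1
#' for a spectrally constant image with two or more classes.
#'
#' @inheritParams nonlocal_intra_error
#' @return A list of class `fitness_report` with components
#'   `e_local_intra`, `e_nonlocal_intra`, `e_intra`, `e_inter`, `e` and
#'   the per-class homogeneity vector `Hk`.
#' @export
total_cost <- function(img, gt, config = fitness_config()) {
  img <- spectral_image(img); gt <- as_ground_truth(gt)
  check_dims(img, gt)
  if (!is.null(config$seed)) set.seed(config$seed)
  fld <- neighbor_angle_field(img)
  interior <- unlist(gt$interior, use.names = FALSE)
  e_local <- if (length(interior)) mean(fld[interior]) else 0
  Hk <- vapply(gt$interior, function(idx) if (length(idx)) mean(fld[idx]) else 0, 0)
  e_nonlocal <- nonlocal_intra_error(img, gt, config, pairs = draw_intra_pairs(gt, config))
  single <- gt$n_classes < 2 ||
    !any(!vapply(gt$pair_border, is.null, TRUE) & diag(gt$n_classes) == 0)
  e_inter <- if (single) 0 else
    inter_error(img, gt, Hk = Hk, config = config, pairs = draw_inter_pairs(gt, config))
  e_intra <- max(e_local, e_nonlocal)
  structure(list(e_local_intra = e_local, e_nonlocal_intra = e_nonlocal,
                 e_intra = e_intra, e_inter = e_inter,
                 e = max(e_intra, e_inter), Hk = Hk),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf(paste0("<fitness_report> e = %.4f (intra %.4f [local %.4f, ",
                     "non-local %.4f], inter %.4f)\n"),
              x$e, x$e_intra, x$e_local_intra, x$e_nonlocal_intra, x$e_inter))
  invisible(x)
}
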