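# Independent brute-force oracles used to validate the fast implementation,
# plus small programmatic fixtures.  Everything here is written naively and
# directly from the defining formulas, on purpose.

oracle_angle <- function(a, b) {
  # same stable half-angle form the package uses (the arccos form is
  # ill-conditioned near 0, so 1e-12 equivalence is only meaningful on a
  # well-conditioned formulation), written out independently
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(0)
  dm <- sqrt(sum((a / na - b / nb)^2))
  dp <- sqrt(sum((a / na + b / nb)^2))
  (4 / pi) * atan2(dm, dp)
}

# gradient masks written out from their printed fractions (independent of
# the package's constructor)
oracle_masks <- function() {
  mx3 <- (1 / 2) * matrix(c(-1/2, 0, 1/2,
                            -1,   0, 1,
                            -1/2, 0, 1/2), 3, 3, byrow = TRUE)
  mx5 <- (10 / 33) * matrix(c(-1/8, -1/5, 0, 1/5, 1/8,
                              -1/5, -1/2, 0, 1/2, 1/5,
                              -1/4, -1,   0, 1,   1/4,
                              -1/5, -1/2, 0, 1/2, 1/5,
                              -1/8, -1/5, 0, 1/5, 1/8), 5, 5, byrow = TRUE)
  mx7 <- (361 / 1527) *
    matrix(c(-1/18, -1/13, -1/10, 0, 1/10, 1/13, 1/18,
             -1/13, -1/8,  -1/5,  0, 1/5,  1/8,  1/13,
             -1/10, -1/5,  -1/2,  0, 1/2,  1/5,  1/10,
             -1/9,  -1/4,  -1,    0, 1,    1/4,  1/9,
             -1/10, -1/5,  -1/2,  0, 1/2,  1/5,  1/10,
             -1/13, -1/8,  -1/5,  0, 1/5,  1/8,  1/13,
             -1/18, -1/13, -1/10, 0, 1/10, 1/13, 1/18), 7, 7, byrow = TRUE)
  list(mx3 = mx3, mx5 = mx5, mx7 = mx7)
}

reflect_index <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# naive double-loop gradient feature of one cell
oracle_gradients <- function(img, r, c) {
  mk <- oracle_masks()
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- numeric(6)
  for (ns in 1:3) {
    h <- ns  # half-width 1, 2, 3
    mx <- mk[[ns]]; my <- t(mx)
    gx <- 0; gy <- 0
    for (dy in -h:h) for (dx in -h:h) {
      rr <- reflect_index(r + dy, H); cc <- reflect_index(c + dx, W)
      a <- oracle_angle(img[r, c, ], img[rr, cc, ])
      gx <- gx + a * mx[dy + h + 1, dx + h + 1]
      gy <- gy + a * my[dy + h + 1, dx + h + 1]
    }
    out[2 * ns - 1] <- sqrt(gx^2 + gy^2)
    out[2 * ns] <- if (out[2 * ns - 1] < 1e-12) 0 else atan2(gy, gx) %% (2 * pi)
  }
  # (|G3|, |G5|, |G7|, phi3, phi5, phi7)
  c(out[c(1, 3, 5)], out[c(2, 4, 6)])
}

# rule condition vectors as 3 x 2 matrices (size-3 vector at angle 0)
rule_vectors <- function(rule) {
  rbind(c(rule[1], 0),
        rule[2] * c(cos(rule[4]), sin(rule[4])),
        rule[3] * c(cos(rule[5]), sin(rule[5])))
}

feature_vectors <- function(feature) {
  # feature = (|G3|, |G5|, |G7|, phi3, phi5, phi7)
  cbind(feature[1:3] * cos(feature[4:6]), feature[1:3] * sin(feature[4:6]))
}

# exhaustive rotation x reflection scan of the unsquared alignment distance
oracle_match <- function(feature, rules, steps = 4096) {
  g <- feature_vectors(feature)
  grid <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  cg <- cos(grid); sg <- sin(grid)
  per_rule <- apply(unclass(rules), 1, function(rule) {
    u <- rule_vectors(rule)
    best <- Inf
    for (refl in c(1, -1)) {
      uu <- u; uu[, 2] <- refl * uu[, 2]
      cm <- rowSums(g^2) + rowSums(uu^2)
      dt <- rowSums(g * uu)
      cr <- uu[, 1] * g[, 2] - uu[, 2] * g[, 1]
      d <- sqrt(pmax(rep(cm, each = steps) - 2 * (outer(cg, dt) + outer(sg, cr)), 0))
      dim(d) <- c(steps, 3)
      best <- min(best, min(rowSums(d)))
    }
    best
  })
  list(rule = which.min(per_rule), distance = min(per_rule), per_rule = per_rule)
}

# Lipschitz bound on the error of a `steps`-point rotation grid for rule k
grid_tolerance <- function(rules, steps = 4096) {
  (pi / steps) * max(rowSums(abs(unclass(rules)[, 1:3, drop = FALSE])))
}

# naive fitness components ------------------------------------------------

oracle_neighbor_mean <- function(img, r, c) {
  H <- dim(img)[1]; W <- dim(img)[2]
  acc <- 0; n <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > H || cc < 1 || cc > W) next
    acc <- acc + oracle_angle(img[r, c, ], img[rr, cc, ])
    n <- n + 1
  }
  acc / n
}

oracle_local_intra <- function(img, gt) {
  acc <- 0; n <- 0
  for (k in seq_len(gt$n_classes)) for (p in gt$interior[[k]]) {
    rc <- arrayInd(p, dim(gt$labels))
    acc <- acc + oracle_neighbor_mean(img, rc[1], rc[2])
    n <- n + 1
  }
  if (n == 0) 0 else acc / n
}

oracle_homogeneity <- function(img, gt, k) {
  idx <- gt$interior[[k]]
  if (!length(idx)) return(0)
  mean(vapply(idx, function(p) {
    rc <- arrayInd(p, dim(gt$labels))
    oracle_neighbor_mean(img, rc[1], rc[2])
  }, 0))
}

pix <- function(img, p) {
  rc <- arrayInd(p, dim(img)[1:2])
  img[rc[1], rc[2], ]
}

oracle_nonlocal_intra <- function(img, gt, pairs) {
  acc <- 0; w <- 0
  for (k in seq_along(pairs)) {
    pk <- pairs[[k]]
    if (is.null(pk)) next
    m <- mean(vapply(seq_len(nrow(pk)), function(v)
      oracle_angle(pix(img, pk[v, 1]), pix(img, pk[v, 2])), 0))
    acc <- acc + length(gt$interior[[k]]) * m
    w <- w + length(gt$interior[[k]])
  }
  if (w == 0) 0 else acc / w
}

oracle_inter <- function(img, gt, Hk, pairs) {
  sizes <- vapply(gt$region, length, 0L)
  M <- gt$n_classes
  oa <- 0; ow <- 0
  for (k in seq_len(M)) {
    ia <- 0; iw <- 0
    for (kp in seq_len(M)) {
      pk <- pairs[[k, kp]]
      if (is.null(pk)) next
      f <- mean(vapply(seq_len(nrow(pk)), function(u)
        oracle_angle(pix(img, pk[u, 1]), pix(img, pk[u, 2])) <= Hk[k] + Hk[kp], TRUE))
      ia <- ia + sizes[kp] * f
      iw <- iw + sizes[kp]
    }
    if (iw > 0) { oa <- oa + sizes[k] * ia / iw; ow <- ow + sizes[k] }
  }
  if (ow == 0) 0 else oa / ow
}

# small fixtures -----------------------------------------------------------

random_image <- function(H, W, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  normalize_image(spectral_image(array(runif(H * W * B), c(H, W, B))))
}

# vertical two-class split with distinct constant spectra
halfplane_scene <- function(H = 12, W = 12, left = c(1, 0, 0), right = c(0, 1, 0)) {
  lab <- label_map(cbind(matrix(1L, H, W %/% 2), matrix(2L, H, W - W %/% 2)))
  img <- array(0, c(H, W, length(left)))
  for (b in seq_along(left))
    img[, , b] <- cbind(matrix(left[b], H, W %/% 2), matrix(right[b], H, W - W %/% 2))
  list(image = spectral_image(img), labels = lab)
}

random_labels <- function(H, W, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # blocky random labels (3x3-upscaled coarse grid) so every class has
  # interior pixels with high probability; guaranteed M classes
  for (i in 1:50) {
    coarse <- matrix(sample.int(M, ceiling(H / 3) * ceiling(W / 3),
                                replace = TRUE),
                     ceiling(H / 3), ceiling(W / 3))
    lab <- coarse[rep(seq_len(nrow(coarse)), each = 3)[1:H],
                  rep(seq_len(ncol(coarse)), each = 3)[1:W]]
    if (length(unique(as.vector(lab))) == M) return(label_map(lab))
  }
  stop("fixture failure")
}
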