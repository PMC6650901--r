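#' Spectral image container
#'
#' A spectral image is an `H x W x B` numeric array of per-pixel spectra
#' (band intensities).  Any number of bands `B >= 1` is accepted: every
#' comparison in the package goes through the normalized spectral angle,
#' which is independent of spectral dimensionality.  A plain matrix is
#' promoted to a single-band cube.
#'
#' @param data numeric array `H x W x B` (or `H x W` matrix).
#' @return An object of class `spectral_image` (a 3D array).
#' @examples
#' img <- spectral_image(array(runif(4 * 5 * 3), c(4, 5, 3)))
#' dim(img)
#' @export
spectral_image <- function(data) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an H x W x B array")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("`data` must be finite numeric")
  storage.mode(data) <- "double"
  structure(data, class = c("spectral_image", "array"))
}

as_cube <- function(img) {
  # strip class for C++ calls; keeps dim attribute
  unclass(spectral_image(img))
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectral_image> %d x %d pixels, %d band%s, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], if (d[3] == 1) "" else "s", min(x), max(x)))
  invisible(x)
}

#' Normalized spectral angle between two spectra
#'
#' The spectral angle between spectra `a` and `b` is
#' `(2 / pi) * acos(<a, b> / (||a|| ||b||))`, scaled so it lies in
#' `[0, 1]`.  It is symmetric, invariant to positive rescaling of either
#' argument (hence insensitive to illumination changes) and independent of
#' the number of bands.  If either spectrum has (numerically) zero norm the
#' angle is defined as 0.
#'
#' @param a,b numeric vectors of equal length.
#' @details The angle is evaluated as `2 * atan2(||u - v||, ||u + v||)` on
#'   the unit-normalized spectra `u`, `v` rather than as the arccosine of
#'   their inner product: the two forms are mathematically identical but
#'   the arccosine is ill-conditioned near 0, where most within-region
#'   comparisons live.
#' @return A number in `[0, 1]`.
#' @examples
#' spectral_angle(c(1, 1), c(1, 0))  # 0.5
#' spectral_angle(c(1, 2, 3), 2 * c(1, 2, 3))  # 0: scale invariance
#' @export
spectral_angle <- function(a, b) {
  if (length(a) != length(b))
    stop("spectra must have the same length (got ", length(a), " and ", length(b), ")")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na < 1e-12 || nb < 1e-12) return(0)
  u <- a / na; v <- b / nb
  (2 / pi) * 2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2)))
}

# vectorized spectral angle between paired rows of two matrices
row_spectral_angle <- function(A, B) {
  na <- sqrt(rowSums(A * A)); nb <- sqrt(rowSums(B * B))
  zero <- na < 1e-12 | nb < 1e-12
  U <- A / pmax(na, 1e-300); V <- B / pmax(nb, 1e-300)
  ang <- (2 / pi) * 2 * atan2(sqrt(rowSums((U - V)^2)), sqrt(rowSums((U + V)^2)))
  ang[zero] <- 0
  ang
}

#' Rescale a spectral image into \[0, 1\]
#'
#' Affine rescaling by the global minimum and maximum of the cube (all
#' bands pooled).  A constant image maps to all zeros.  The operation is
#' idempotent.
#'
#' @param img a [spectral_image()] (or array coercible to one).
#' @return A `spectral_image` with values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  img <- spectral_image(img)
  lo <- min(img); hi <- max(img)
  if (hi - lo < 1e-300) {
    img[] <- 0
    return(img)
  }
  img[] <- (img - lo) / (hi - lo)
  img
}

#' 2D angular transform of a spectral image
#'
#' Maps each pixel to the normalized spectral angle between its spectrum
#' and a fully saturated reference spectrum (all bands at 1).  Useful as a
#' single-channel visualization of a hyperspectral cube that respects the
#' geometry the automaton operates in.
#'
#' @param img a [spectral_image()].
#' @return An `H x W` numeric matrix with values in `[0, 1]`.
#' @export
angular_transform <- function(img) {
  img <- spectral_image(img)
  d <- dim(img)
  px <- matrix(img, d[1] * d[2], d[3])
  ref <- matrix(1, d[1] * d[2], d[3])
  matrix(row_spectral_angle(px, ref), d[1], d[2])
}

#' Mean within-image 8-neighbor spectral angle
#'
#' Per-pixel mean normalized spectral angle to the in-image 8-neighbors
#' (pixels on the frame average over the neighbors that exist).  This is
#' the local homogeneity field underlying the intra-class cost terms and
#' the generator's noise calibration.
#'
#' @param img a [spectral_image()].
#' @return An `H x W` numeric matrix.
#' @export
neighbor_angle_field <- function(img) {
  .mean_neighbor_angle_cpp(as_cube(spectral_image(img)))
}

#' Label map container
#'
#' An `H x W` integer grid of class ids.  Arbitrary label values are
#' canonicalized to `1..M` in order of first appearance (column-major);
#' the original values are kept in the `"levels"` attribute.
#'
#' @param labels integer matrix (any values; `NA` not allowed).
#' @return An object of class `label_map`: integer matrix with values
#'   `1..M`, attributes `n_classes` and `levels`.
#' @export
label_map <- function(labels) {
  if (inherits(labels, "label_map")) return(labels)
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (anyNA(labels)) stop("`labels` must not contain NA")
  lev <- unique(as.vector(labels))
  canon <- match(as.vector(labels), lev)
  out <- matrix(as.integer(canon), nrow(labels), ncol(labels))
  structure(out, class = "label_map", n_classes = length(lev), levels = lev)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes\n", nrow(x), ncol(x),
              attr(x, "n_classes")))
  invisible(x)
}

n_classes <- function(labels) attr(label_map(labels), "n_classes")

#' Border map of a label map
#'
#' A pixel is a border pixel iff at least one of its in-image 8-neighbors
#' carries a different label; all other pixels are interior.
#'
#' @param labels a [label_map()] (or integer matrix).
#' @return An `H x W` integer matrix: 0 = border, 1 = interior.
#' @export
border_map <- function(labels) {
  lab <- label_map(labels)
  H <- nrow(lab); W <- ncol(lab)
  border <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(H, H + dr)
    c1 <- max(1, 1 + dc):min(W, W + dc)
    r0 <- r1 - dr; c0 <- c1 - dc
    border[r0, c0] <- border[r0, c0] | (lab[r0, c0] != lab[r1, c1])
  }
  matrix(as.integer(!border), H, W)
}
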