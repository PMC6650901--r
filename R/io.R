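# File I/O: ENVI header + flat binary for cubes, PNG / integer CSV for
# label maps, JSON for rule sets.

#' Write a spectral image as an ENVI header + flat binary pair
#'
#' Writes `<path>.hdr` (text header) and `<path>.raw` (little-endian
#' IEEE doubles).  Interleave can be band-sequential (`bsq`), by line
#' (`bil`) or by pixel (`bip`); the header records it and [read_envi()]
#' honors all three.
#'
#' @param img a [spectral_image()].
#' @param path output path without extension.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(img, path, interleave = c("bsq", "bil", "bip")) {
  img <- spectral_image(img)
  interleave <- match.arg(interleave)
  d <- dim(img)  # H (lines), W (samples), B (bands)
  hdr <- c("ENVI",
           "description = {mgca spectral image}",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0")
  writeLines(hdr, paste0(path, ".hdr"))
  # ENVI raster order is row-major within a band: sample fastest, then line
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vals <- as.vector(aperm(unclass(img), perm))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 8, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  get <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (!length(hit)) stop("ENVI header ", hdr_path, ": missing field `", key, "`")
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  list(samples = as.integer(get("samples")),
       lines = as.integer(get("lines")),
       bands = as.integer(get("bands")),
       dtype = as.integer(get("data type")),
       interleave = tolower(get("interleave")),
       byte_order = as.integer(get("byte order")))
}

#' Read an ENVI header + flat binary cube
#'
#' @param path path without extension, or the `.hdr` path; the binary part
#'   is looked up as `.raw`, `.img`, `.dat` or the bare path.
#' @return A [spectral_image()].
#' @export
read_envi <- function(path) {
  base <- sub("\\.hdr$", "", path)
  hdr_path <- paste0(base, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  bin <- NULL
  for (ext in c(".raw", ".img", ".dat", "")) {
    cand <- paste0(base, ext)
    if (file.exists(cand) && cand != hdr_path) { bin <- cand; break }
  }
  if (is.null(bin)) stop("ENVI binary not found for ", base)
  size <- switch(as.character(h$dtype), "4" = 4L, "5" = 8L,
                 stop("ENVI header ", hdr_path, ": unsupported `data type` ", h$dtype))
  n <- h$samples * h$lines * h$bands
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = size,
                  endian = if (h$byte_order == 0) "little" else "big")
  if (length(vals) != n)
    stop("ENVI binary ", bin, ": expected ", n, " values, found ", length(vals),
         " (field `samples`/`lines`/`bands` mismatch)")
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines),
                 stop("ENVI header ", hdr_path, ": unsupported `interleave` ", h$interleave))
  arr <- array(vals, dims)
  perm <- switch(h$interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2), bip = c(3, 2, 1))
  spectral_image(aperm(arr, perm))
}

label_palette <- function(m) {
  # deterministic distinct colors for up to 255 classes
  hues <- (seq_len(m) - 1) / max(m, 1)
  t(sapply(hues, function(h) {
    rgb <- grDevices::hsv(h, s = 0.75, v = 0.9)
    as.numeric(grDevices::col2rgb(rgb)) / 255
  }))
}

#' Write a label map
#'
#' `.png` paths get a paletted color image (one distinct color per class);
#' `.csv` paths get a plain integer grid without header.
#'
#' @param labels a [label_map()].
#' @param path output path ending in `.png` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  lab <- label_map(labels)
  if (grepl("\\.png$", path)) {
    m <- attr(lab, "n_classes")
    pal <- label_palette(m)
    img <- array(0, c(nrow(lab), ncol(lab), 3))
    for (ch in 1:3) img[, , ch] <- matrix(pal[lab, ch], nrow(lab), ncol(lab))
    png::writePNG(img, path)
  } else if (grepl("\\.csv$", path)) {
    write.table(unclass(lab), path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else stop("unsupported label format: ", path)
  invisible(path)
}

#' Read a label map
#'
#' PNG colors are mapped to class ids `1..M` in order of first appearance;
#' CSV files are read as integer grids and canonicalized the same way.
#'
#' @param path path ending in `.png` or `.csv`.
#' @return A [label_map()].
#' @export
read_labels <- function(path) {
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
    key <- apply(round(img * 255), c(1, 2), paste, collapse = ",")
    lev <- unique(as.vector(key))
    out <- label_map(matrix(match(key, lev), nrow(key), ncol(key)))
    attr(out, "levels") <- lev  # persist colors so maps can be re-aligned
    out
  } else if (grepl("\\.csv$", path)) {
    label_map(as.matrix(read.csv(path, header = FALSE)))
  } else stop("unsupported label format: ", path)
}

#' Write a transition rule set to JSON
#'
#' The JSON object carries `rules` (an `M x 6` array: three gradient
#' moduli, two condition angles, one action angle) and `bounds`.
#'
#' @param rules a [rule_set()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  rules <- rule_set(rules)
  obj <- list(rules = unname(apply(unclass(rules), 1, as.numeric, simplify = FALSE)),
              bounds = list(modulus = c(0, 2), angle = c(0, 2 * pi)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transition rule set from JSON
#'
#' @param path `.json` path written by [write_rules()].
#' @return A [rule_set()].
#' @export
read_rules <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rules)) stop("rule-set JSON ", path, ": missing field `rules`")
  m <- obj$rules
  if (is.list(m)) m <- do.call(rbind, m)
  if (!is.matrix(m) || ncol(m) != 6)
    stop("rule-set JSON ", path, ": `rules` must be an M x 6 array")
  rule_set(m)
}
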