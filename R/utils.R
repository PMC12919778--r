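#' @importFrom withr with_seed
NULL

## Evaluate expr under a fixed RNG state without disturbing the caller's
## stream. All seeded operations in the package funnel through here so that
## "same seed => bitwise-identical result" holds package-wide.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

## Largest-remainder apportionment of `size` draws across strata with the
## given counts. Ties in the fractional remainders are broken by stratum
## order (names ascending when named).
largestRemainder <- function(counts, size) {
  stopifnot(all(counts >= 0), size >= 0, size <= sum(counts))
  quota <- size * counts / sum(counts)
  base <- floor(quota)
  left <- size - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))
    take <- ord[seq_len(left)]
    base[take] <- base[take] + 1L
  }
  as.integer(base)
}

## Consistent error helper: all user-facing validation errors carry a class
## so tests can target them without string matching.
flensError <- function(msg, class = "featurelens_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Derive a stream of sub-seeds from one master seed, staying inside the
## 32-bit integer range.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

## Accept an image as an H x W x 3 array in [0,1], an H x W matrix
## (grayscale, promoted to 3 channels), or values on the 0..255 integer
## scale (rescaled). Returns H x W x 3 in [0,1].
asRGBArray <- function(img) {
  if (is.character(img)) img <- readImageFile(img)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!(is.array(img) && length(dim(img)) == 3L))
    flensError("image must be an H x W x C array or matrix")
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L)
    flensError(sprintf("expected 1, 3 or 4 channels, got %d", dim(img)[3]))
  if (max(img) > 1 + 1e-9) img <- img / 255
  img
}

readImageFile <- function(path) {
  if (!file.exists(path))
    flensError(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    tryCatch(png::readPNG(path),
             error = function(e) flensError(
               sprintf("cannot decode image %s: %s", path, conditionMessage(e))))
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      flensError(sprintf("reading %s files requires the EBImage package", ext))
    tryCatch({
      x <- EBImage::readImage(path)
      a <- EBImage::imageData(x)
      ## EBImage stores x (width) as the first dimension; transpose to H x W
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }, error = function(e) flensError(
      sprintf("cannot decode image %s: %s", path, conditionMessage(e))))
  }
  img
}
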