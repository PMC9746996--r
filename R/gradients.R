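#' Convert an RGB array to a grey map
#'
#' Fixed Rec. 601 luminance weights (0.299, 0.587, 0.114). Histology crops
#' are stained RGB; all co-occurrence statistics here operate on a single
#' grey channel, so colour input is collapsed first. Already-grey input
#' (a plain matrix) is returned unchanged.
#'
#' @param pixels either a numeric matrix (returned as-is) or an
#'   `rows x cols x 3` array with values in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
rgb_to_grey <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_to_grey: expected a rows x cols x 3 array", call. = FALSE)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# one-dimensional first derivative: central differences in the interior,
# one-sided at the two borders
.diff1 <- function(f, along) {
  n <- dim(f)[along]
  if (along == 2L) {
    g <- (f[, c(2:n, n), drop = FALSE] - f[, c(1, 1:(n - 1)), drop = FALSE]) / 2
    g[, 1] <- f[, 2] - f[, 1]
    g[, n] <- f[, n] - f[, n - 1]
  } else {
    g <- (f[c(2:n, n), , drop = FALSE] - f[c(1, 1:(n - 1)), , drop = FALSE]) / 2
    g[1, ] <- f[2, ] - f[1, ]
    g[n, ] <- f[n, ] - f[n - 1, ]
  }
  g
}

.sobel <- function(f, along) {
  # separable 3x3 Sobel, normalised by 8 so a unit ramp gives slope 1;
  # edges replicated
  nr <- nrow(f); nc <- ncol(f)
  pad <- rbind(f[1, , drop = FALSE], f, f[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sm <- function(m, k, along2) {   # 1-d correlation with kernel k (length 3)
    n <- dim(m)[along2]
    if (along2 == 2L)
      k[1] * m[, 1:(n - 2), drop = FALSE] + k[2] * m[, 2:(n - 1), drop = FALSE] +
        k[3] * m[, 3:n, drop = FALSE]
    else
      k[1] * m[1:(n - 2), , drop = FALSE] + k[2] * m[2:(n - 1), , drop = FALSE] +
        k[3] * m[3:n, , drop = FALSE]
  }
  if (along == 2L) sm(sm(pad, c(1, 2, 1) / 4, 1L), c(-1, 0, 1) / 2, 2L)
  else             sm(sm(pad, c(1, 2, 1) / 4, 2L), c(-1, 0, 1) / 2, 1L)
}

#' Gradient magnitude and direction maps of a cell image
#'
#' Computes the image gradient `(gx, gy)` of the grey map by finite
#' differences, its magnitude `sqrt(gx^2 + gy^2)` and its direction. The
#' x axis runs along columns and the y axis along rows (row index increasing
#' downward). Two direction conventions are supported:
#' \describe{
#'   \item{`"atan2"` (default)}{four-quadrant `atan2(gy, gx)` with principal
#'     range `(-pi, pi]` -- the standard image-gradient direction.}
#'   \item{`"transposed"`}{`atan(gx / gy)` with principal range `(-pi/2, pi/2]`
#'     and value 0 where `gy = 0` -- the transposed arctangent ratio some
#'     texts print; retained so either reading is reproducible.}
#' }
#' Pixels with `gx = gy = 0` get direction 0, avoiding NaN propagation into
#' quantization.
#'
#' @param cell a [cell_image()] or a plain numeric matrix (full mask
#'   assumed). Must be at least 3x3.
#' @param scheme `"central"` (default; one-sided at borders) or `"sobel"`.
#' @param direction_convention `"atan2"` or `"transposed"`.
#' @return object of class `gradient_maps` with fields `gx`, `gy`,
#'   `magnitude`, `direction`, `mask`, `direction_range`.
#' @export
compute_gradients <- function(cell, scheme = c("central", "sobel"),
                              direction_convention = c("atan2", "transposed")) {
  scheme <- match.arg(scheme)
  direction_convention <- match.arg(direction_convention)
  if (is.matrix(cell)) cell <- cell_image(cell, label = "healthy")
  f <- cell$pixels
  if (nrow(f) < 3 || ncol(f) < 3)
    stop("compute_gradients: image must be at least 3x3", call. = FALSE)
  if (scheme == "central") {
    gx <- .diff1(f, 2L); gy <- .diff1(f, 1L)
  } else {
    gx <- .sobel(f, 2L); gy <- .sobel(f, 1L)
  }
  magnitude <- sqrt(gx^2 + gy^2)
  if (direction_convention == "atan2") {
    direction <- atan2(gy, gx)
    direction[gx == 0 & gy == 0] <- 0
    rng <- c(-pi, pi)
  } else {
    direction <- atan(ifelse(gy == 0, 0, gx / gy))
    direction[gy == 0] <- 0
    rng <- c(-pi / 2, pi / 2)
  }
  structure(list(gx = gx, gy = gy, magnitude = magnitude,
                 direction = direction, mask = cell$mask,
                 direction_range = rng,
                 convention = direction_convention),
            class = "gradient_maps")
}

#' Rescale a map to N grey levels
#'
#' Linear binning of in-mask values into integer levels `1..N`. Under the
#' default `"per-image-minmax"` policy the in-mask minimum and maximum span
#' the bins, which makes the representation invariant to affine rescaling of
#' the input -- the property that shields gradient-based texture statistics
#' from global staining-intensity shifts. A constant map maps to level 1
#' everywhere. Under `"fixed-range"` an explicit `range = c(lo, hi)` spans
#' the bins instead (values outside are clipped). Out-of-mask pixels carry
#' `NA`, the sentinel later excluded from co-occurrence counting.
#'
#' @param map numeric matrix.
#' @param mask logical matrix of the same shape; defaults to all-`TRUE`.
#' @param N grey-level count; one of 8, 16, 32, 64.
#' @param range_policy `"per-image-minmax"` or `"fixed-range"`.
#' @param range length-2 numeric, required for `"fixed-range"`.
#' @param source_kind one of `"GD"`, `"GM"`, `"intensity"` (metadata only).
#' @return object of class `quantized_map`: fields `levels` (integer matrix,
#'   `NA` outside mask), `N`, `mask`, `source_kind`.
#' @export
quantize <- function(map, mask = NULL, N,
                     range_policy = c("per-image-minmax", "fixed-range"),
                     range = NULL, source_kind = c("intensity", "GD", "GM")) {
  range_policy <- match.arg(range_policy)
  source_kind <- match.arg(source_kind)
  if (!N %in% c(8L, 16L, 32L, 64L))
    stop("quantize: N must be one of 8, 16, 32, 64", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map), ncol(map))
  if (!any(mask)) stop("quantize: empty mask", call. = FALSE)
  if (range_policy == "per-image-minmax") {
    lo <- min(map[mask]); hi <- max(map[mask])
  } else {
    if (is.null(range) || length(range) != 2L)
      stop("quantize: 'fixed-range' needs range = c(lo, hi)", call. = FALSE)
    lo <- range[1]; hi <- range[2]
  }
  lev <- matrix(NA_integer_, nrow(map), ncol(map))
  if (hi > lo) {
    v <- floor((map[mask] - lo) / (hi - lo) * N) + 1L
    lev[mask] <- as.integer(pmin(pmax(v, 1L), N))
  } else {
    lev[mask] <- 1L
  }
  structure(list(levels = lev, N = as.integer(N), mask = mask,
                 source_kind = source_kind),
            class = "quantized_map")
}

# map selection shared by the GLCM and Haralick dataset builders
.cell_qmap <- function(cell, map_kind, N, scheme = "central",
                       direction_convention = "atan2",
                       range_policy = "per-image-minmax") {
  map_kind <- match.arg(map_kind, c("GD", "GM", "intensity"))
  if (map_kind == "intensity") {
    m <- rgb_to_grey(cell$pixels)
    rng <- c(0, 1)
  } else {
    g <- compute_gradients(cell, scheme = scheme,
                           direction_convention = direction_convention)
    if (map_kind == "GD") { m <- g$direction; rng <- g$direction_range }
    else { m <- g$magnitude; rng <- c(0, sqrt(2) / 2) }  # bound for 0..1 input
  }
  quantize(m, cell$mask, N, range_policy = range_policy,
           range = if (range_policy == "fixed-range") rng,
           source_kind = map_kind)
}
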