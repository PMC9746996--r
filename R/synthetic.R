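#' Synthetic two-class cell-image generator
#'
#' Configuration for [generate_dataset()]. The generator emulates the
#' statistical structure of segmented NeuN-stained neuron crops: two classes
#' of variably sized cell images whose *interior texture* -- not their raw
#' staining intensity -- separates them. "Healthy" cells carry a smooth,
#' low-spatial-frequency interior (radial intensity ramp plus a darker
#' elliptical nucleus over a smooth staining field), so neighbouring
#' gradient directions agree; "dying" cells carry dense granular
#' fragmentation impulses, so gradient directions are spatially disordered
#' while the intensity co-occurrence structure stays deliberately close to
#' the healthy class.
#'
#' @param n_per_class cells generated per class (default 500, the scale of
#'   the motivating 500 healthy + 500 dying dataset).
#' @param size_range integer vector `c(min, max)` side length in pixels.
#'   Minimum allowed is 16 so the smallest cell still admits co-occurrence
#'   displacements up to d = 15 along at least one axis.
#' @param noise_sd additive Gaussian pixel noise, on the 0..1 intensity
#'   scale.
#' @param intensity_overlap scalar in `[0, 1]`. 1 means the two classes draw
#'   their per-cell mean intensity from an identical distribution (intensity
#'   carries no class signal); 0 gives the maximal mean separation of 0.1.
#' @param seed integer RNG seed; the dataset is bit-identical for equal
#'   configurations.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 500L, size_range = c(20L, 100L),
                         noise_sd = 0.02, intensity_overlap = 0.8,
                         seed = 1L) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L ||
      n_per_class < 1 || n_per_class != round(n_per_class))
    stop("synth_config: 'n_per_class' must be a positive integer", call. = FALSE)
  if (!is.numeric(size_range) || length(size_range) != 2L ||
      any(size_range != round(size_range)) || size_range[1] > size_range[2])
    stop("synth_config: 'size_range' must be an increasing integer pair", call. = FALSE)
  if (size_range[1] < 16)
    stop("synth_config: 'size_range' minimum side must be >= 16", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("synth_config: 'noise_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(intensity_overlap) || length(intensity_overlap) != 1L ||
      intensity_overlap < 0 || intensity_overlap > 1)
    stop("synth_config: 'intensity_overlap' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("synth_config: 'seed' must be an integer", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 size_range = as.integer(size_range),
                 noise_sd = noise_sd,
                 intensity_overlap = intensity_overlap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Construct a cell image
#'
#' One segmented cell: a grey-value map in 0..1, a binary mask marking the
#' cell interior (everything outside is background excluded from all texture
#' statistics), a class label and an identifier.
#'
#' @param pixels numeric matrix, values in `[0, 1]`.
#' @param mask logical matrix of the same shape; defaults to all-`TRUE`.
#' @param label `"healthy"` or `"dying"`.
#' @param cell_id opaque identifier string.
#' @return an object of class `cell_image`.
#' @export
cell_image <- function(pixels, mask = NULL, label, cell_id = "cell") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("cell_image: 'pixels' must be a numeric matrix", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!identical(dim(mask), dim(pixels)))
    stop("cell_image: 'mask' and 'pixels' must share shape", call. = FALSE)
  if (!label %in% c("healthy", "dying"))
    stop("cell_image: 'label' must be \"healthy\" or \"dying\"", call. = FALSE)
  structure(list(pixels = pixels, mask = mask > 0, label = label,
                 cell_id = as.character(cell_id)),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image %s: %dx%d px, %d in mask, label=%s>\n",
              x$cell_id, nrow(x$pixels), ncol(x$pixels), sum(x$mask), x$label))
  invisible(x)
}

# Filled-ellipse mask with random orientation; axes sized so the mask keeps
# a wide interior (>= 16 columns for the smallest cells).
.ellipse_mask <- function(side, ecc = stats::runif(1, 0.75, 1),
                          theta = stats::runif(1, 0, pi)) {
  c0 <- (side + 1) / 2
  a <- 0.46 * side
  b <- min(a, max(a * ecc, 8.2))   # minor axis wide enough that the mask
                                   # bounding box keeps >= 16 columns
  rc <- expand.grid(r = seq_len(side), c = seq_len(side))
  dx <- rc$c - c0
  dy <- rc$r - c0
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, side, side)
}

# separable Gaussian blur with edge replication
.gaussian_blur <- function(m, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(m, along) {
    n <- dim(m)[along]
    idx <- function(sh) pmin(pmax(seq_len(n) + sh, 1L), n)
    out <- 0
    for (t in seq_along(k)) {
      sh <- t - hw - 1L
      out <- out + k[t] * (if (along == 2L) m[, idx(sh), drop = FALSE]
                           else m[idx(sh), , drop = FALSE])
    }
    out
  }
  conv1(conv1(m, 1L), 2L)
}

# Smooth interior: radial ramp falling away from an off-centre nucleus, a
# darker Gaussian nucleus blob, and a heavily smoothed random field standing
# in for gradual cytoplasmic staining variation. Gradients are locally
# coherent: neighbouring pixels agree on direction.
.healthy_texture <- function(side) {
  c0 <- (side + 1) / 2
  off <- stats::runif(2, -0.1, 0.1) * side
  rc <- expand.grid(r = seq_len(side), c = seq_len(side))
  d2 <- (rc$r - c0 - off[1])^2 + (rc$c - c0 - off[2])^2
  rmax2 <- (0.7 * side)^2
  ramp <- 0.35 * (1 - pmin(d2 / rmax2, 1))          # bright centre, dim rim
  nuc_r2 <- (stats::runif(1, 0.12, 0.2) * side)^2
  nucleus <- 0.25 * exp(-d2 / (2 * nuc_r2))          # darker nucleus
  field <- .gaussian_blur(matrix(stats::rnorm(side * side), side, side),
                          sigma = 3)                 # fixed granule scale
  field <- 0.6 * field / max(abs(field))
  matrix(ramp - nucleus, side, side) + field
}

# Disordered interior: the same smooth staining background as the healthy
# recipe, overlaid with dense granular impulses (fragmented, condensed
# chromatin). Each impulse flips only isolated intensity values -- the
# raw-intensity co-occurrence structure stays close to the healthy class,
# especially under the per-cell staining tone curve -- but it scrambles the
# intensity derivatives around every hit pixel: the fragmentation signature
# lives in derivative (gradient-direction) space.
.dying_texture <- function(side) {
  rho <- stats::runif(1, 0.5, 0.8)      # fragment density
  amp <- stats::runif(1, 0.1, 0.2)      # fragment contrast
  imp <- matrix(0, side, side)
  hit <- stats::runif(side * side) < rho
  imp[hit] <- amp * sign(stats::runif(sum(hit)) - 0.5)
  .healthy_texture(side) + imp
}

#' Generate a labelled synthetic cell-image dataset
#'
#' Produces `2 * n_per_class` [cell_image()] objects, alternating recipes:
#' healthy cells get a smooth radial-ramp-plus-nucleus interior over a
#' smooth staining field (spatially coherent gradient directions), dying
#' cells get the same background overlaid with dense granular fragmentation
#' impulses (disordered gradient directions). Every cell is then passed
#' through a random monotone staining tone curve (gamma in about 1/3..3)
#' and contrast depth, the staining nuisance that confounds raw-intensity
#' co-occurrence statistics but leaves gradient directions untouched.
#' Each cell's in-mask mean intensity is set to a draw from a class
#' distribution whose means are `0.5 +/- 0.05 * (1 - intensity_overlap)`,
#' so at `intensity_overlap = 1` brightness alone is non-discriminative by
#' construction. Fully deterministic given the configuration.
#'
#' @param config a [synth_config()].
#' @return list of `cell_image`, length `2 * n_per_class`.
#' @export
#' @examples
#' cells <- generate_dataset(synth_config(n_per_class = 3, seed = 7))
#' table(vapply(cells, `[[`, "", "label"))
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, as.list(config))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  sep <- 0.05 * (1 - config$intensity_overlap)
  cells <- vector("list", 2L * config$n_per_class)
  idx <- 0L
  for (i in seq_len(config$n_per_class)) {
    for (label in c("healthy", "dying")) {
      idx <- idx + 1L
      pool <- seq(config$size_range[1], config$size_range[2])
      side <- pool[sample.int(length(pool), 1L)]
      mask <- .ellipse_mask(side)
      tex <- if (label == "healthy") .healthy_texture(side) else .dying_texture(side)
      if (config$noise_sd > 0)
        tex <- tex + matrix(stats::rnorm(side * side, 0, config$noise_sd), side, side)
      mu_class <- if (label == "healthy") 0.5 + sep else 0.5 - sep
      target_mean <- stats::rnorm(1, mu_class, 0.05)
      # per-cell staining variability: a random monotone tone curve (gamma)
      # and a random contrast depth, applied identically to both classes.
      # Gradient DIRECTION is exactly invariant to monotone intensity
      # transforms, so this confounds raw-intensity co-occurrence statistics
      # (the staining nuisance motivating gradient representations) while
      # leaving the direction signal intact.
      lo <- min(tex[mask]); hi <- max(tex[mask])
      tex <- (tex - lo) / max(hi - lo, 1e-12)
      gamma <- exp(stats::runif(1, -1.1, 1.1))
      tex <- tex^gamma
      depth <- stats::runif(1, 0.35, 0.9)          # staining contrast depth
      tex <- tex * depth
      # shift the in-mask interior to the drawn target mean exactly, then clip
      tex <- tex - mean(tex[mask]) + target_mean
      tex <- pmin(pmax(tex, 0), 1)
      tex[!mask] <- 0
      cells[[idx]] <- cell_image(tex, mask, label,
                                 sprintf("%s_%04d", label, i))
    }
  }
  cells
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mean local circular dispersion of gradient directions
#'
#' Diagnostic used to verify the generator's separability-by-design: for
#' every in-mask pixel the circular variance `1 - |mean(exp(i * theta))|` of
#' gradient directions over its 3x3 neighbourhood is computed, and the
#' in-mask average returned. Smooth interiors (healthy recipe) give values
#' near 0; speckle (dying recipe) approaches 1.
#'
#' @param cell a [cell_image()].
#' @return scalar in `[0, 1]`.
#' @export
direction_dispersion <- function(cell) {
  g <- compute_gradients(cell)
  d <- g$direction
  zr <- cos(d); zi <- sin(d)
  box <- function(m) {               # 3x3 box sum via row/col shifts
    m2 <- m
    m2 <- m2 + rbind(m[-1, , drop = FALSE], 0) + rbind(0, m[-nrow(m), , drop = FALSE])
    m2 + cbind(m2[, -1, drop = FALSE], 0) + cbind(0, m2[, -ncol(m2), drop = FALSE])
  }
  w <- matrix(1, nrow(zr), ncol(zr))
  R <- sqrt(box(zr)^2 + box(zi)^2) / box(w)
  mean(1 - R[cell$mask])
}

# ---- plain-text image I/O (ASCII PGM, "P2") -------------------------------
# No PNG/TIFF codec ships with the supported R stack, so datasets round-trip
# through 8-bit ASCII portable greymaps: text-only, self-describing, and
# readable by any image viewer / scikit-image / ImageMagick.

#' Write a matrix as an 8-bit ASCII PGM image
#' @param m numeric matrix, values in `[0, 1]` (logical masks allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path) {
  v <- round(pmin(pmax(as.numeric(m), 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  # row-major pixel order, one image row per line
  apply(matrix(v, nrow(m), ncol(m)), 1L,
        function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read an ASCII PGM image into a matrix scaled to 0..1
#' @param path a P2 (ASCII) PGM file.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("read_pgm: not an ASCII PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); mx <- as.numeric(toks[4])
  v <- as.numeric(toks[-(1:4)])
  if (length(v) != w * h) stop("read_pgm: truncated pixel data in ", path, call. = FALSE)
  matrix(v, nrow = h, ncol = w, byrow = TRUE) / mx
}

#' Write a cell dataset to disk
#'
#' One PGM image and one PGM mask per cell, plus a CSV manifest with columns
#' `cell_id, image_path, mask_path, label`. Round-trips via
#' [read_dataset()].
#'
#' @param cells list of [cell_image()].
#' @param dir output directory (created if absent).
#' @return path of the manifest CSV.
#' @export
write_dataset <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("write_dataset: cannot create directory ", dir, call. = FALSE)
  rows <- lapply(cells, function(cl) {
    img <- file.path(dir, paste0(cl$cell_id, ".pgm"))
    msk <- file.path(dir, paste0(cl$cell_id, "_mask.pgm"))
    write_pgm(cl$pixels, img)
    write_pgm(cl$mask, msk)
    data.frame(cell_id = cl$cell_id, image_path = basename(img),
               mask_path = basename(msk), label = cl$label,
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), image_path = character(),
               mask_path = character(), label = character())
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Read a cell dataset from a manifest
#'
#' @param manifest path to a manifest CSV as written by [write_dataset()];
#'   image/mask paths are resolved relative to the manifest's directory.
#' @return list of [cell_image()].
#' @export
read_dataset <- function(manifest) {
  dir <- dirname(manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    px <- read_pgm(file.path(dir, tab$image_path[i]))
    mk <- read_pgm(file.path(dir, tab$mask_path[i])) > 0.5
    cell_image(px, mk, tab$label[i], tab$cell_id[i])
  })
}
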