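#' Displacement offsets for a dataset group
#'
#' The co-occurrence grid uses four angles (0, 45, 90, 135 degrees) and
#' nested distance sets: group 1 uses d = 1..4 (16 offsets), group 2
#' d = 1..8 (32 offsets), group 3 d = 1..15 (60 offsets). The distance
#' ceiling of 15 reflects the column count of the smallest admissible cell.
#' Ordering is angle-major, then distance.
#'
#' @param group 1, 2 or 3.
#' @return data.frame with columns `distance`, `angle` (degrees).
#' @export
offsets_for_group <- function(group) {
  if (!length(group) == 1L || !group %in% 1:3)
    stop("offsets_for_group: group must be 1, 2 or 3", call. = FALSE)
  dmax <- c(4L, 8L, 15L)[group]
  # expand.grid varies its first factor fastest: all distances for angle 0,
  # then 45, 90, 135 -- the documented angle-major order
  expand.grid(distance = seq_len(dmax), angle = c(0L, 45L, 90L, 135L),
              KEEP.OUT.ATTRS = FALSE)
}

# displacement (delta_row, delta_col) for one (distance, angle);
# row index increases downward, so 45 degrees points up-right
.offset_delta <- function(distance, angle) {
  if (!angle %in% c(0, 45, 90, 135))
    stop("offset: angle must be one of 0, 45, 90, 135", call. = FALSE)
  if (distance < 1 || distance > 15 || distance != round(distance))
    stop("offset: distance must be an integer in 1..15", call. = FALSE)
  d <- as.integer(distance)
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

#' Grey-level co-occurrence matrix of a quantized map
#'
#' Counts in-mask pixel pairs `(p, p + delta)` with levels `(i, j)` where
#' `delta` is the displacement for `(distance, angle)`. Pairs with either
#' endpoint outside the mask (or the image) are skipped. With
#' `symmetric = TRUE` (default) the reversed displacement is counted too --
#' pairs taken "in both the right and left direction" -- which makes the
#' matrix symmetric. With `normalize = TRUE` counts are divided by the total
#' pair count, giving relative frequencies summing to 1.
#'
#' An offset too large for the map yields an all-zero matrix with a warning,
#' never an error, so per-cell sample counts stay constant downstream.
#'
#' @param qmap a [quantize()]d map.
#' @param distance integer pixels, 1..15.
#' @param angle 0, 45, 90 or 135 (degrees).
#' @param symmetric count the reversed displacement as well (default TRUE).
#' @param normalize divide by the total pair count (default TRUE).
#' @return object of class `glcm`: `counts` (N x N matrix), `N`, `distance`,
#'   `angle`, `symmetric`, `normalized`, `n_pairs`.
#' @export
compute_glcm <- function(qmap, distance, angle, symmetric = TRUE,
                         normalize = TRUE) {
  stopifnot(inherits(qmap, "quantized_map"))
  delta <- .offset_delta(distance, angle)
  lev <- qmap$levels
  N <- qmap$N
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- delta[1]; dc <- delta[2]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  counts <- matrix(0, N, N)
  if (nr - abs(dr) >= 1 && nc - abs(dc) >= 1 &&
      length(r0) >= 1 && length(c0) >= 1 && (nr > abs(dr)) && (nc > abs(dc))) {
    a <- lev[r0, c0, drop = FALSE]
    b <- lev[r0 + dr, c0 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      idx <- (a[ok] - 1L) * N + b[ok]          # row-major pair code
      tab <- tabulate(idx, nbins = N * N)
      counts <- matrix(as.numeric(tab), N, N, byrow = TRUE)
    }
  }
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0)
    warning(sprintf("compute_glcm: no valid pixel pair for d=%d, angle=%d",
                    as.integer(distance), as.integer(angle)), call. = FALSE)
  if (normalize && n_pairs > 0) counts <- counts / n_pairs
  structure(list(counts = counts, N = N, distance = as.integer(distance),
                 angle = as.integer(angle), symmetric = symmetric,
                 normalized = normalize, n_pairs = n_pairs),
            class = "glcm")
}

#' All GLCMs of one cell for a dataset group
#'
#' @param cell a [cell_image()].
#' @param map_kind `"GD"`, `"GM"` or `"intensity"`.
#' @param N GLCM size (8, 16, 32 or 64).
#' @param group dataset group 1, 2 or 3 (16 / 32 / 60 offsets).
#' @param ... passed to the quantization stage (`scheme`,
#'   `direction_convention`, `range_policy`).
#' @param symmetric,normalize as in [compute_glcm()].
#' @return object of class `glcm_stack`: list with `glcms` (list of `glcm`),
#'   `group`, `cell_id`, `label`, `N`.
#' @export
glcm_stack <- function(cell, map_kind = "GD", N = 8L, group = 1L,
                       symmetric = TRUE, normalize = TRUE, ...) {
  offs <- offsets_for_group(group)
  qmap <- .cell_qmap(cell, map_kind, N, ...)
  glcms <- lapply(seq_len(nrow(offs)), function(i)
    compute_glcm(qmap, offs$distance[i], offs$angle[i],
                 symmetric = symmetric, normalize = normalize))
  structure(list(glcms = glcms, group = as.integer(group),
                 cell_id = cell$cell_id, label = cell$label,
                 N = as.integer(N)),
            class = "glcm_stack")
}

#' Vectorise a GLCM
#'
#' Row-major flattening to a length-`N^2` vector; the inverse of
#' [unflatten_glcm()].
#' @param g a `glcm` or a plain N x N matrix.
#' @return numeric vector of length `N^2`.
#' @export
flatten_glcm <- function(g) {
  m <- if (inherits(g, "glcm")) g$counts else g
  as.vector(t(m))
}

#' Reshape a flattened GLCM back to its N x N matrix
#' @param v numeric vector of length `N^2`.
#' @param N matrix side.
#' @return N x N matrix.
#' @export
unflatten_glcm <- function(v, N) matrix(v, N, N, byrow = TRUE)

#' Build a vectorised-GLCM design matrix
#'
#' The core size-invariance trick: every cell, whatever its pixel size,
#' contributes `k` fixed-length samples, where `k` is the group's offset
#' count (16/32/60) and each sample is one row-major-flattened `N x N` GLCM.
#' GLCMs are thus treated as data augmentation -- `k` samples per cell, each
#' carrying its `cell_id` so evaluation can optionally group them.
#'
#' @inheritParams glcm_stack
#' @param cells non-empty list of [cell_image()].
#' @return list of class `glcm_dataset`: `X` (samples x N^2 matrix), `label`
#'   (character vector), `cell_id`, `distance`, `angle` (per-sample
#'   metadata), `map_kind`, `N`, `group`.
#' @export
build_dataset <- function(cells, map_kind = "GD", N = 8L, group = 1L,
                          symmetric = TRUE, normalize = TRUE, ...) {
  if (!length(cells)) stop("build_dataset: 'cells' is empty", call. = FALSE)
  offs <- offsets_for_group(group)
  k <- nrow(offs)
  n <- length(cells) * k
  X <- matrix(0, n, as.integer(N)^2)
  label <- character(n); cell_id <- character(n)
  row <- 0L
  for (cl in cells) {
    st <- glcm_stack(cl, map_kind = map_kind, N = N, group = group,
                     symmetric = symmetric, normalize = normalize, ...)
    for (g in st$glcms) {
      row <- row + 1L
      X[row, ] <- flatten_glcm(g)
      label[row] <- cl$label
      cell_id[row] <- cl$cell_id
    }
  }
  structure(list(X = X, label = label, cell_id = cell_id,
                 distance = rep(offs$distance, length(cells)),
                 angle = rep(offs$angle, length(cells)),
                 map_kind = map_kind, N = as.integer(N),
                 group = as.integer(group)),
            class = "glcm_dataset")
}

#' Enumerate the 12-dataset grid for one map kind
#'
#' Four GLCM sizes (8, 16, 32, 64) crossed with three offset groups.
#' @return data.frame with columns `N` and `group`, 12 rows.
#' @export
dataset_grid <- function() {
  expand.grid(N = c(8L, 16L, 32L, 64L), group = 1:3,
              KEEP.OUT.ATTRS = FALSE)
}
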