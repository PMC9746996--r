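#' Names of the ten Haralick texture statistics, in their fixed order
#' @export
haralick_names <- function() c(
  "contrast", "energy", "entropy", "homogeneity", "variance",
  "sum_average", "sum_variance", "sum_entropy",
  "difference_variance", "difference_entropy")

#' Ten Haralick texture statistics of a normalized GLCM
#'
#' The classical second-order texture descriptors computed from a normalized
#' co-occurrence matrix `p(i, j)` with levels `i, j = 1..N`:
#' \itemize{
#'   \item contrast: `sum (i - j)^2 p(i, j)`
#'   \item energy (angular second moment): `sum p(i, j)^2`
#'   \item entropy: `-sum p log p` (natural log; `0 log 0 := 0`)
#'   \item homogeneity (inverse difference moment variant):
#'     `sum p / (1 + (i - j)^2)`
#'   \item variance: `sum (i - mu)^2 p(i, j)` with `mu = sum i p(i, j)`,
#'     the GLCM mean (equal for rows and columns of a symmetric matrix)
#'   \item sum average / sum variance / sum entropy: mean, variance and
#'     entropy of the diagonal-sum marginal `p_{x+y}(k) = sum_{i+j=k} p`
#'   \item difference variance / difference entropy: variance and entropy of
#'     the absolute-difference marginal `p_{x-y}(k) = sum_{|i-j|=k} p`
#' }
#' Sum variance is taken about the sum average and difference variance about
#' the difference mean (the variance-of-marginal reading); entropies use
#' base e. Both choices are fixed and documented here because the
#' literature's definitions are ambiguous on exactly these points.
#'
#' @param glcm a [compute_glcm()] result with `normalized = TRUE`, or a
#'   plain matrix whose entries sum to 1.
#' @return named numeric vector of length 10 (order of [haralick_names()]).
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) {
    if (!glcm$normalized)
      stop("haralick_features: GLCM must be normalized", call. = FALSE)
    glcm$counts
  } else glcm
  N <- nrow(p)
  if (N < 2 || ncol(p) != N)
    stop("haralick_features: need a square GLCM with N >= 2", call. = FALSE)
  s <- sum(p)
  if (s == 0)
    stop("haralick_features: all-zero (degenerate) GLCM", call. = FALSE)
  if (abs(s - 1) > 1e-8)
    stop("haralick_features: GLCM entries must sum to 1", call. = FALSE)

  i <- matrix(seq_len(N), N, N)           # row level
  j <- t(i)                               # column level
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

  contrast    <- sum((i - j)^2 * p)
  energy      <- sum(p^2)
  entropy     <- -sum(xlogx(p))
  homogeneity <- sum(p / (1 + (i - j)^2))
  mu          <- sum(i * p)
  variance    <- sum((i - mu)^2 * p)

  # marginals over i+j (2..2N) and |i-j| (0..N-1)
  psum  <- as.vector(tapply(p, i + j, sum))
  ksum  <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(tapply(p, abs(i - j), sum))
  kdiff <- sort(unique(as.vector(abs(i - j))))

  sum_average        <- sum(ksum * psum)
  sum_variance       <- sum((ksum - sum_average)^2 * psum)
  sum_entropy        <- -sum(xlogx(psum))
  dmean              <- sum(kdiff * pdiff)
  difference_variance <- sum((kdiff - dmean)^2 * pdiff)
  difference_entropy  <- -sum(xlogx(pdiff))

  c(contrast = contrast, energy = energy, entropy = entropy,
    homogeneity = homogeneity, variance = variance,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy)
}

#' Build the standard-method (Haralick baseline) design matrix
#'
#' The conventional pipeline this package's gradient-direction method is
#' benchmarked against: GLCMs are computed from the raw intensity-quantized
#' map and each is reduced to its ten Haralick statistics, giving one
#' width-10 sample per GLCM (same per-cell sample multiplicity as
#' [build_dataset()]).
#'
#' @inheritParams build_dataset
#' @return list of class `glcm_dataset` with `X` of width 10 and
#'   `map_kind = "intensity"`, `features = "haralick"`.
#' @export
build_standard_dataset <- function(cells, N = 8L, group = 1L, ...) {
  if (!length(cells)) stop("build_standard_dataset: 'cells' is empty", call. = FALSE)
  offs <- offsets_for_group(group)
  k <- nrow(offs)
  n <- length(cells) * k
  X <- matrix(0, n, 10L, dimnames = list(NULL, haralick_names()))
  label <- character(n); cell_id <- character(n)
  row <- 0L
  for (cl in cells) {
    st <- glcm_stack(cl, map_kind = "intensity", N = N, group = group,
                     normalize = TRUE, ...)
    for (g in st$glcms) {
      row <- row + 1L
      X[row, ] <- if (g$n_pairs > 0) haralick_features(g) else rep(0, 10)
      label[row] <- cl$label
      cell_id[row] <- cl$cell_id
    }
  }
  structure(list(X = X, label = label, cell_id = cell_id,
                 distance = rep(offs$distance, length(cells)),
                 angle = rep(offs$angle, length(cells)),
                 map_kind = "intensity", features = "haralick",
                 N = as.integer(N), group = as.integer(group)),
            class = "glcm_dataset")
}
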