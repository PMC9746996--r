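# Independent brute-force oracles. These deliberately share no code with the
# implementation: naive double loops and closed forms only.

# co-occurrence counts by looping over every pixel and both displacement
# signs; levels matrix with NA outside the mask
oracle_glcm <- function(lev, N, distance, angle, symmetric = TRUE,
                        normalize = TRUE) {
  delta <- switch(as.character(angle),
                  "0" = c(0, distance), "45" = c(-distance, distance),
                  "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, N, N)
  signs <- if (symmetric) c(1, -1) else 1
  for (r in seq_len(nrow(lev))) for (cc in seq_len(ncol(lev))) {
    i <- lev[r, cc]
    if (is.na(i)) next
    for (s in signs) {
      r2 <- r + s * delta[1]; c2 <- cc + s * delta[2]
      if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
      j <- lev[r2, c2]
      if (is.na(j)) next
      counts[i, j] <- counts[i, j] + 1
    }
  }
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# the ten Haralick statistics by naive double loops
oracle_haralick <- function(p) {
  N <- nrow(p)
  contrast <- energy <- entropy <- homogeneity <- mu <- 0
  for (i in 1:N) for (j in 1:N) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    if (p[i, j] > 0) entropy <- entropy - p[i, j] * log(p[i, j])
    homogeneity <- homogeneity + p[i, j] / (1 + (i - j)^2)
    mu <- mu + i * p[i, j]
  }
  variance <- 0
  for (i in 1:N) for (j in 1:N) variance <- variance + (i - mu)^2 * p[i, j]
  psum <- rep(0, 2 * N); pdiff <- rep(0, N)     # indices k and |k|+1
  for (i in 1:N) for (j in 1:N) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  ks <- 2:(2 * N); kd <- 0:(N - 1)
  psum <- psum[ks]
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  dmean <- sum(kd * pdiff)
  difference_variance <- sum((kd - dmean)^2 * pdiff)
  difference_entropy <- -sum(ifelse(pdiff > 0, pdiff * log(pdiff), 0))
  c(contrast = contrast, energy = energy, entropy = entropy,
    homogeneity = homogeneity, variance = variance,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy)
}

# AUC as the Mann-Whitney U statistic: pairwise comparison with half-credit
# for ties
oracle_auc <- function(score, pos) {
  sp <- score[pos]; sn <- score[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# central-difference numerical gradient of a scalar function; the step is
# near the optimum h ~ eps^(1/3) so truncation and round-off error are both
# well below the 1e-6 comparison tolerance
oracle_num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# small deterministic random quantized map (levels 1..N, optional mask holes)
random_qmap <- function(nr, nc, N, p_hole = 0, seed = 1) {
  set.seed(seed)
  lev <- matrix(sample.int(N, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) >= p_hole, nr, nc)
  if (!any(mask)) mask[1] <- TRUE
  lev[!mask] <- NA_integer_
  structure(list(levels = lev, N = as.integer(N), mask = mask,
                 source_kind = "intensity"),
            class = "quantized_map")
}

small_cells <- function(n_per_class = 5, seed = 42, ...)
  generate_dataset(synth_config(n_per_class = n_per_class, seed = seed,
                                size_range = c(20L, 40L), ...))
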