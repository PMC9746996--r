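test_that("offsets_for_group yields the 16/32/60 grid in angle-major order", {
  for (g in 1:3) {
    offs <- offsets_for_group(g)
    expect_equal(nrow(offs), c(16L, 32L, 60L)[g])
    expect_setequal(unique(offs$angle), c(0L, 45L, 90L, 135L))
    expect_equal(max(offs$distance), c(4L, 8L, 15L)[g])
    # angle-major, distance ascending within each angle
    expect_equal(offs$distance, rep(seq_len(max(offs$distance)), 4))
  }
  expect_error(offsets_for_group(4), "group")
})

test_that("compute_glcm matches forced small cases", {
  # constant 4x4 map, d=1, horizontal, symmetric: 4 rows x 3 pairs x 2 dirs
  q <- structure(list(levels = matrix(1L, 4, 4), N = 8L,
                      mask = matrix(TRUE, 4, 4), source_kind = "intensity"),
                 class = "quantized_map")
  g <- compute_glcm(q, 1, 0, normalize = FALSE)
  expect_equal(g$counts[1, 1], 24)
  expect_equal(sum(g$counts), 24)

  # the 2x2 checker [[1,2],[2,1]]: horizontal pairs are all (1,2)/(2,1)
  q$levels <- matrix(c(1L, 2L, 2L, 1L), 2, 2); q$mask <- matrix(TRUE, 2, 2)
  g <- compute_glcm(q, 1, 0, normalize = FALSE)
  expect_equal(g$counts[1, 2], 2)
  expect_equal(g$counts[2, 1], 2)
  expect_equal(sum(diag(g$counts)), 0)
})

test_that("compute_glcm equals the brute-force pair counter everywhere", {
  cases <- expand.grid(seed = 1:5, angle = c(0, 45, 90, 135),
                       d = c(1, 2, 15), holes = c(0, 0.2))
  # 50+ random maps x all angles x d in {1, 2, 15}, with and without mask holes
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    q <- random_qmap(17, 19, 8, p_hole = cs$holes, seed = cs$seed + 100 * i)
    got <- compute_glcm(q, cs$d, cs$angle, normalize = FALSE)
    want <- oracle_glcm(q$levels, 8, cs$d, cs$angle, normalize = FALSE)
    expect_identical(unname(got$counts), unname(want))
    # normalized variant sums to one whenever any pair exists
    if (sum(want) > 0) {
      gn <- compute_glcm(q, cs$d, cs$angle, normalize = TRUE)
      expect_equal(sum(gn$counts), 1, tolerance = 1e-9)
      expect_equal(gn$counts, want / sum(want), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("symmetric GLCMs are symmetric and conserve pair counts", {
  set.seed(31)
  for (case in 1:10) {
    q <- random_qmap(12, 14, 16, p_hole = 0.1, seed = case)
    d <- sample(1:4, 1); a <- sample(c(0, 45, 90, 135), 1)
    gs <- compute_glcm(q, d, a, symmetric = TRUE, normalize = FALSE)
    gf <- compute_glcm(q, d, a, symmetric = FALSE, normalize = FALSE)
    expect_identical(gs$counts, t(gs$counts))
    expect_equal(sum(gs$counts), 2 * sum(gf$counts))
  }
})

test_that("an offset larger than the map yields a warned all-zero GLCM", {
  q <- random_qmap(8, 8, 8, seed = 3)
  expect_warning(g <- compute_glcm(q, 15, 0), "no valid")
  expect_equal(sum(g$counts), 0)
})

test_that("build_dataset emits per-GLCM samples of fixed width", {
  cells <- small_cells(5, seed = 17)           # 10 cells
  ds <- build_dataset(cells, "GD", N = 8, group = 1)
  expect_equal(dim(ds$X), c(160L, 64L))        # 10 x 16 samples, width 8^2
  expect_equal(unname(table(ds$label)[c("dying", "healthy")]), c(80L, 80L),
               ignore_attr = TRUE)
  expect_equal(length(unique(ds$cell_id)), 10L)
  # normalized rows sum to 1
  expect_equal(unname(rowSums(ds$X)), rep(1, 160), tolerance = 1e-9)
  # flatten/unflatten round-trip
  st <- glcm_stack(cells[[1]], "GD", N = 8, group = 1)
  for (g in st$glcms[c(1, 7, 16)])
    expect_identical(unflatten_glcm(flatten_glcm(g), 8L), g$counts)
  expect_error(build_dataset(list(), "GD", 8, 1), "empty")
})

test_that("design-matrix width is size-invariant and the grid has 12 cells", {
  # the core trick: a 20 px and a 100 px cell produce identical-width inputs
  cells <- generate_dataset(synth_config(n_per_class = 1, seed = 1,
                                         size_range = c(20L, 20L)))
  big <- generate_dataset(synth_config(n_per_class = 1, seed = 2,
                                       size_range = c(100L, 100L)))
  for (N in c(8L, 16L)) {
    d1 <- build_dataset(cells, "GD", N = N, group = 1)
    d2 <- build_dataset(big, "GD", N = N, group = 1)
    expect_identical(ncol(d1$X), ncol(d2$X))
    expect_identical(ncol(d1$X), as.integer(N^2))
  }
  expect_equal(nrow(dataset_grid()), 12L)
  expect_setequal(dataset_grid()$N, c(8L, 16L, 32L, 64L))
  expect_setequal(dataset_grid()$group, 1:3)
})

test_that("GM and intensity map kinds produce valid datasets too", {
  cells <- small_cells(2, seed = 23)
  for (mk in c("GM", "intensity")) {
    ds <- build_dataset(cells, mk, N = 8, group = 1)
    expect_equal(dim(ds$X), c(64L, 64L))
    expect_true(all(ds$X >= 0))
  }
})
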