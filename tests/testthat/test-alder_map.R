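make_stack <- function(nr = 10, nc = 10, nb = 2, seed = 1, res = 5) {
  set.seed(seed)
  raster_stack(lapply(seq_len(nb), function(b) matrix(rnorm(nr * nc), nr, nc)),
               res = res)
}

test_that("fusion standardizes bands and unions nodata masks", {
  st <- make_stack()
  fused <- fuse_and_standardize(list(st))
  for (b in fused$bands) {
    expect_equal(mean(b), 0, tolerance = 1e-12)
    expect_equal(sd(b), 1, tolerance = 1e-12)
  }
  # constant band standardizes to zeros rather than dividing by zero
  cst <- raster_stack(matrix(3, 10, 10), res = 5)
  expect_true(all(fuse_and_standardize(list(cst))$bands[[1]] == 0))
  # band counts add across layers
  two <- fuse_and_standardize(list(make_stack(nb = 2), make_stack(nb = 3)))
  expect_length(two$bands, 5)
  # NA in one band masks the cell everywhere
  st2 <- make_stack(nb = 2)
  st2$bands[[1]][1, 1] <- NA
  fused2 <- fuse_and_standardize(list(st2))
  expect_true(all(is.na(vapply(fused2$bands, function(b) b[1, 1], numeric(1)))))
  # disjoint extents are rejected
  far <- raster_stack(matrix(1, 5, 5), res = 5, xll = 1e6, yll = 1e6)
  expect_error(fuse_and_standardize(list(st, far)), "overlap")
})

test_that("resampling aligns a finer layer onto the target grid", {
  target <- raster_stack(matrix(0, 5, 5), res = 10)
  # linear ramp in x at 5-m resolution resamples to the coarse centers
  fine_vals <- matrix(rep(seq(2.5, 47.5, by = 5), each = 10), 10, 10)
  fine <- raster_stack(fine_vals, res = 5)
  fused <- fuse_and_standardize(list(target, fine))
  ramp <- fused$bands[[2]]
  expect_true(all(diff(ramp[1, ]) > 0))
  expect_equal(ramp[1, ], ramp[5, ], tolerance = 1e-12)
})

test_that("k-means classification is deterministic and recovers two classes", {
  set.seed(3)
  truth <- matrix(rep(c(TRUE, FALSE), each = 200), 20, 20)
  bands <- lapply(1:3, function(b) {
    m <- matrix(rnorm(400), 20, 20); m[truth] <- m[truth] + 6; m
  })
  st <- fuse_and_standardize(list(raster_stack(bands, res = 5)))
  r1 <- kmeans_classify(st, k = 2, seed = 11)
  r2 <- kmeans_classify(st, k = 2, seed = 11)
  expect_identical(r1$labels$values, r2$labels$values)
  agree <- two_class_agreement(r1$labels$values == 1, truth)
  expect_gte(agree, 0.95)

  one <- kmeans_classify(st, k = 1, seed = 2)
  expect_equal(length(unique(as.vector(one$labels$values))), 1)
  X <- do.call(cbind, lapply(st$bands, as.vector))
  expect_equal(one$model$inertia,
               sum(scale(X, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(kmeans_classify(st, k = 401, seed = 1), "fewer valid cells")
})

test_that("cluster selection follows the ground-point purity rule", {
  labels <- structure(list(values = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                           res = 5, xll = 0, yll = 0, nrow = 2, ncol = 2),
                      class = "label_map")
  # all alder points in cluster 1 (left column)
  gt <- data.frame(x = c(2.5, 2.5), y = c(2.5, 7.5),
                   label = c("alder", "alder"))
  expect_equal(select_alder_clusters(labels, gt), 1L)
  # alder points split over both clusters, both pure
  gt2 <- data.frame(x = c(2.5, 7.5), y = c(2.5, 2.5),
                    label = c("alder", "alder"))
  expect_equal(select_alder_clusters(labels, gt2), c(1L, 2L))
  # impure cluster excluded at min_purity 0.5 (1 alder vs 9 other)
  gt3 <- data.frame(x = rep(c(2.5, 2.5), c(1, 9)),
                    y = rep(c(2.5, 7.5), c(1, 9)),
                    label = c("alder", rep("other", 9)))
  expect_length(select_alder_clusters(labels, gt3), 0)
  # off-grid points are dropped with a warning
  gt4 <- rbind(gt, data.frame(x = 100, y = 100, label = "alder"))
  expect_warning(ids <- select_alder_clusters(labels, gt4), "dropped")
  expect_equal(ids, 1L)
  expect_error(select_alder_clusters(labels,
                                     data.frame(x = 2.5, y = 2.5,
                                                label = "other")),
               "alder")
})

test_that("binary map, validation and area behave as set operations", {
  labels <- structure(list(values = matrix(c(1L, 2L, 3L, 4L), 2, 2),
                           res = 5, xll = 0, yll = 0, nrow = 2, ncol = 2),
                      class = "label_map")
  all_ids <- 1:4
  expect_true(all(binary_map(labels, all_ids)$values))
  expect_error(binary_map(labels, 9L), "not present")
  m13 <- binary_map(labels, c(1L, 3L))
  m24 <- binary_map(labels, c(2L, 4L))
  expect_equal(m13$values, !m24$values)
  expect_equal(map_area(m13) + map_area(m24), 4 * 25)
  expect_equal(map_area(binary_map(labels, 1L)), 25)

  gt <- data.frame(x = c(2.5, 2.5, 7.5, 7.5), y = c(7.5, 2.5, 7.5, 2.5),
                   label = c("alder", "alder", "other", "other"))
  perfect <- binary_map(labels, c(1L, 2L))
  v <- validate_map(perfect, gt)
  expect_equal(v$accuracy, 1)
  expect_equal(v$precision, 1)
  expect_equal(v$recall, 1)
  inverted <- binary_map(labels, c(3L, 4L))
  vi <- validate_map(inverted, gt)
  expect_equal(vi$recall, 0)
  half <- binary_map(labels, c(1L, 3L))
  expect_equal(validate_map(half, gt)$accuracy, 0.5)
})

test_that("classification chain recovers a well-separated synthetic scene", {
  cfg <- scenario_config(seed = 5)
  scene <- gen_raster_scene(cfg)
  fused <- fuse_and_standardize(list(scene$stack))
  km <- kmeans_classify(fused, k = 50, seed = 5)
  ids <- select_alder_clusters(km$labels, scene$ground_truth)
  amap <- binary_map(km$labels, ids)
  acc <- mean(amap$values == scene$truth_map$values)
  expect_gte(acc, 0.95)
  expect_gte(validate_map(amap, scene$ground_truth)$accuracy, 0.95)
  # k-means labelling is invariant to band order up to identical assignment
  rev_stack <- raster_stack(rev(fused$bands), res = fused$res)
  km_rev <- kmeans_classify(fuse_and_standardize(list(rev_stack)),
                            k = 50, seed = 5)
  expect_equal(map_area(binary_map(
    km_rev$labels, select_alder_clusters(km_rev$labels, scene$ground_truth))),
    map_area(amap), tolerance = 0.1)
})

test_that("ascii grid round-trips rasters and binary maps", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  st <- make_stack(nb = 1, nr = 6, nc = 4)
  st$bands[[1]][2, 3] <- NA
  write_ascii_grid(st, tmp)
  back <- read_ascii_grid(tmp)
  expect_equal(back$bands[[1]], st$bands[[1]], tolerance = 1e-6)
  expect_equal(back$res, st$res)
  m <- binary_class_map(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2), res = 5,
                        xll = 10, yll = 20)
  write_ascii_grid(m, tmp)
  back2 <- read_ascii_grid(tmp)
  expect_equal(back2$bands[[1]] == 1, m$values)
  expect_equal(back2$xll, 10)
})
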