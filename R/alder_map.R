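#' Fuse raster layers onto a common grid and standardize bands
#'
#' Emulates a multi-sensor fusion step: every layer is resampled onto the
#' grid of the first layer (bilinear interpolation for continuous bands,
#' nearest neighbour for categorical layers), the bands are concatenated,
#' each band is z-scored over its valid cells, and the union of the nodata
#' masks is applied. A band with zero variance standardizes to all zeros.
#'
#' @param layers list of [raster_stack()] objects with overlapping extents.
#' @param categorical logical vector, one entry per layer: resample that
#'   layer with nearest-neighbour instead of bilinear.
#' @return a standardized `raster_stack` on the first layer's grid.
#' @export
fuse_and_standardize <- function(layers, categorical = rep(FALSE, length(layers))) {
  if (length(layers) == 0) stop("no layers supplied", call. = FALSE)
  target <- layers[[1]]
  bands <- list()
  for (i in seq_along(layers)) {
    lay <- layers[[i]]
    if (!extents_overlap(target, lay)) {
      stop(sprintf("layer %d does not overlap the target grid", i),
           call. = FALSE)
    }
    res <- if (same_grid(target, lay)) lay$bands else
      lapply(lay$bands, function(b)
        resample_band(lay, b, target, nearest = categorical[i]))
    bands <- c(bands, res)
  }
  mask <- Reduce(`&`, lapply(bands, function(b) !is.na(b)))
  bands <- lapply(bands, function(b) {
    b[!mask] <- NA
    v <- b[mask]
    s <- stats::sd(v)
    b[mask] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    b
  })
  raster_stack(bands, res = target$res, xll = target$xll, yll = target$yll)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$res, a$xll, a$yll, a$nrow, a$ncol),
                   c(b$res, b$xll, b$yll, b$nrow, b$ncol)))
}

extents_overlap <- function(a, b) {
  ax <- c(a$xll, a$xll + a$ncol * a$res)
  ay <- c(a$yll, a$yll + a$nrow * a$res)
  bx <- c(b$xll, b$xll + b$ncol * b$res)
  by <- c(b$yll, b$yll + b$nrow * b$res)
  ax[1] < bx[2] && bx[1] < ax[2] && ay[1] < by[2] && by[1] < ay[2]
}

# resample one band of `src` onto the grid of `target`
resample_band <- function(src, band, target, nearest = FALSE) {
  ctr <- cell_centers(target)
  xg <- rep(ctr$x, each = target$nrow)
  yg <- rep(ctr$y, times = target$ncol)
  out <- if (nearest) {
    cells <- point_to_cell(src, xg, yg)
    ifelse(is.na(cells$row), NA_real_, band[cbind(cells$row, cells$col)])
  } else {
    bilinear_sample(src, band, xg, yg)
  }
  matrix(out, nrow = target$nrow, ncol = target$ncol)
}

bilinear_sample <- function(src, band, x, y) {
  sc <- cell_centers(src)
  xs <- sc$x                       # increasing
  ys <- rev(sc$y)                  # increasing
  bandr <- band[rev(seq_len(src$nrow)), , drop = FALSE]  # row 1 = south
  fx <- (x - xs[1]) / src$res
  fy <- (y - ys[1]) / src$res
  j0 <- pmin(pmax(floor(fx), 0), src$ncol - 2)
  i0 <- pmin(pmax(floor(fy), 0), src$nrow - 2)
  tx <- pmin(pmax(fx - j0, 0), 1)
  ty <- pmin(pmax(fy - i0, 0), 1)
  v00 <- bandr[cbind(i0 + 1, j0 + 1)]
  v01 <- bandr[cbind(i0 + 1, j0 + 2)]
  v10 <- bandr[cbind(i0 + 2, j0 + 1)]
  v11 <- bandr[cbind(i0 + 2, j0 + 2)]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  off <- x < xs[1] - src$res / 2 | x > xs[length(xs)] + src$res / 2 |
    y < ys[1] - src$res / 2 | y > ys[length(ys)] + src$res / 2
  out[off] <- NA
  out
}

#' Unsupervised k-means classification of a raster stack
#'
#' Clusters the valid cells of a fused, standardized stack into `k` spectral
#' clusters by Lloyd's algorithm with k-means++ initialization from a fixed
#' seed, so repeated runs with the same seed produce identical labels.
#'
#' @param stack a [raster_stack()].
#' @param k number of clusters (site analysis used 50).
#' @param seed integer RNG seed for the k-means++ initialization.
#' @param max_iter maximum Lloyd iterations.
#' @return list with `model` (a `cluster_model`: centroids, k, seed,
#'   inertia, iterations) and `labels`, an integer matrix of cluster ids
#'   (1..k) on the stack's grid, NA on nodata cells.
#' @export
kmeans_classify <- function(stack, k = 50, seed = 1, max_iter = 300) {
  mask <- valid_mask(stack)
  X <- vapply(stack$bands, function(b) b[mask], numeric(sum(mask)))
  if (!is.matrix(X)) X <- matrix(X, ncol = length(stack$bands))
  if (nrow(X) < k) stop("fewer valid cells than clusters", call. = FALSE)
  centers <- withr_seed(seed, kmeanspp_centers(X, k))
  km <- suppressWarnings(
    stats::kmeans(X, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd")
  )
  labels <- matrix(NA_integer_, stack$nrow, stack$ncol)
  labels[mask] <- km$cluster
  model <- structure(list(k = k, centroids = km$centers, seed = seed,
                          inertia = km$tot.withinss, iterations = km$iter),
                     class = "cluster_model")
  list(model = model,
       labels = structure(list(values = labels, res = stack$res,
                               xll = stack$xll, yll = stack$yll,
                               nrow = stack$nrow, ncol = stack$ncol),
                          class = "label_map"))
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    idx <- if (sum(d2) > 0) sample.int(n, 1, prob = d2 / sum(d2)) else
      sample.int(n, 1)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
  }
  # jitter exact duplicates so stats::kmeans accepts the initial centers
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(X), sd = 1e-8)
  }
  centers
}

#' Select clusters representing the target class from ground-truth points
#'
#' A cluster is selected as shrubland when it contains at least one
#' alder-labelled ground point and the fraction of alder points among the
#' ground points landing in it is at least `min_purity`. Points falling
#' outside the grid or on nodata cells are dropped with a warning.
#'
#' @param labels a `label_map` from [kmeans_classify()].
#' @param gt data frame of ground-truth points with columns `x`, `y`,
#'   `label` (\"alder\" or other).
#' @param min_purity minimum alder fraction (default 0.5).
#' @return integer vector of selected cluster ids.
#' @export
select_alder_clusters <- function(labels, gt, min_purity = 0.5) {
  cells <- point_to_cell(labels, gt$x, gt$y)
  cl <- ifelse(is.na(cells$row), NA_integer_,
               labels$values[cbind(cells$row, cells$col)])
  dropped <- sum(is.na(cl))
  if (dropped > 0) {
    warning(sprintf("%d ground point(s) outside the valid grid were dropped",
                    dropped), call. = FALSE)
  }
  ok <- !is.na(cl)
  cl <- cl[ok]
  lab <- gt$label[ok]
  if (!any(lab == "alder")) {
    stop("no usable alder-labelled ground points", call. = FALSE)
  }
  tab_all <- table(cl)
  tab_alder <- table(cl[lab == "alder"])
  ids <- as.integer(names(tab_alder))
  purity <- as.numeric(tab_alder) / as.numeric(tab_all[names(tab_alder)])
  sort(ids[purity >= min_purity])
}

#' Binary class map from selected cluster ids
#'
#' @param labels a `label_map`.
#' @param ids cluster ids to mark TRUE.
#' @return a [binary_class_map()].
#' @export
binary_map <- function(labels, ids) {
  seen <- unique(labels$values[!is.na(labels$values)])
  if (length(setdiff(ids, seen))) {
    stop("ids not present in the label map: ",
         paste(setdiff(ids, seen), collapse = ", "), call. = FALSE)
  }
  vals <- matrix(labels$values %in% ids, labels$nrow, labels$ncol)
  vals[is.na(labels$values)] <- NA
  binary_class_map(vals, res = labels$res, xll = labels$xll, yll = labels$yll)
}

#' Validate a binary map against ground-truth points
#'
#' @param map a [binary_class_map()].
#' @param gt ground-truth points (`x`, `y`, `label`); `label == "alder"` is
#'   the positive class.
#' @return list with the confusion counts (`tp`, `fp`, `fn`, `tn`),
#'   `accuracy`, `precision`, `recall` and `n_used`.
#' @export
validate_map <- function(map, gt) {
  cells <- point_to_cell(map, gt$x, gt$y)
  pred <- ifelse(is.na(cells$row), NA,
                 map$values[cbind(cells$row, cells$col)])
  ok <- !is.na(pred)
  if (!any(ok)) stop("no ground points fall on valid cells", call. = FALSE)
  pred <- pred[ok]
  truth <- gt$label[ok] == "alder"
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       n_used = tp + fp + fn + tn)
}

#' Mapped area of the positive class
#'
#' @param map a [binary_class_map()].
#' @return area in m^2 (positive cells x resolution^2).
#' @export
map_area <- function(map) {
  sum(map$values, na.rm = TRUE) * map$res^2
}
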