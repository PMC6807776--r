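# Independent oracles used across test files.

# point-to-rectangle distance built from point-to-segment distances over the
# four edges plus an inside test; structurally independent of the clamped
# formula used by distance_to_shrubland()
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  t <- ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)
  t <- min(max(t, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

oracle_point_rect_dist <- function(px, py, x0, y0, x1, y1) {
  if (px >= x0 && px <= x1 && py >= y0 && py <= y1) return(0)
  min(point_segment_dist(px, py, x0, y0, x1, y0),
      point_segment_dist(px, py, x1, y0, x1, y1),
      point_segment_dist(px, py, x1, y1, x0, y1),
      point_segment_dist(px, py, x0, y1, x0, y0))
}

oracle_distance_to_map <- function(px, py, map) {
  idx <- which(map$values, arr.ind = TRUE)
  best <- Inf
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, "row"]; j <- idx[r, "col"]
    x0 <- map$xll + (j - 1) * map$res
    y0 <- map$yll + (map$nrow - i) * map$res
    best <- min(best, oracle_point_rect_dist(px, py, x0, y0,
                                             x0 + map$res, y0 + map$res))
  }
  best
}

# brute-force area-weighted mean of zone means, written from the definition
oracle_weighted_zone_mean <- function(d_in, d_out, r_in, r_out) {
  a_in <- pi * r_in^2
  a_out <- pi * r_out^2 - a_in
  (mean(d_in) * a_in + mean(d_out) * a_out) / (a_in + a_out)
}

# unit-tracking tracer-rate oracle: converts every term explicitly
oracle_fixation_rate <- function(ape_pct, pct_n, time_h, headspace_pct) {
  mol_n_per_g <- (pct_n / 100) / 14.0067          # mol N per g nodule
  umol_n_per_g <- mol_n_per_g * 1e6
  ape_fraction <- ape_pct / 100
  headspace_fraction <- headspace_pct / 100
  (ape_fraction * umol_n_per_g) / (time_h * headspace_fraction)
}

# accuracy of a 2-class labelling against truth, up to label permutation
two_class_agreement <- function(labels, truth) {
  acc <- mean(labels == truth)
  max(acc, 1 - acc)
}
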