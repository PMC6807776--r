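#' Area-basis leaf nutrient content
#'
#' Converts a mass fraction (%) and specific leaf area (cm^2 g^-1) to an
#' area-basis content: (pct/100) x (1e4 / SLA) g m^-2 leaf.
#'
#' @param pct_x nutrient mass fraction, percent.
#' @param sla specific leaf area, cm^2 g^-1, > 0.
#' @return g of the element per m^2 leaf.
#' @examples
#' area_basis(2.33, 120.55)  # sun-leaf N_area, g N m^-2
#' @export
area_basis <- function(pct_x, sla) {
  if (any(sla <= 0, na.rm = TRUE)) stop("SLA must be > 0", call. = FALSE)
  (pct_x / 100) * (1e4 / sla)
}

#' Litter specific leaf area from green-leaf SLA
#'
#' Litter SLA is the canopy-mean green SLA corrected for dry-mass loss
#' during senescence: area is conserved while mass shrinks by
#' `mass_loss_frac`, so SLA_litter = mean(sun, shade) / (1 - mass_loss_frac).
#'
#' @param green_sun_sla,green_shade_sla green-leaf SLA, cm^2 g^-1, > 0.
#' @param mass_loss_frac fraction of dry mass lost during senescence
#'   (default 0.07).
#' @return litter SLA, cm^2 g^-1.
#' @examples
#' litter_sla(120.55, 160.6)  # 151.16 cm^2 g^-1
#' @export
litter_sla <- function(green_sun_sla, green_shade_sla, mass_loss_frac = 0.07) {
  if (any(green_sun_sla <= 0, na.rm = TRUE) ||
      any(green_shade_sla <= 0, na.rm = TRUE)) {
    stop("green-leaf SLA must be > 0", call. = FALSE)
  }
  if (any(mass_loss_frac < 0 | mass_loss_frac >= 1)) {
    stop("mass_loss_frac must be in [0, 1)", call. = FALSE)
  }
  (green_sun_sla + green_shade_sla) / 2 / (1 - mass_loss_frac)
}

#' Nutrient resorption efficiency during senescence
#'
#' Percent of area-basis leaf nutrient withdrawn before litterfall:
#' (1 - litter / green) x 100, with the green reference taken as the canopy
#' (sun + shade) mean area-basis content.
#'
#' @param green_area_mass canopy-mean green-leaf area-basis content,
#'   g m^-2, > 0 (pass `mean(area_basis(...))` of sun and shade).
#' @param litter_area_mass litter area-basis content, g m^-2.
#' @return resorption efficiency, percent.
#' @export
resorption_efficiency <- function(green_area_mass, litter_area_mass) {
  if (any(green_area_mass <= 0, na.rm = TRUE)) {
    stop("green-leaf area-basis content must be > 0", call. = FALSE)
  }
  (1 - litter_area_mass / green_area_mass) * 100
}

#' PCA of a trait matrix with bootstrapped eigenvector significance
#'
#' Eigendecomposition of the covariance matrix (no correlation scaling) of
#' a complete-case trait matrix, with nonparametric row-resampling bootstrap
#' of the eigenvectors. Each replicate's eigenvectors are sign-aligned to
#' the point estimate (by maximal dot product) before percentile intervals
#' are formed; a trait is significant on a component when the 95% interval
#' of its loading excludes zero.
#'
#' @param x numeric matrix or data frame, rows = individuals, columns =
#'   traits; rows with missing values are dropped.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `loadings` (eigenvectors, columns = PCs),
#'   `variance_fraction`, `sdev`, `ci_lower`/`ci_upper` (loading intervals),
#'   `significant` (logical matrix), `n` and `n_boot`.
#' @export
pca_bootstrap <- function(x, n_boot = 1000, seed = 1) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows", call. = FALSE)
  cv <- stats::cov(x)
  if (qr(cv)$rank < ncol(x)) {
    stop("trait covariance matrix is rank deficient", call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  load0 <- eg$vectors
  dimnames(load0) <- list(colnames(x), paste0("PC", seq_len(ncol(x))))
  boots <- withr_seed(seed, {
    arr <- array(NA_real_, c(ncol(x), ncol(x), n_boot))
    for (bi in seq_len(n_boot)) {
      xb <- x[sample.int(nrow(x), nrow(x), replace = TRUE), , drop = FALSE]
      eb <- tryCatch(eigen(stats::cov(xb), symmetric = TRUE)$vectors,
                     error = function(e) NULL)
      if (is.null(eb)) next
      # sign-align each replicate eigenvector to the point estimate
      for (j in seq_len(ncol(x))) {
        if (sum(eb[, j] * load0[, j]) < 0) eb[, j] <- -eb[, j]
      }
      arr[, , bi] <- eb
    }
    arr
  })
  ci_lower <- apply(boots, c(1, 2), stats::quantile, probs = 0.025,
                    na.rm = TRUE)
  ci_upper <- apply(boots, c(1, 2), stats::quantile, probs = 0.975,
                    na.rm = TRUE)
  dimnames(ci_lower) <- dimnames(ci_upper) <- dimnames(load0)
  list(loadings = load0,
       variance_fraction = eg$values / sum(eg$values),
       sdev = sqrt(pmax(eg$values, 0)),
       ci_lower = ci_lower, ci_upper = ci_upper,
       significant = ci_lower > 0 | ci_upper < 0,
       n = nrow(x), n_boot = n_boot)
}
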