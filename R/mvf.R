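# Mean-value fundus (en-face) projection.

#' Project one layer of an OCT volume to a mean-value fundus image
#'
#' Each en-face pixel is the mean of the A-scan samples lying between the
#' layer's two bounding interfaces. The axial samples included at
#' `(b, a)` are the 0-based depth indices in the half-open interval
#' `[ceil(upper), ceil(lower))`, so adjacent layers partition every
#' A-scan and no voxel is counted twice. Pixels whose layer contributes
#' fewer than `min_samples` samples are masked out (not zero-filled).
#'
#' @param volume An [oct_volume()].
#' @param bset A [boundary_set()] with matching en-face grid.
#' @param layer Layer name (see [layer_names()]).
#' @param min_samples Minimum axial samples for a pixel to be valid.
#' @return An object of class `mvf_image` with fields `values`
#'   (`n_bscans` x `n_ascans`, `NA` off-mask), `mask` (logical), `layer`,
#'   `n_samples`.
#' @export
project_mvf <- function(volume, bset, layer, min_samples = 1L) {
  stopifnot(inherits(volume, "oct_volume"), inherits(bset, "boundary_set"))
  d <- dim(bset$depths)
  if (d[2] != volume$n_bscans || d[3] != volume$n_ascans)
    stopf("boundary grid (%d x %d) does not match volume (%d x %d)",
          d[2], d[3], volume$n_bscans, volume$n_ascans)
  k <- match(layer, bset$layers)
  if (is.na(k)) stopf("unknown layer '%s'", layer)
  nb <- volume$n_bscans; na <- volume$n_ascans; nd <- volume$depth

  zs <- ceiling(bset$depths[k, , ])       # first 0-based depth index included
  ze <- ceiling(bset$depths[k + 1L, , ])  # first index excluded
  zs <- pmin(pmax(zs, 0), nd)
  ze <- pmin(pmax(ze, 0), nd)
  n_samp <- matrix(pmax(ze - zs, 0), nb, na)

  m <- matrix(aperm(volume$intensities, c(3, 1, 2)), nd, nb * na)
  cs <- rbind(0, apply(m, 2, cumsum))     # cs[z + 1, ] = sum of depths 0..z-1
  col <- seq_len(nb * na)
  sums <- cs[cbind(as.vector(ze) + 1L, col)] - cs[cbind(as.vector(zs) + 1L, col)]
  sums <- matrix(sums, nb, na)

  mask <- n_samp >= max(1L, min_samples)
  values <- ifelse(mask, sums / pmax(n_samp, 1L), NA_real_)
  structure(list(values = values, mask = mask, layer = layer,
                 n_samples = n_samp),
            class = "mvf_image")
}

#' @export
print.mvf_image <- function(x, ...) {
  cat(sprintf("<mvf_image> layer %s, %d x %d, %.1f%% valid\n",
              x$layer, nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Write an MVF image (and its mask) as 16-bit TIFF
#'
#' @param mvf An `mvf_image`.
#' @param path Output TIFF path; the validity mask is written alongside
#'   with suffix `_mask`.
#' @param vmax Intensity mapped to the top of the 16-bit range; defaults
#'   to the image maximum.
#' @return `path`, invisibly.
#' @export
write_mvf <- function(mvf, path, vmax = NULL) {
  stopifnot(inherits(mvf, "mvf_image"))
  v <- mvf$values
  v[!mvf$mask] <- 0
  vmax <- vmax %||% max(v, 1e-12)
  tiff::writeTIFF(pmin(v / vmax, 1), path, bits.per.sample = 16L,
                  compression = "none")
  mask_path <- sub("(\\.tiff?)$", "_mask\\1", path, ignore.case = TRUE)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask.tiff")
  tiff::writeTIFF(mvf$mask * 1, mask_path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}
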