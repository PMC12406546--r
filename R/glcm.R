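# Grey-level co-occurrence texture analysis.
#
# The texture of each mean-value fundus image is summarised by a masked,
# direction-averaged, symmetric grey-level co-occurrence matrix (GLCM):
# the empirical probability of observing the grey-level pair (A, B) at a
# fixed pixel offset. Twenty second-order features are computed from it:
# the thirteen Haralick features, autocorrelation and maximum probability,
# Conners' cluster shade and cluster prominence, Clausi's normalised
# inverse-difference features (INN, IDN), and Soh's dissimilarity.
# Logarithms are base 2 (entropies in bits), with 0 * log 0 := 0.

#' Default GLCM direction offsets
#'
#' The four standard unit offsets `(drow, dcol)` covering 0, 45, 90 and
#' 135 degrees; with a symmetric GLCM these capture all eight neighbour
#' directions.
#'
#' @return List of four integer 2-vectors.
#' @export
glcm_directions <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Quantize an image to integer grey levels
#'
#' Linear binning of the masked pixel values into `n_levels` equal-width
#' bins with 1-based level indices. Under `"minmax"` scaling the observed
#' minimum maps to level 1 and the maximum to level `n_levels`, which
#' makes all downstream GLCM features invariant to positive affine
#' transforms of the input intensities.
#'
#' @param img An `mvf_image`, or a numeric matrix (non-finite entries are
#'   masked out).
#' @param n_levels Number of grey levels `N_g >= 2`.
#' @param range_mode `"minmax"` (per image) or `"fixed"`.
#' @param range Length-2 `c(lo, hi)` when `range_mode = "fixed"`; values
#'   outside are clamped.
#' @return An object of class `quantized_image` with fields `levels`
#'   (integer matrix, `NA` off-mask), `mask`, `n_levels`.
#' @export
quantize <- function(img, n_levels = 64L, range_mode = c("minmax", "fixed"),
                     range = NULL) {
  range_mode <- match.arg(range_mode)
  if (n_levels < 2L) stopf("n_levels must be >= 2")
  if (inherits(img, "mvf_image")) {
    values <- img$values; mask <- img$mask
  } else {
    values <- as.matrix(img); mask <- is.finite(values)
  }
  v <- values[mask]
  if (range_mode == "minmax") {
    lo <- suppressWarnings(min(v)); hi <- suppressWarnings(max(v))
  } else {
    if (is.null(range) || length(range) != 2L || range[2] <= range[1])
      stopf("range_mode 'fixed' needs range = c(lo, hi) with hi > lo")
    lo <- range[1]; hi <- range[2]
    v <- pmin(pmax(v, lo), hi)
  }
  levels <- matrix(NA_integer_, nrow(values), ncol(values))
  if (length(v)) {
    if (hi > lo) {
      lv <- floor((v - lo) / (hi - lo) * n_levels) + 1L
      lv <- pmin(pmax(lv, 1L), n_levels)
    } else {
      lv <- rep(1L, length(v))  # constant image: single occupied level
    }
    levels[mask] <- as.integer(lv)
  }
  structure(list(levels = levels, mask = mask, n_levels = as.integer(n_levels)),
            class = "quantized_image")
}

#' Compute a masked grey-level co-occurrence matrix
#'
#' Counts co-occurring level pairs over every pixel pair whose endpoints
#' are both inside the mask, at offset `distance * direction`, summed
#' over all requested directions. With `symmetric = TRUE` the transposed
#' counts are added before normalisation, so each unordered pair
#' contributes in both orders.
#'
#' @param q A [quantize()]d image.
#' @param distance Pixel distance `d` (offset multiplier).
#' @param directions List of `(drow, dcol)` offsets; default
#'   [glcm_directions()].
#' @param symmetric Add the transpose before normalisation.
#' @return An object of class `glcm` with fields `p` (`N_g` x `N_g`
#'   probabilities summing to 1), `n_pairs` (ordered source pairs before
#'   symmetrisation; 0 flags a degenerate matrix), `distance`,
#'   `directions`, `symmetric`, `n_levels`.
#' @export
compute_glcm <- function(q, distance = 1L, directions = glcm_directions(),
                         symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  ng <- q$n_levels
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  counts <- matrix(0, ng, ng)
  n_pairs <- 0L
  for (dir in directions) {
    dr <- dir[1] * distance; dc <- dir[2] * distance
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1) || r1[1] > r1[length(r1)] ||
        c1[1] > c1[length(c1)]) next
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- a[ok]; j <- b[ok]
    tab <- tabulate(i + (j - 1L) * ng, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng)
    n_pairs <- n_pairs + length(i)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else counts
  structure(list(p = p, n_pairs = n_pairs, distance = distance,
                 directions = directions, symmetric = symmetric,
                 n_levels = ng),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d x %d, d = %d, %d direction(s), %s, %d pairs%s\n",
              x$n_levels, x$n_levels, x$distance, length(x$directions),
              if (x$symmetric) "symmetric" else "asymmetric", x$n_pairs,
              if (x$n_pairs == 0) " [degenerate]" else ""))
  invisible(x)
}

#' Marginal distributions and entropies of a GLCM
#'
#' Computes the row/column marginals, the diagonal sum and difference
#' distributions `p_sum(k) = sum_{i+j=k} p(i,j)` (k in 2..2N_g) and
#' `p_diff(k) = sum_{|i-j|=k} p(i,j)` (k in 0..N_g-1), the marginal
#' moments, and the entropies `HX`, `HY`, `HXY`, `HXY1`, `HXY2` (bits)
#' needed by the information measures of correlation.
#'
#' @param g A non-degenerate [compute_glcm()] result.
#' @return List with elements `p_x`, `p_y`, `p_sum`, `p_diff`, `mu_x`,
#'   `mu_y`, `sigma_x`, `sigma_y`, `HX`, `HY`, `HXY`, `HXY1`, `HXY2`.
#' @export
glcm_marginals <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (g$n_pairs == 0L) stopf("degenerate GLCM: no co-occurring pixel pairs")
  p <- g$p
  ng <- g$n_levels
  i <- seq_len(ng)
  p_x <- rowSums(p); p_y <- colSums(p)
  mu_x <- sum(i * p_x); mu_y <- sum(i * p_y)
  sigma_x <- sqrt(sum((i - mu_x)^2 * p_x))
  sigma_y <- sqrt(sum((i - mu_y)^2 * p_y))
  s <- as.vector(outer(i, i, "+"))
  dm <- as.vector(abs(outer(i, i, "-")))
  pv <- as.vector(p)
  p_sum <- as.vector(rowsum(pv, s))              # ordered by k = 2..2*ng
  names(p_sum) <- sort(unique(s))
  p_diff <- as.vector(rowsum(pv, dm))            # ordered by k = 0..ng-1
  names(p_diff) <- sort(unique(dm))
  pxpy <- outer(p_x, p_y)
  pos <- p > 0
  HXY1 <- -sum(p[pos] * log2(pxpy[pos]))
  list(p_x = p_x, p_y = p_y, p_sum = p_sum, p_diff = p_diff,
       mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
       HX = entropy_bits(p_x), HY = entropy_bits(p_y),
       HXY = entropy_bits(pv), HXY1 = HXY1, HXY2 = entropy_bits(pxpy))
}

#' Canonical names of the 20 texture features
#'
#' @return Character vector of the 20 feature keys in canonical order.
#' @export
texture_feature_names <- function() {
  c("angular_second_moment", "contrast", "correlation",
    "sum_of_squares_variance", "inverse_difference_moment",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "IMCI", "IMCII",
    "autocorrelation", "maximum_probability", "cluster_prominence",
    "cluster_shade", "INN", "IDN", "dissimilarity")
}

#' Compound literature aliases of the 20 features
#'
#' Several features circulate under compound names; the map below records
#' them (e.g. angular second moment is also called uniformity, energy or
#' homogeneity in part of the literature, while "homogeneity" most often
#' denotes the inverse difference moment).
#'
#' @return Named character vector keyed by canonical feature name.
#' @export
texture_feature_aliases <- function() {
  c(angular_second_moment = "angular second moment/uniformity/homogeneity",
    inverse_difference_moment = "inverse difference moment/energy/homogeneity (common usage)",
    contrast = "contrast/inertia",
    sum_of_squares_variance = "sum of squares: variance",
    IMCI = "information measure of correlation I",
    IMCII = "information measure of correlation II",
    INN = "inverse difference normalised",
    IDN = "inverse difference moment normalised")
}

#' Compute the 20 GLCM texture features
#'
#' Feature definitions, with `p(i, j)` the symmetric GLCM over 1-based
#' levels `i, j = 1..N_g` and marginals as in [glcm_marginals()]:
#' angular second moment `sum p^2`; contrast `sum (i-j)^2 p`; correlation
#' `(sum ij p - mu_x mu_y) / (sigma_x sigma_y)`; sum of squares
#' `sum (i - mu_x)^2 p`; inverse difference moment
#' `sum p / (1 + (i-j)^2)`; sum average `sum k p_sum(k)`; sum variance
#' (centred on the sum average); sum entropy; entropy; difference
#' variance (variance of `p_diff` about its own mean); difference
#' entropy; the information measures of correlation
#' `IMCI = (HXY - HXY1) / max(HX, HY)` and
#' `IMCII = sqrt(1 - exp(-2 (HXY2 - HXY)))`; autocorrelation `sum ij p`;
#' maximum probability; cluster prominence and cluster shade
#' (fourth/third moments of `i + j - mu_x - mu_y`); the normalised
#' inverse differences `INN = sum p / (1 + |i-j| / N_g)` and
#' `IDN = sum p / (1 + (i-j)^2 / N_g^2)`; and dissimilarity
#' `sum |i-j| p`.
#'
#' Degenerate conventions, chosen so a constant region yields a finite
#' vector: `correlation := 1` when `sigma_x * sigma_y = 0`, `IMCI := 0`
#' when `max(HX, HY) = 0`, and the `IMCII` radicand is clamped at 0.
#'
#' @param g A [compute_glcm()] result.
#' @param marginals Optional precomputed [glcm_marginals()].
#' @return Named numeric vector of the 20 features (class
#'   `texture_features`), all `NA` with attribute `degenerate = TRUE`
#'   when the GLCM has no pairs. The alias map is attached as attribute
#'   `aliases`.
#' @export
texture_features <- function(g, marginals = NULL) {
  stopifnot(inherits(g, "glcm"))
  nms <- texture_feature_names()
  if (g$n_pairs == 0L) {
    out <- stats::setNames(rep(NA_real_, length(nms)), nms)
    return(structure(out, degenerate = TRUE,
                     aliases = texture_feature_aliases(),
                     class = "texture_features"))
  }
  m <- marginals %||% glcm_marginals(g)
  p <- g$p
  ng <- g$n_levels
  idx <- seq_len(ng)
  I <- matrix(idx, ng, ng)
  J <- matrix(idx, ng, ng, byrow = TRUE)
  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)

  asm <- sum(p^2)
  contrast <- sum((I - J)^2 * p)
  autoc <- sum(I * J * p)
  correlation <- if (m$sigma_x * m$sigma_y == 0) 1 else
    (autoc - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  sos <- sum((I - m$mu_x)^2 * p)
  idm <- sum(p / (1 + (I - J)^2))
  sum_average <- sum(ks * m$p_sum)
  sum_variance <- sum((ks - sum_average)^2 * m$p_sum)
  sum_entropy <- entropy_bits(m$p_sum)
  ent <- m$HXY
  mu_d <- sum(kd * m$p_diff)
  diff_variance <- sum((kd - mu_d)^2 * m$p_diff)
  diff_entropy <- entropy_bits(m$p_diff)
  hmax <- max(m$HX, m$HY)
  imci <- if (hmax == 0) 0 else (m$HXY - m$HXY1) / hmax
  imcii <- sqrt(max(0, 1 - exp(-2 * (m$HXY2 - m$HXY))))
  cdev <- I + J - m$mu_x - m$mu_y
  out <- c(
    angular_second_moment = asm,
    contrast = contrast,
    correlation = correlation,
    sum_of_squares_variance = sos,
    inverse_difference_moment = idm,
    sum_average = sum_average,
    sum_variance = sum_variance,
    sum_entropy = sum_entropy,
    entropy = ent,
    difference_variance = diff_variance,
    difference_entropy = diff_entropy,
    IMCI = imci,
    IMCII = imcii,
    autocorrelation = autoc,
    maximum_probability = max(p),
    cluster_prominence = sum(cdev^4 * p),
    cluster_shade = sum(cdev^3 * p),
    INN = sum(p / (1 + abs(I - J) / ng)),
    IDN = sum(p / (1 + (I - J)^2 / ng^2)),
    dissimilarity = sum(abs(I - J) * p)
  )
  structure(out[nms], degenerate = FALSE,
            aliases = texture_feature_aliases(),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, digits = 4, ...) {
  if (isTRUE(attr(x, "degenerate"))) {
    cat("<texture_features> degenerate GLCM (no pixel pairs); all NA\n")
    return(invisible(x))
  }
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, digits))
  invisible(x)
}
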