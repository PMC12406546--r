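# Segmented interface surfaces, validation, and thickness measurement.

#' Construct a boundary set
#'
#' Seven ordered interface surfaces delimiting the six retinal layers.
#' Depths are stored in (possibly sub-pixel) 0-based depth pixels and must
#' be monotone non-decreasing across interfaces at every en-face position.
#'
#' @param depths Numeric array `(7, n_bscans, n_ascans)`.
#' @param layers Layer names in order; defaults to [layer_names()].
#' @param validate Check interface ordering on construction.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(depths, layers = layer_names(), validate = TRUE) {
  if (!is.array(depths) || length(dim(depths)) != 3L || dim(depths)[1] != 7L)
    stopf("depths must be a (7, n_bscans, n_ascans) array")
  if (length(layers) != 6L) stopf("exactly 7 interfaces define 6 layers")
  if (!all(is.finite(depths))) stopf("interface depths must be finite")
  bs <- structure(list(depths = depths, layers = as.character(layers)),
                  class = "boundary_set")
  if (validate) {
    rep <- validate_boundaries(bs)
    if (nrow(rep))
      stopf("interface ordering violated at %d en-face position(s); see validate_boundaries()",
            length(unique(paste(rep$bscan, rep$ascan))))
  }
  bs
}

#' @export
print.boundary_set <- function(x, ...) {
  d <- dim(x$depths)
  cat(sprintf("<boundary_set> 7 interfaces / 6 layers on a %d x %d grid\n",
              d[2], d[3]))
  invisible(x)
}

#' Validate interface ordering and depth range
#'
#' @param bset A [boundary_set()] (or raw depth array).
#' @param volume_depth Optional axial extent; when given, depths outside
#'   `[0, volume_depth)` are reported as range violations.
#' @return Data frame report with columns `bscan`, `ascan` (1-based),
#'   `interface` (0-based), `type` (`"ordering"` or `"range"`) and
#'   `detail`. Zero rows means the set is valid.
#' @export
validate_boundaries <- function(bset, volume_depth = NULL) {
  depths <- if (inherits(bset, "boundary_set")) bset$depths else bset
  rep <- list()
  for (k in 1:6) {
    bad <- which(depths[k + 1L, , , drop = FALSE] - depths[k, , , drop = FALSE] < 0,
                 arr.ind = TRUE)
    if (nrow(bad))
      rep[[length(rep) + 1L]] <- data.frame(
        bscan = bad[, 2], ascan = bad[, 3], interface = k,
        type = "ordering",
        detail = sprintf("interface %d above interface %d", k, k - 1L))
  }
  lo <- which(depths < 0, arr.ind = TRUE)
  if (nrow(lo))
    rep[[length(rep) + 1L]] <- data.frame(
      bscan = lo[, 2], ascan = lo[, 3], interface = lo[, 1] - 1L,
      type = "range", detail = "depth < 0")
  if (!is.null(volume_depth)) {
    hi <- which(depths >= volume_depth, arr.ind = TRUE)
    if (nrow(hi))
      rep[[length(rep) + 1L]] <- data.frame(
        bscan = hi[, 2], ascan = hi[, 3], interface = hi[, 1] - 1L,
        type = "range", detail = sprintf("depth >= %g", volume_depth))
  }
  if (!length(rep))
    return(data.frame(bscan = integer(), ascan = integer(),
                      interface = integer(), type = character(),
                      detail = character()))
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  out
}

#' Per-layer or total retinal thickness map
#'
#' Thickness at each en-face position is the distance between the layer's
#' bounding interfaces; the total retina is the distance between the first
#' and last interface, identically equal to the sum of the six layers.
#'
#' @param bset A [boundary_set()].
#' @param layer A layer name (see [layer_names()]) or `"total"`.
#' @param axial_scale Micrometres per depth pixel; `NULL` keeps pixels.
#' @return An object of class `thickness_map` with fields `values`
#'   (`n_bscans` x `n_ascans`), `layer` and `units` (`"px"` or `"um"`).
#' @export
thickness_map <- function(bset, layer = "total", axial_scale = NULL) {
  stopifnot(inherits(bset, "boundary_set"))
  if (identical(layer, "total")) {
    v <- bset$depths[7L, , ] - bset$depths[1L, , ]
  } else {
    k <- match(layer, bset$layers)
    if (is.na(k)) stopf("unknown layer '%s'", layer)
    v <- bset$depths[k + 1L, , ] - bset$depths[k, , ]
  }
  units <- "px"
  if (!is.null(axial_scale) && axial_scale != 1) {
    v <- v * axial_scale
    units <- "um"
  }
  v <- as.matrix(v)
  structure(list(values = v, layer = layer, units = units),
            class = "thickness_map")
}

#' Mean thickness over the scanned region
#'
#' Unweighted arithmetic mean over the full en-face grid.
#'
#' @param map A [thickness_map()].
#' @return Scalar mean thickness in the map's units.
#' @export
mean_thickness <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (!length(map$values)) stopf("empty thickness map")
  mean(map$values)
}

#' Percent of baseline
#'
#' Expresses a follow-up measurement as a percentage of the same animal's
#' baseline (week 0) value.
#'
#' @param value_t Follow-up value.
#' @param value_0 Baseline value; must be positive.
#' @return `100 * value_t / value_0`.
#' @export
percent_of_baseline <- function(value_t, value_0) {
  if (any(value_0 <= 0)) stopf("baseline value must be positive")
  100 * value_t / value_0
}

#' Gradient-based fallback segmentation of layered volumes
#'
#' A simple intensity-gradient segmenter for phantoms and other volumes
#' with axially layered contrast: the mean axial profile is smoothed and
#' its seven strongest gradient-magnitude peaks define candidate
#' interfaces, which are then refined per A-scan within a local window.
#' This is a deliberately simple stand-in for a learned retinal segmenter
#' and carries no claim about clinical segmentation quality.
#'
#' @param volume An [oct_volume()].
#' @param n_interfaces Number of interfaces to find (7).
#' @param axial_sigma Gaussian smoothing (px) applied along depth.
#' @param window Half-width (px) of the per-A-scan refinement search
#'   around each globally detected interface.
#' @return A [boundary_set()] passing [validate_boundaries()].
#' @export
fallback_segment <- function(volume, n_interfaces = 7L, axial_sigma = 2,
                             window = 4L) {
  stopifnot(inherits(volume, "oct_volume"))
  nb <- volume$n_bscans; na <- volume$n_ascans; nd <- volume$depth
  m <- matrix(aperm(volume$intensities, c(3, 1, 2)), nd, nb * na)
  k <- gaussian_smoother(nd, axial_sigma)
  prof <- k %*% rowMeans(m)
  g <- abs(diff(prof))
  if (max(g) <= 1e-9 * (mean(prof) + 1e-12))
    stopf("segmentation failure: volume has no axial contrast")
  n <- length(g)
  is_peak <- c(FALSE, g[2:(n - 1)] >= g[1:(n - 2)] & g[2:(n - 1)] > g[3:n], FALSE) |
    (seq_len(n) %in% c(1L, n) & g >= max(g) * 0.999)
  peaks <- which(is_peak & g > max(g) * 1e-3)
  if (length(peaks) < n_interfaces)
    stopf("segmentation failure: found %d gradient peaks, need %d (peak depths: %s)",
          length(peaks), n_interfaces,
          paste(utils::head(peaks, 10), collapse = ","))
  sel <- sort(peaks[order(g[peaks], decreasing = TRUE)][seq_len(n_interfaces)])
  # refine per A-scan: argmax of the smoothed gradient within +/- window
  sm <- k %*% m
  gm <- abs(sm[-1L, , drop = FALSE] - sm[-nd, , drop = FALSE])
  depths <- array(0, dim = c(n_interfaces, nb, na))
  for (i in seq_len(n_interfaces)) {
    lo <- max(1L, sel[i] - window); hi <- min(n, sel[i] + window)
    win <- gm[lo:hi, , drop = FALSE]
    arg <- max.col(t(win), ties.method = "first") + lo - 1L
    # gradient row r marks the transition between depth pixels r and r+1
    # (1-based), i.e. a sub-pixel interface at 0-based depth r - 0.5
    depths[i, , ] <- matrix(arg - 0.5, nb, na)
  }
  # enforce monotone ordering pixel-wise
  for (i in 2:n_interfaces)
    depths[i, , ] <- pmax(depths[i, , ], depths[i - 1L, , ])
  boundary_set(depths, validate = FALSE)
}
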