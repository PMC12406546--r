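# Volume and boundary I/O.
#
# Axis convention (fixed, logged by the reader): TIFF page index = B-scan
# index; within a page, rows = depth (axial) and columns = A-scans, unless
# `transpose = TRUE`. Depth increases from the inner (vitreal) surface
# outwards. All on-disk indices (boundary CSV) are 0-based; in-memory R
# arrays are 1-based.

#' Read an OCT volume from non-compressed TIFF
#'
#' Accepts either a multipage TIFF file or a directory of single-page
#' TIFFs (sorted by file name). Pages must be greyscale and share
#' dimensions; integer intensities are preserved losslessly.
#'
#' @param path Multipage TIFF file, or directory of TIFF pages.
#' @param meta Optional [animal_meta()].
#' @param axial_scale Micrometres per depth pixel (default 1).
#' @param transpose If `TRUE`, pages are interpreted as
#'   (rows = A-scans, columns = depth).
#' @param quiet Suppress the axis-convention message.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, meta = NULL, axial_scale = 1,
                        transpose = FALSE, quiet = TRUE) {
  if (!file.exists(path)) stopf("path not found: %s", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stopf("no TIFF files found in %s", path)
    pages <- unlist(lapply(files, tiff::readTIFF, all = TRUE, as.is = TRUE),
                    recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stopf("no TIFF pages read from %s", path)
  if (any(!vapply(pages, function(p) is.matrix(p) || length(dim(p)) == 2L,
                  logical(1))))
    stopf("non-greyscale TIFF page in %s (multi-channel pages unsupported)", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("TIFF pages in %s have mixed dimensions", path)
  if (transpose) pages <- lapply(pages, t)
  # page rows = depth, columns = A-scans -> array (bscan, ascan, depth)
  nb <- length(pages)
  nd <- nrow(pages[[1]]); na <- ncol(pages[[1]])
  vol <- array(0, dim = c(nb, na, nd))
  for (b in seq_len(nb)) vol[b, , ] <- t(pages[[b]])
  if (!quiet)
    message(sprintf(
      "read_volume: %d pages as B-scans; page rows = depth (%d), columns = A-scans (%d)%s",
      nb, nd, na, if (transpose) " [transposed]" else ""))
  oct_volume(vol, axial_scale = axial_scale, meta = meta)
}

#' Write an OCT volume as a non-compressed multipage TIFF
#'
#' Integer-valued intensities round-trip bit-exactly through
#' [read_volume()] at 8 or 16 bits per sample.
#'
#' @param volume An [oct_volume()].
#' @param path Output file path.
#' @param bits_per_sample 8 or 16; default picks 8 when all intensities
#'   fit, otherwise 16.
#' @param rescale If `TRUE`, linearly map intensities onto the full output
#'   range instead of erroring when they exceed it.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits_per_sample = NULL,
                         rescale = FALSE) {
  stopifnot(inherits(volume, "oct_volume"))
  x <- volume$intensities
  if (is.null(bits_per_sample))
    bits_per_sample <- if (max(x) <= 255 && !rescale) 8L else 16L
  if (!bits_per_sample %in% c(8L, 16L))
    stopf("bits_per_sample must be 8 or 16")
  vmax <- 2^bits_per_sample - 1
  if (rescale) {
    rng <- range(x)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * vmax else x * 0
  } else if (max(x) > vmax) {
    stopf("intensities exceed the %d-bit range [0, %d]; pass rescale = TRUE",
          bits_per_sample, vmax)
  }
  pages <- lapply(seq_len(volume$n_bscans),
                  function(b) t(x[b, , ]) / vmax)  # rows = depth
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

#' Read layer-interface boundaries from CSV
#'
#' The CSV schema is `interface_index` (0..6), `bscan`, `ascan` (0-based
#' en-face indices) and `depth_px` (possibly sub-pixel depth). Every
#' (interface, bscan, ascan) cell must be present.
#'
#' @param path CSV file.
#' @return A [boundary_set()].
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) stopf("path not found: %s", path)
  tab <- utils::read.csv(path)
  need <- c("interface_index", "bscan", "ascan", "depth_px")
  if (!all(need %in% names(tab)))
    stopf("boundary CSV must have columns %s", paste(need, collapse = ", "))
  ks <- sort(unique(tab$interface_index))
  if (!identical(as.integer(ks), 0:6))
    stopf("boundary table must cover interface_index 0..6 (found: %s)",
          paste(ks, collapse = ","))
  nb <- max(tab$bscan) + 1L
  na <- max(tab$ascan) + 1L
  if (nrow(tab) != 7L * nb * na)
    stopf("incomplete boundary table: expected %d rows for a %d x %d grid, got %d",
          7L * nb * na, nb, na, nrow(tab))
  depths <- array(NA_real_, dim = c(7L, nb, na))
  depths[cbind(tab$interface_index + 1L, tab$bscan + 1L, tab$ascan + 1L)] <-
    tab$depth_px
  if (anyNA(depths))
    stopf("incomplete boundary table: some (interface, bscan, ascan) cells missing")
  boundary_set(depths)
}

#' Write layer-interface boundaries to CSV
#'
#' @param bset A [boundary_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(bset, path) {
  stopifnot(inherits(bset, "boundary_set"))
  d <- dim(bset$depths)
  grid <- expand.grid(interface_index = 0:(d[1] - 1L),
                      bscan = 0:(d[2] - 1L),
                      ascan = 0:(d[3] - 1L))
  grid$depth_px <- as.vector(bset$depths)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A YAML file listing one entry per scan: `animal_id`, `group`, `week`,
#' `eye`, `volume` and `boundaries` paths (relative to the manifest), and
#' optionally `axial_scale`.
#'
#' @param path Manifest YAML file.
#' @return Data frame with one row per scan; paths resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- yaml::read_yaml(path)
  scans <- m$scans %||% m
  base <- dirname(normalizePath(path))
  rows <- lapply(scans, function(s) {
    data.frame(animal_id = s$animal_id, group = s$group,
               week = as.integer(s$week), eye = s$eye %||% "OD",
               volume = file.path(base, s$volume),
               boundaries = file.path(base, s$boundaries),
               axial_scale = as.numeric(s$axial_scale %||% 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("animal_id", "week")])
  if (any(dup))
    stopf("manifest has duplicate (animal_id, week) entries")
  out
}

#' Write a cohort manifest
#'
#' @param manifest Data frame as returned by [read_manifest()]; `volume`
#'   and `boundaries` should be relative to `path`'s directory.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  scans <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    list(animal_id = r$animal_id, group = r$group, week = r$week,
         eye = r$eye, volume = r$volume, boundaries = r$boundaries,
         axial_scale = r$axial_scale %||% 1)
  })
  yaml::write_yaml(list(scans = scans), path)
  invisible(path)
}
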