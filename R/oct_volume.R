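#' Canonical retinal layer names
#'
#' The six segmented retinal structures, ordered from the inner (vitreal)
#' to the outer retina: nerve fibre layer + ganglion cell layer complex,
#' inner plexiform layer, inner nuclear layer, outer plexiform layer,
#' outer nuclear layer, and photoreceptor inner/outer segments.
#'
#' @return Character vector of the six layer names.
#' @export
layer_names <- function() {
  c("NFL-GCL", "IPL", "INL", "OPL", "ONL", "IS/OS")
}

#' Animal metadata for one scan
#'
#' @param animal_id Character identifier, unique within a cohort.
#' @param group One of `"control"` or `"T2D"`.
#' @param week Study week, one of 0, 4, 8, 12.
#' @param eye Eye label; the study design images the right eye only.
#' @return An object of class `animal_meta`.
#' @export
animal_meta <- function(animal_id, group = c("control", "T2D"),
                        week = 0L, eye = "OD") {
  group <- match.arg(group)
  week <- as.integer(week)
  if (!week %in% c(0L, 4L, 8L, 12L))
    stopf("week must be one of 0, 4, 8, 12 (got %s)", week)
  structure(
    list(animal_id = as.character(animal_id), group = group,
         week = week, eye = eye),
    class = "animal_meta"
  )
}

#' Construct an OCT volume
#'
#' A volumetric OCT scan stored as a 3D array indexed
#' `(bscan, ascan, depth)`, with the depth axis increasing from the inner
#' (vitreal) surface towards the outer retina.
#'
#' @param intensities Numeric 3D array `(n_bscans, n_ascans, depth)`,
#'   finite and non-negative.
#' @param axial_scale Micrometres per depth pixel; the default 1 reports
#'   thickness in pixels.
#' @param meta Optional [animal_meta()].
#' @return An object of class `oct_volume` with fields `intensities`,
#'   `n_bscans`, `n_ascans`, `depth`, `axial_scale`, `meta`.
#' @export
oct_volume <- function(intensities, axial_scale = 1, meta = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stopf("intensities must be a 3D array (bscan, ascan, depth)")
  if (any(dim(intensities) < 1L))
    stopf("all three volume dimensions must be >= 1")
  if (!all(is.finite(intensities)))
    stopf("intensities must be finite")
  if (min(intensities) < 0)
    stopf("intensities must be non-negative")
  if (!is.null(meta) && !inherits(meta, "animal_meta"))
    stopf("meta must be an animal_meta object")
  d <- dim(intensities)
  structure(
    list(intensities = intensities,
         n_bscans = d[1L], n_ascans = d[2L], depth = d[3L],
         axial_scale = axial_scale, meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("<oct_volume> %d B-scans x %d A-scans x %d depth px",
              x$n_bscans, x$n_ascans, x$depth))
  if (!is.null(x$meta))
    cat(sprintf("  [%s, %s, week %d]",
                x$meta$animal_id, x$meta$group, x$meta$week))
  cat("\n")
  invisible(x)
}

#' @export
print.animal_meta <- function(x, ...) {
  cat(sprintf("<animal_meta> %s (%s), week %d, eye %s\n",
              x$animal_id, x$group, x$week, x$eye))
  invisible(x)
}
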