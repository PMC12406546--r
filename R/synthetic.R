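# Synthetic OCT phantoms and longitudinal two-group cohorts.
#
# Phantoms are stacks of smoothly undulating layer interfaces filled with
# multiplicative speckle: within each layer, intensity = mean reflectivity
# x a unit-mean speckle field whose first-order statistics (contrast =
# std/mean) and second-order statistics (lateral correlation length) are
# independently tunable -- exactly the two axes GLCM features measure.
# Cohorts add persistent animal-level random effects (so the baseline
# covariate is informative) and per (layer, week) group effects on
# thickness and texture. All generators are pure functions of their
# configuration and seed.

#' Correlated multiplicative speckle field
#'
#' Draws a unit-mean gamma white-noise field, smooths it laterally with a
#' Gaussian kernel of the requested correlation length, then re-scales it
#' to unit mean and the requested contrast (std/mean), clipping at zero.
#' The re-standardisation keeps the first-order contrast fixed while the
#' correlation length varies, so the two texture axes are decoupled.
#'
#' @param n_rows,n_cols Field dimensions.
#' @param contrast Target std/mean of the field; 0 gives a constant 1.
#' @param corr_len Lateral Gaussian correlation length in pixels; 0
#'   leaves the field white.
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @return `n_rows` x `n_cols` numeric matrix with mean 1.
#' @export
speckle_field <- function(n_rows, n_cols, contrast = 0.3, corr_len = 0,
                          seed = NULL) {
  gen <- function() {
    if (contrast <= 0) return(matrix(1, n_rows, n_cols))
    sh <- 1 / contrast^2
    s <- matrix(stats::rgamma(n_rows * n_cols, shape = sh, rate = sh),
                n_rows, n_cols)
    if (corr_len > 0) {
      s <- gaussian_smoother(n_rows, corr_len) %*% s %*%
        t(gaussian_smoother(n_cols, corr_len))
    }
    sd0 <- stats::sd(s)
    if (sd0 > 0) s <- 1 + (s - mean(s)) / sd0 * contrast
    pmax(s, 0)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Phantom configuration
#'
#' Geometry defaults follow the acquisition design of 512 B-scans of 512
#' A-scans x 1024 depth pixels; tests and simulations scale the geometry
#' down. Per-layer baseline thicknesses default to retina-like
#' proportions scaled to `depth`; reflectivities alternate bright/dark as
#' plexiform/nuclear layers do, so every interface carries axial
#' contrast.
#'
#' @param n_bscans,n_ascans,depth Volume geometry.
#' @param layers Data frame with columns `name`, `thickness` (px),
#'   `reflectivity`, `contrast`, `corr_len`; default described above.
#' @param margin_top Mean depth of the first interface (px).
#' @param background Reflectivity/contrast of the regions above and
#'   below the retina.
#' @param undulation_amplitude Std (px) of the smooth random surface
#'   added to all interfaces (rigid, so layer thickness stays exact).
#' @param undulation_cells Coarse grid size of the undulation surface.
#' @param bit_depth Intensity clamp (8 -> 0..255).
#' @param seed RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_bscans = 512L, n_ascans = 512L, depth = 1024L,
                           layers = NULL, margin_top = NULL,
                           background = list(above = 6, below = 10,
                                             contrast = 0.15, corr_len = 0),
                           undulation_amplitude = 2,
                           undulation_cells = 4L,
                           bit_depth = 8L, seed = 1L) {
  if (is.null(layers)) {
    sc <- depth / 1024
    layers <- data.frame(
      name = layer_names(),
      thickness = c(60, 110, 70, 40, 180, 90) * sc,
      reflectivity = c(100, 66, 33, 78, 27, 112),
      contrast = rep(0.3, 6),
      corr_len = rep(1.2, 6),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(layers) == 6L,
            all(c("name", "thickness", "reflectivity", "contrast",
                  "corr_len") %in% names(layers)))
  if (any(layers$thickness < 1)) stopf("layer thicknesses must be >= 1 px")
  if (any(layers$reflectivity <= 0)) stopf("reflectivities must be > 0")
  if (any(layers$corr_len < 0)) stopf("correlation lengths must be >= 0")
  margin_top <- margin_top %||% round(0.2 * depth)
  budget <- margin_top + sum(layers$thickness) + 4 * undulation_amplitude
  if (budget > depth)
    stopf("thickness budget (%.1f px incl. margin and undulation) exceeds depth %d",
          budget, depth)
  structure(list(n_bscans = as.integer(n_bscans),
                 n_ascans = as.integer(n_ascans), depth = as.integer(depth),
                 layers = layers, margin_top = margin_top,
                 background = background,
                 undulation_amplitude = undulation_amplitude,
                 undulation_cells = as.integer(undulation_cells),
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a speckle phantom with ground-truth boundaries
#'
#' All seven interfaces share one smooth random undulation surface, so
#' the configured per-layer thicknesses are reproduced exactly by
#' [thickness_map()] on the returned boundaries. Intensities are rounded
#' to the configured bit depth so phantoms round-trip losslessly through
#' TIFF.
#'
#' @param cfg A [phantom_config()].
#' @param intensities If `FALSE`, skip speckle synthesis and return
#'   `volume = NULL` with the boundaries only (fast path for
#'   thickness-only studies).
#' @param meta Optional [animal_meta()] attached to the volume.
#' @return List with elements `volume` ([oct_volume()] or `NULL`) and
#'   `boundaries` ([boundary_set()], exact ground truth).
#' @export
generate_phantom <- function(cfg, intensities = TRUE, meta = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  nb <- cfg$n_bscans; na <- cfg$n_ascans; nd <- cfg$depth
  with_seed(cfg$seed, {
    k <- cfg$undulation_cells + 1L
    und <- bilinear_upsample(matrix(stats::rnorm(k * k), k, k), nb, na)
    und <- (und - mean(und)) * cfg$undulation_amplitude
    depths <- array(0, dim = c(7L, nb, na))
    depths[1L, , ] <- cfg$margin_top + und
    for (i in 1:6)
      depths[i + 1L, , ] <- depths[i, , ] + cfg$layers$thickness[i]
    if (min(depths) < 0 || max(depths) >= nd)
      stopf("interfaces fall outside the axial range [0, %d)", nd)
    bset <- boundary_set(depths, layers = cfg$layers$name, validate = FALSE)
    if (!intensities)
      return(list(volume = NULL, boundaries = bset))

    refl <- c(cfg$background$above, cfg$layers$reflectivity,
              cfg$background$below)
    ctr <- c(cfg$background$contrast, cfg$layers$contrast,
             cfg$background$contrast)
    crl <- c(cfg$background$corr_len, cfg$layers$corr_len,
             cfg$background$corr_len)
    # cache lateral smoothers per correlation length
    smo <- new.env(parent = emptyenv())
    get_smoother <- function(n, sigma) {
      key <- sprintf("%d_%g", n, sigma)
      if (is.null(smo[[key]])) smo[[key]] <- gaussian_smoother(n, sigma)
      smo[[key]]
    }
    region_field <- function(r) {
      if (ctr[r] <= 0) return(matrix(1, nb, na))
      sh <- 1 / ctr[r]^2
      s <- matrix(stats::rgamma(nb * na, shape = sh, rate = sh), nb, na)
      if (crl[r] > 0)
        s <- get_smoother(nb, crl[r]) %*% s %*% t(get_smoother(na, crl[r]))
      sd0 <- stats::sd(s)
      if (sd0 > 0) s <- 1 + (s - mean(s)) / sd0 * ctr[r]
      pmax(s, 0)
    }
    cd <- lapply(1:7, function(i) ceiling(depths[i, , ]))
    vmax <- 2^cfg$bit_depth - 1
    vol <- array(0, dim = c(nb, na, nd))
    for (z0 in 0:(nd - 1L)) {
      reg <- matrix(1L, nb, na)
      for (i in 1:7) reg <- reg + (cd[[i]] <= z0)
      plane <- matrix(0, nb, na)
      for (r in unique(as.vector(reg))) {
        f <- region_field(r)
        sel <- reg == r
        plane[sel] <- refl[r] * f[sel]
      }
      vol[, , z0 + 1L] <- round(pmin(pmax(plane, 0), vmax))
    }
    list(volume = oct_volume(vol, meta = meta), boundaries = bset)
  })
}

#' Example longitudinal effect pattern for a T2D cohort
#'
#' A ready-made effect specification emulating early type-2-diabetic
#' retinal change: progressive thinning of the inner/outer layers at
#' weeks 4-12 (factors set to reported percent-of-baseline magnitudes of
#' a few percent to ~14%), an increased speckle correlation length in
#' the IPL, and a decreased correlation length in the photoreceptor
#' IS/OS, both from week 8.
#'
#' @return Effect list accepted by [cohort_config()].
#' @export
example_t2d_effects <- function() {
  list(
    thickness = list(
      "IPL" = c("8" = 0.954, "12" = 0.952),
      "INL" = c("4" = 0.937, "8" = 0.863, "12" = 0.860),
      "OPL" = c("8" = 0.967, "12" = 0.974),
      "ONL" = c("4" = 0.969, "8" = 0.935, "12" = 0.930),
      "IS/OS" = c("4" = 0.961, "8" = 0.905, "12" = 0.915)),
    corr_len = list(
      "IPL" = c("8" = 1.8, "12" = 1.8),
      "IS/OS" = c("8" = 0.55, "12" = 0.55)),
    contrast = list())
}

effect_factor <- function(effects, kind, layer, week) {
  f <- effects[[kind]][[layer]]
  if (is.null(f)) return(1)
  v <- unname(f[as.character(week)])
  if (length(v) != 1L || is.na(v)) 1 else v
}

#' Cohort configuration
#'
#' Defaults give the test-scale study: 10 animals per group, weeks
#' 0/4/8/12, 64 x 64 x 256 phantoms. Effects apply to the T2D group
#' only; week 0 is pre-induction and must not carry effects.
#'
#' @param n_control,n_t2d Animals per group.
#' @param weeks Study weeks (must include the baseline week 0).
#' @param phantom Base [phantom_config()] shared by all scans.
#' @param effects List with elements `thickness`, `corr_len`,
#'   `contrast`; each a per-layer named vector of multiplicative factors
#'   keyed by week (see [example_t2d_effects()]).
#' @param animal_sd Variability components: SDs of the persistent
#'   per-animal multipliers on layer thickness, correlation length
#'   (log scale), speckle contrast (log scale) and reflectivity
#'   (log scale), plus `thickness_scan`, the SD of the per-scan
#'   (week-level) thickness jitter emulating repositioning and
#'   segmentation variability.
#' @param seed Master seed; every scan seed derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 10L, n_t2d = 10L,
                          weeks = c(0L, 4L, 8L, 12L),
                          phantom = phantom_config(n_bscans = 64L,
                                                   n_ascans = 64L,
                                                   depth = 256L),
                          effects = list(thickness = list(),
                                         corr_len = list(),
                                         contrast = list()),
                          animal_sd = list(thickness = 0.03,
                                           corr_len = 0.10,
                                           contrast = 0.05,
                                           reflectivity = 0.05,
                                           thickness_scan = 0.01),
                          seed = 1L) {
  weeks <- sort(unique(as.integer(weeks)))
  if (!0L %in% weeks) stopf("weeks must include the baseline week 0")
  if (!all(weeks %in% c(0L, 4L, 8L, 12L)))
    stopf("weeks must be drawn from {0, 4, 8, 12}")
  for (kind in names(effects)) {
    for (ly in names(effects[[kind]])) {
      f <- effects[[kind]][[ly]]
      if (any(f <= 0)) stopf("effect factors must be > 0 (%s/%s)", kind, ly)
      if ("0" %in% names(f))
        stopf("week 0 is the pre-induction baseline and cannot carry effects")
      if (!ly %in% layer_names()) stopf("unknown layer '%s' in effects", ly)
    }
  }
  structure(list(n_control = as.integer(n_control),
                 n_t2d = as.integer(n_t2d), weeks = weeks,
                 phantom = phantom, effects = effects,
                 animal_sd = animal_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw the persistent per-animal multipliers and per-scan seeds.
cohort_plan <- function(cfg) {
  ids <- c(sprintf("C%02d", seq_len(cfg$n_control)),
           sprintf("D%02d", seq_len(cfg$n_t2d)))
  groups <- rep(c("control", "T2D"), c(cfg$n_control, cfg$n_t2d))
  n_scan <- length(ids) * length(cfg$weeks)
  with_seed(cfg$seed, {
    animals <- lapply(seq_along(ids), function(a) {
      list(id = ids[a], group = groups[a],
           thick_mult = pmax(stats::rnorm(6, 1, cfg$animal_sd$thickness), 0.5),
           corr_mult = exp(stats::rnorm(6, 0, cfg$animal_sd$corr_len)),
           contrast_mult = exp(stats::rnorm(6, 0, cfg$animal_sd$contrast)),
           refl_mult = exp(stats::rnorm(1, 0, cfg$animal_sd$reflectivity)))
    })
    seeds <- sample.int(.Machine$integer.max - 1L, n_scan)
    sd_scan <- cfg$animal_sd$thickness_scan %||% 0
    jitter <- matrix(pmax(stats::rnorm(n_scan * 6, 1, sd_scan), 0.5),
                     n_scan, 6)
    list(animals = animals, seeds = seeds, jitter = jitter)
  })
}

# Phantom config for one (animal, week) scan.
scan_phantom_config <- function(cfg, animal, week, seed,
                                jitter = rep(1, 6)) {
  ly <- cfg$phantom$layers
  t2d <- animal$group == "T2D"
  for (i in seq_len(6)) {
    nm <- ly$name[i]
    ef_t <- if (t2d) effect_factor(cfg$effects, "thickness", nm, week) else 1
    ef_c <- if (t2d) effect_factor(cfg$effects, "corr_len", nm, week) else 1
    ef_s <- if (t2d) effect_factor(cfg$effects, "contrast", nm, week) else 1
    ly$thickness[i] <- max(1, ly$thickness[i] * animal$thick_mult[i] *
                             jitter[i] * ef_t)
    ly$corr_len[i] <- ly$corr_len[i] * animal$corr_mult[i] * ef_c
    ly$contrast[i] <- ly$contrast[i] * animal$contrast_mult[i] * ef_s
    ly$reflectivity[i] <- ly$reflectivity[i] * animal$refl_mult
  }
  p <- cfg$phantom
  p$layers <- ly
  p$seed <- seed
  p
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' One phantom per animal per week. Animal-level multipliers on layer
#' thickness, texture and reflectivity persist across weeks (making the
#' baseline covariate informative); group x week effects are applied to
#' the T2D group per the configuration. With `dir` given, volumes are
#' written as non-compressed multipage TIFF, boundaries as CSV, and a
#' YAML manifest alongside; otherwise scans are kept in memory (use only
#' for small cohorts).
#'
#' @param cfg A [cohort_config()].
#' @param dir Optional output directory.
#' @param intensities Generate speckle volumes (`FALSE` = boundaries
#'   only, for thickness-only studies).
#' @return List with `manifest` (data frame: `animal_id`, `group`,
#'   `week`, `eye`, `volume`, `boundaries`), `scans` (named list of
#'   `volume`/`boundaries`/`meta`, `NULL` when writing to `dir`),
#'   `manifest_path`, and the `config`.
#' @export
generate_cohort <- function(cfg, dir = NULL, intensities = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  plan <- cohort_plan(cfg)
  write_out <- !is.null(dir)
  if (write_out) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); scans <- if (write_out) NULL else list()
  s <- 0L
  for (animal in plan$animals) for (wk in cfg$weeks) {
    s <- s + 1L
    meta <- animal_meta(animal$id, animal$group, wk)
    pcfg <- scan_phantom_config(cfg, animal, wk, plan$seeds[s],
                                plan$jitter[s, ])
    ph <- generate_phantom(pcfg, intensities = intensities, meta = meta)
    key <- sprintf("%s_w%02d", animal$id, wk)
    if (write_out) {
      vfile <- paste0(key, ".tiff"); bfile <- paste0(key, "_boundaries.csv")
      if (!is.null(ph$volume))
        write_volume(ph$volume, file.path(dir, vfile),
                     bits_per_sample = cfg$phantom$bit_depth)
      write_boundaries(ph$boundaries, file.path(dir, bfile))
      rows[[s]] <- data.frame(animal_id = animal$id, group = animal$group,
                              week = wk, eye = "OD",
                              volume = vfile, boundaries = bfile,
                              axial_scale = 1,
                              stringsAsFactors = FALSE)
    } else {
      scans[[key]] <- ph
      scans[[key]]$meta <- meta
      rows[[s]] <- data.frame(animal_id = animal$id, group = animal$group,
                              week = wk, eye = "OD",
                              volume = NA_character_,
                              boundaries = NA_character_,
                              axial_scale = 1,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- NULL
  if (write_out) {
    manifest_path <- file.path(dir, "manifest.yaml")
    write_manifest(manifest, manifest_path)
  }
  list(manifest = manifest, scans = scans, manifest_path = manifest_path,
       config = cfg)
}

#' Write the deterministic fixture suite
#'
#' Small plain-text/TIFF fixtures used throughout the test suite: a
#' constant 4x4x8 volume, an 8x8x32 axial-ramp volume (intensity = depth
#' index), an 8x8 checkerboard image, and a flat 7-interface
#' segmentation at depths 10..70 on a 4x4 grid. Regenerates
#' bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest of the written files (also saved as
#'   `fixtures.json` in `out_dir`).
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  const <- oct_volume(array(7, dim = c(4, 4, 8)))
  write_volume(const, file.path(out_dir, "constant_volume.tiff"),
               bits_per_sample = 8L)
  files <- c(files, "constant_volume.tiff")

  ramp <- oct_volume(array(rep(0:31, each = 64), dim = c(8, 8, 32)))
  write_volume(ramp, file.path(out_dir, "ramp_volume.tiff"),
               bits_per_sample = 8L)
  files <- c(files, "ramp_volume.tiff")

  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 * 255)
  tiff::writeTIFF(cb / 255, file.path(out_dir, "checkerboard.tiff"),
                  bits.per.sample = 8L, compression = "none")
  files <- c(files, "checkerboard.tiff")

  depths <- array(rep(seq(10, 70, by = 10), times = 16), dim = c(7, 4, 4))
  write_boundaries(boundary_set(depths),
                   file.path(out_dir, "flat_boundaries.csv"))
  files <- c(files, "flat_boundaries.csv")

  manifest <- data.frame(file = files,
                         md5 = vapply(file.path(out_dir, files),
                                      function(f) unname(tools::md5sum(f)),
                                      character(1)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "fixtures.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}
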