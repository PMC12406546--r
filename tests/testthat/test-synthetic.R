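small_cfg <- function(seed = 1, ...) {
  phantom_config(n_bscans = 32, n_ascans = 32, depth = 160, seed = seed, ...)
}

test_that("noise-free phantoms are piecewise constant with exact thickness", {
  cfg <- small_cfg(seed = 2)
  cfg$layers$contrast <- rep(0, 6)
  cfg$background$contrast <- 0
  cfg$undulation_amplitude <- 0
  ph <- generate_phantom(cfg)
  for (i in 1:6) {
    tm <- thickness_map(ph$boundaries, cfg$layers$name[i])
    expect_equal(unique(as.vector(tm$values)), cfg$layers$thickness[i])
    mvf <- project_mvf(ph$volume, ph$boundaries, cfg$layers$name[i])
    expect_equal(unique(as.vector(mvf$values)),
                 round(cfg$layers$reflectivity[i]))
  }
})

test_that("thickness ground truth is exact even with undulating interfaces", {
  cfg <- small_cfg(seed = 3)
  ph <- generate_phantom(cfg, intensities = FALSE)
  for (i in 1:6) {
    tm <- thickness_map(ph$boundaries, cfg$layers$name[i])
    expect_equal(max(abs(tm$values - cfg$layers$thickness[i])), 0)
  }
  expect_equal(nrow(validate_boundaries(ph$boundaries, cfg$depth)), 0L)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(small_cfg(seed = 7))
  b <- generate_phantom(small_cfg(seed = 7))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$boundaries$depths, b$boundaries$depths)
  c2 <- generate_phantom(small_cfg(seed = 8))
  expect_false(identical(a$volume$intensities, c2$volume$intensities))
})

test_that("per-layer voxel means track the configured reflectivity", {
  cfg <- phantom_config(n_bscans = 128, n_ascans = 128, depth = 256, seed = 9)
  ph <- generate_phantom(cfg)
  for (i in c(1, 3, 6)) {
    mvf <- project_mvf(ph$volume, ph$boundaries, cfg$layers$name[i])
    rel <- mean(mvf$values[mvf$mask]) / cfg$layers$reflectivity[i]
    expect_lt(abs(rel - 1), 0.02)
  }
})

test_that("speckle fields have the configured first-order statistics", {
  f <- speckle_field(128, 128, contrast = 0.4, corr_len = 2, seed = 5)
  # unit mean up to the zero-clipping of the deepest speckle troughs
  expect_equal(mean(f), 1, tolerance = 5e-3)
  expect_equal(sd(f) / mean(f), 0.4, tolerance = 0.02)
  expect_identical(f, speckle_field(128, 128, 0.4, 2, seed = 5))
  expect_equal(speckle_field(8, 8, contrast = 0, corr_len = 3),
               matrix(1, 8, 8))
})

test_that("configuration invariants are enforced", {
  fat <- data.frame(name = layer_names(), thickness = 20,
                    reflectivity = 100, contrast = 0.3, corr_len = 1)
  expect_error(phantom_config(32, 32, 64, layers = fat), "budget")
  expect_error(cohort_config(weeks = c(4, 8)), "baseline week 0")
  expect_error(cohort_config(effects = list(thickness = list(
    IPL = c("0" = 0.9)))), "week 0")
  expect_error(cohort_config(effects = list(thickness = list(
    IPL = c("8" = -1)))), "> 0")
  expect_error(cohort_config(effects = list(thickness = list(
    XXX = c("8" = 0.9)))), "unknown layer")
})

test_that("recovered thinning deepens monotonically with the injected effect", {
  pct_at <- function(factor, seed) {
    eff <- list(thickness = list(INL = c("8" = factor)),
                corr_len = list(), contrast = list())
    cfg <- cohort_config(n_control = 8, n_t2d = 8, weeks = c(0, 8),
                         effects = eff, seed = seed)
    tab <- simulate_cohort_table(cfg, intensities = FALSE)
    p <- tab[tab$measure == "thickness_pct" & tab$layer == "INL" &
               tab$group == "T2D", ]
    mean(p$value)
  }
  rec <- sapply(c(1.0, 0.95, 0.86), pct_at, seed = 44)
  expect_true(all(diff(rec) < 0))
  expect_equal(rec[1], 100, tolerance = 0.02)
  expect_equal(rec[3], 86, tolerance = 0.02)
})

test_that("cohorts write a readable manifest with lossless volumes", {
  d <- withr::local_tempdir()
  cfg <- cohort_config(n_control = 2, n_t2d = 2, weeks = c(0, 8),
                       phantom = small_cfg(seed = 12), seed = 13)
  coh <- generate_cohort(cfg, dir = d)
  expect_true(file.exists(coh$manifest_path))
  man <- read_manifest(coh$manifest_path)
  expect_equal(nrow(man), 8)
  expect_setequal(unique(man$group), c("control", "T2D"))
  vol <- read_volume(man$volume[1])
  expect_equal(dim(vol$intensities), c(32, 32, 160))
  bs <- read_boundaries(man$boundaries[1])
  expect_equal(nrow(validate_boundaries(bs, vol$depth)), 0L)

  # in-memory generation of the same cohort matches the files bit-exactly
  mem <- generate_cohort(cfg)
  key <- sprintf("%s_w%02d", man$animal_id[1], man$week[1])
  expect_identical(mem$scans[[key]]$volume$intensities, vol$intensities)
  # sub-pixel depths pass through decimal CSV text, so equality is to
  # formatting precision (integer depths round-trip bit-exactly)
  expect_equal(mem$scans[[key]]$boundaries$depths, bs$depths,
               tolerance = 1e-9)
})

test_that("the fixture suite regenerates bit-identically and as derived", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- make_fixture_suite(d1)
  m2 <- make_fixture_suite(d2)
  expect_equal(m1$md5, m2$md5)
  expect_true(all(file.exists(file.path(d1, m1$file))))

  cb <- tiff::readTIFF(file.path(d1, "checkerboard.tiff"), as.is = TRUE)
  g <- compute_glcm(quantize(cb, 2), directions = list(c(0, 1)))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  const <- read_volume(file.path(d1, "constant_volume.tiff"))
  expect_equal(unique(as.vector(const$intensities)), 7)

  ramp <- read_volume(file.path(d1, "ramp_volume.tiff"))
  expect_equal(as.vector(ramp$intensities[1, 1, ]), 0:31)

  bs <- read_boundaries(file.path(d1, "flat_boundaries.csv"))
  expect_equal(unique(as.vector(thickness_map(bs, "total")$values)), 60)
})
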