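# End-to-end orchestration: scans -> MVF -> texture/thickness -> statistics.

default_glcm_opts <- function(glcm = list()) {
  utils::modifyList(list(n_levels = 64L, distance = 1L,
                         directions = glcm_directions(),
                         range_mode = "minmax", symmetric = TRUE,
                         min_samples = 1L),
                    glcm)
}

#' Extract the 20 texture features for every layer of one scan
#'
#' Projects each requested layer to its mean-value fundus image,
#' quantizes it, builds the masked symmetric GLCM and computes the
#' 20-feature vector.
#'
#' @param volume An [oct_volume()].
#' @param bset A [boundary_set()].
#' @param layers Layers to process (default all six).
#' @param glcm Options list overriding the defaults `n_levels = 64`,
#'   `distance = 1`, four averaged directions, `range_mode = "minmax"`,
#'   `symmetric = TRUE`, `min_samples = 1`.
#' @return Data frame, one row per layer: `layer` plus the 20 feature
#'   columns.
#' @export
extract_features <- function(volume, bset, layers = NULL, glcm = list()) {
  opts <- default_glcm_opts(glcm)
  layers <- layers %||% bset$layers
  rows <- lapply(layers, function(ly) {
    mvf <- project_mvf(volume, bset, ly, min_samples = opts$min_samples)
    q <- quantize(mvf, n_levels = opts$n_levels,
                  range_mode = opts$range_mode, range = opts$range)
    g <- compute_glcm(q, distance = opts$distance,
                      directions = opts$directions,
                      symmetric = opts$symmetric)
    fv <- texture_features(g)
    cbind(data.frame(layer = ly, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv))))
  })
  do.call(rbind, rows)
}

#' Mean thickness of every layer and the total retina for one scan
#'
#' @param bset A [boundary_set()].
#' @param axial_scale Micrometres per depth pixel (`NULL` = pixels).
#' @return Data frame with columns `layer` (six layers plus `"total"`)
#'   and `mean_thickness`.
#' @export
scan_thickness <- function(bset, axial_scale = NULL) {
  lys <- c(bset$layers, "total")
  data.frame(layer = lys,
             mean_thickness = vapply(lys, function(ly)
               mean_thickness(thickness_map(bset, ly, axial_scale)),
               numeric(1)),
             stringsAsFactors = FALSE,
             row.names = NULL)
}

# Long-format measurement rows (features + thickness) for one scan.
scan_measurements <- function(volume, bset, meta, layers = NULL,
                              glcm = list(), axial_scale = NULL) {
  th <- scan_thickness(bset, axial_scale)
  rows <- data.frame(animal_id = meta$animal_id, group = meta$group,
                     week = meta$week, layer = th$layer,
                     measure = "thickness", value = th$mean_thickness,
                     stringsAsFactors = FALSE)
  if (!is.null(volume)) {
    ft <- extract_features(volume, bset, layers = layers, glcm = glcm)
    long <- do.call(rbind, lapply(texture_feature_names(), function(ms)
      data.frame(animal_id = meta$animal_id, group = meta$group,
                 week = meta$week, layer = ft$layer, measure = ms,
                 value = ft[[ms]], stringsAsFactors = FALSE)))
    rows <- rbind(rows, long)
  }
  rows
}

#' Append percent-of-baseline rows to a cohort table
#'
#' For each (animal, layer) with a baseline-week value, adds rows with
#' `measure = paste0(measure, "_pct")` holding
#' `100 * value_week / value_baseline`.
#'
#' @param table Long-format cohort table.
#' @param measure Source measure (default `"thickness"`).
#' @param baseline_week Baseline week (default 0).
#' @return The table with the percent rows appended.
#' @export
add_percent_of_baseline <- function(table, measure = "thickness",
                                    baseline_week = 0) {
  check_cohort_table(table)
  sub <- table[table$measure == measure, ]
  base <- sub[sub$week == baseline_week, c("animal_id", "layer", "value")]
  names(base)[3] <- "value_0"
  fol <- sub[sub$week != baseline_week, ]
  m <- merge(fol, base, by = c("animal_id", "layer"))
  if (!nrow(m)) return(table)
  m$value <- percent_of_baseline(m$value, m$value_0)
  m$measure <- paste0(measure, "_pct")
  m$value_0 <- NULL
  rbind(table, m[, names(table)])
}

#' Simulate a cohort and measure it, scan by scan
#'
#' Streams through a synthetic cohort without retaining the volumes:
#' each phantom is generated, measured (texture features + thickness)
#' and discarded, and the long cohort table is returned with
#' percent-of-baseline thickness appended. This is the memory-friendly
#' route for simulation studies.
#'
#' @param cfg A [cohort_config()].
#' @param layers Layers to process.
#' @param glcm GLCM options (see [extract_features()]).
#' @param intensities `FALSE` restricts the table to thickness
#'   measurements (no speckle synthesis).
#' @return Long-format cohort table.
#' @export
simulate_cohort_table <- function(cfg, layers = NULL, glcm = list(),
                                  intensities = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  plan <- cohort_plan(cfg)
  rows <- list(); s <- 0L
  for (animal in plan$animals) for (wk in cfg$weeks) {
    s <- s + 1L
    meta <- animal_meta(animal$id, animal$group, wk)
    pcfg <- scan_phantom_config(cfg, animal, wk, plan$seeds[s],
                                plan$jitter[s, ])
    ph <- generate_phantom(pcfg, intensities = intensities, meta = meta)
    rows[[s]] <- scan_measurements(ph$volume, ph$boundaries, meta,
                                   layers = layers, glcm = glcm)
  }
  add_percent_of_baseline(do.call(rbind, rows))
}

#' Run the full analysis pipeline
#'
#' Orchestrates manifest (or in-memory cohort) -> per-scan MVF
#' projection, texture features and thickness -> percent of baseline ->
#' group statistics (ANCOVA with baseline covariate for texture
#' endpoints, normality-gated two-sample tests for percent-of-baseline
#' thickness) -> descriptive summaries. Rerunning on identical inputs
#' reproduces identical tables.
#'
#' @param manifest Path to a cohort manifest YAML (see
#'   [read_manifest()]), or a cohort list from [generate_cohort()].
#' @param out_dir Optional output directory; when given, writes
#'   `features.csv` (GLCM settings echoed as `#` header lines),
#'   `thickness.csv`, `stats.csv`, `summary.csv` and
#'   `run_metadata.json`.
#' @param layers Layers to process (default all six).
#' @param glcm GLCM options (see [extract_features()]).
#' @param alpha Significance level.
#' @param baseline_week Baseline week for covariate adjustment and
#'   percent of baseline.
#' @param fdr Apply Benjamini-Hochberg across all tested cells.
#' @param strict Abort on any per-scan failure instead of skipping the
#'   scan with a warning.
#' @return List with `table` (long cohort table), `features` (wide
#'   per-scan feature rows), `thickness` (wide thickness rows), `stats`
#'   (StatResult rows) and `summary` (per-cell descriptives), invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, layers = NULL,
                         glcm = list(), alpha = 0.05, baseline_week = 0,
                         fdr = FALSE, strict = FALSE) {
  opts <- default_glcm_opts(glcm)
  feat_rows <- list(); th_rows <- list(); long_rows <- list()
  n_failed <- 0L

  process_scan <- function(volume, bset, meta, axial_scale = NULL) {
    ft <- if (!is.null(volume))
      extract_features(volume, bset, layers = layers, glcm = opts)
    th <- scan_thickness(bset, axial_scale)
    list(
      features = if (!is.null(volume))
        cbind(data.frame(animal_id = meta$animal_id, group = meta$group,
                         week = meta$week, stringsAsFactors = FALSE), ft),
      thickness = cbind(data.frame(animal_id = meta$animal_id,
                                   group = meta$group, week = meta$week,
                                   stringsAsFactors = FALSE), th),
      long = scan_measurements(volume, bset, meta, layers = layers,
                               glcm = opts, axial_scale = axial_scale))
  }

  if (is.character(manifest)) {
    man <- read_manifest(manifest)
    for (i in seq_len(nrow(man))) {
      r <- man[i, ]
      res <- tryCatch({
        meta <- animal_meta(r$animal_id, r$group, r$week, r$eye)
        vol <- read_volume(r$volume, meta = meta,
                           axial_scale = r$axial_scale)
        bset <- read_boundaries(r$boundaries)
        process_scan(vol, bset, meta, r$axial_scale)
      }, error = function(err) {
        if (strict)
          stopf("scan %s week %s failed: %s", r$animal_id, r$week,
                conditionMessage(err))
        warning(sprintf("skipping scan %s week %s: %s", r$animal_id,
                        r$week, conditionMessage(err)), call. = FALSE)
        NULL
      })
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      feat_rows[[length(feat_rows) + 1L]] <- res$features
      th_rows[[length(th_rows) + 1L]] <- res$thickness
      long_rows[[length(long_rows) + 1L]] <- res$long
    }
  } else if (is.list(manifest) && !is.null(manifest$scans)) {
    for (key in names(manifest$scans)) {
      sc <- manifest$scans[[key]]
      res <- process_scan(sc$volume, sc$boundaries, sc$meta)
      feat_rows[[length(feat_rows) + 1L]] <- res$features
      th_rows[[length(th_rows) + 1L]] <- res$thickness
      long_rows[[length(long_rows) + 1L]] <- res$long
    }
  } else if (is.list(manifest) && !is.null(manifest$manifest_path)) {
    return(run_pipeline(manifest$manifest_path, out_dir = out_dir,
                        layers = layers, glcm = glcm, alpha = alpha,
                        baseline_week = baseline_week, fdr = fdr,
                        strict = strict))
  } else {
    stopf("manifest must be a manifest path or a generate_cohort() result")
  }
  if (!length(long_rows)) stopf("no scans could be processed")

  table <- add_percent_of_baseline(do.call(rbind, long_rows),
                                   baseline_week = baseline_week)
  measures <- unique(table$measure)
  endpoints <- data.frame(
    measure = setdiff(measures, "thickness"),
    test = ifelse(setdiff(measures, "thickness") == "thickness_pct",
                  "gated", "ancova"),
    stringsAsFactors = FALSE)
  stats_tab <- suppressWarnings(
    run_full_comparison(table, endpoints, baseline_week = baseline_week,
                        alpha = alpha, fdr = fdr))
  summary_tab <- summarize_cohort(table)
  features <- if (length(feat_rows)) do.call(rbind, feat_rows)
  thickness <- do.call(rbind, th_rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(features)) {
      fpath <- file.path(out_dir, "features.csv")
      hdr <- sprintf(
        "# GLCM settings: n_levels=%d distance=%d directions=%s range_mode=%s symmetric=%s",
        opts$n_levels, opts$distance,
        paste(vapply(opts$directions, paste, "", collapse = ","),
              collapse = ";"),
        opts$range_mode, opts$symmetric)
      writeLines(hdr, fpath)
      suppressWarnings(utils::write.table(
        features, fpath, sep = ",", row.names = FALSE, append = TRUE,
        qmethod = "double"))
    }
    utils::write.csv(thickness, file.path(out_dir, "thickness.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    meta_json <- list(
      package = "octtexture",
      version = as.character(utils::packageVersion("octtexture")),
      glcm = list(n_levels = opts$n_levels, distance = opts$distance,
                  directions = opts$directions,
                  range_mode = opts$range_mode,
                  symmetric = opts$symmetric,
                  min_samples = opts$min_samples),
      alpha = alpha, baseline_week = baseline_week, fdr = fdr,
      n_scans = length(long_rows), n_failed = n_failed,
      n_tests = nrow(stats_tab))
    jsonlite::write_json(meta_json, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out <- list(table = table, features = features, thickness = thickness,
              stats = stats_tab, summary = summary_tab,
              n_failed = n_failed)
  if (is.null(out_dir)) out else invisible(out)
}
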