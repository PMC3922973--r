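## Run configuration and the end-to-end pipeline
## (simulate -> detect -> evaluate -> report).

default_run_config <- function() {
  list(
    simulation = list(),          # passed to simulation_config(); NULL to read
    scene = NULL,                 # scene base path when not simulating
    reference = NULL,             # annotation path when not simulating
    methods = c("threshold_band5", "threshold_pan", "kmeans", "isodata"),
    detection = list(threshold = NULL, connectivity = 8, k = 5,
                     min_len_m = 5, max_len_m = 16, max_aspect = 6,
                     min_pixels = 2, weak_contrast_sigma = 2,
                     candidate_k_sd = 2),
    match_radius_m = 10,
    out_dir = "whalesat_run",
    seed = 1L,
    verbosity = 1L)
}

#' Validate a run configuration
#'
#' Takes a parsed JSON/YAML document (a plain list), fills defaults,
#' rejects unknown keys and reports all problems at once.
#'
#' @param document named list; an empty list yields the all-defaults config.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(document = list()) {
  defaults <- default_run_config()
  errs <- character(0)
  unknown <- setdiff(names(document), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, document[setdiff(names(document), unknown)],
                    keep.null = TRUE)

  if (!is.null(cfg$simulation)) {
    sim_keys <- names(formals(simulation_config))
    bad <- setdiff(names(cfg$simulation), sim_keys)
    if (length(bad))
      errs <- c(errs, paste0("unknown simulation key(s): ",
                             paste(bad, collapse = ", ")))
    for (key in c("n_whales", "n_seabird_clusters", "n_bubble_slicks",
                  "n_boats", "n_rocks")) {
      v <- cfg$simulation[[key]]
      if (!is.null(v) && (!is.numeric(v) || v < 0))
        errs <- c(errs, paste0("simulation$", key, " must be >= 0"))
    }
  } else {
    if (is.null(cfg$scene))
      errs <- c(errs, "either 'simulation' or 'scene' must be given")
  }
  known_methods <- c("threshold_band5", "threshold_pan", "kmeans",
                     "isodata", "maxlike")
  bad_m <- setdiff(cfg$methods, known_methods)
  if (length(bad_m))
    errs <- c(errs, paste0("unknown method(s): ", paste(bad_m, collapse = ", ")))
  if (!is.numeric(cfg$match_radius_m) || cfg$match_radius_m <= 0)
    errs <- c(errs, "match_radius_m must be > 0")
  if (!is.numeric(cfg$seed)) errs <- c(errs, "seed must be an integer")
  bad_d <- setdiff(names(cfg$detection), names(defaults$detection))
  if (length(bad_d))
    errs <- c(errs, paste0("unknown detection key(s): ",
                           paste(bad_d, collapse = ", ")))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return Object of class `run_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  validate_config(doc)
}

## ---- detection IO ----------------------------------------------------------

detection_csv_cols <- c("id", "grid", "n_pixels", "centroid_x_m",
                        "centroid_y_m", "area_m2", "major_axis_m",
                        "minor_axis_m", "orientation_rad", "mean_dn",
                        "contrast_sigma", "source", "detection_class")

#' Write / read detections
#'
#' GeoJSON (`.geojson`/`.json`): one feature per detection with the
#' polygonized pixel set as geometry when a scene is supplied (convex hull
#' of the pixel outlines), otherwise a point at the centroid; shape
#' measures, per-grid provenance and the detection class travel as
#' properties. CSV: the summary table without pixel geometry.
#'
#' @param detections a `whale_detections` data.frame.
#' @param path output path (format by extension).
#' @param scene optional `multiband_scene`, enables polygon geometry.
#' @return `read_detections` returns a `whale_detections` data.frame
#'   (without pixel sets).
#' @export
write_detections <- function(detections, path, scene = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(detections)[, detection_csv_cols, drop = FALSE]
  if (ext == "csv") {
    write.csv(df, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  if (!(ext %in% c("geojson", "json")))
    stop("unsupported detections format: .", ext)
  features <- lapply(seq_len(nrow(detections)), function(i) {
    props <- as.list(df[i, ])
    geom <- if (!is.null(scene)) {
      px <- detections$pixels[[i]]
      gsd <- band_gsd(scene, if (df$grid[i] == "pan") "pan" else 1)
      # corners of every member pixel, hulled
      cx <- scene$origin_xy_m[1] + c(px[, 2], px[, 2] + 1, px[, 2],
                                     px[, 2] + 1) * gsd
      cy <- scene$origin_xy_m[2] - c(px[, 1], px[, 1], px[, 1] + 1,
                                     px[, 1] + 1) * gsd
      h <- chull(cx, cy)
      ring <- cbind(cx[h], cy[h])
      ring <- rbind(ring, ring[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(k) ring[k, ])))
    } else {
      list(type = "Point",
           coordinates = c(df$centroid_x_m[i], df$centroid_y_m[i]))
    }
    list(type = "Feature", geometry = geom,
         properties = lapply(props, function(v) if (is.na(v)) NULL else v))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    fc <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(fc$features, function(f) {
      pr <- f$properties
      as.data.frame(lapply(stats::setNames(detection_csv_cols,
                                           detection_csv_cols),
                           function(k) if (is.null(pr[[k]])) NA else pr[[k]]),
                    stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(empty_detections())[detection_csv_cols]
  }
  df$pixels <- rep(list(NULL), nrow(df))
  class(df) <- c("whale_detections", "data.frame")
  df
}

## ---- pipeline --------------------------------------------------------------

stage <- function(name, expr, verbosity = 1) {
  if (verbosity > 0) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' simulate (or load) a scene, run every configured detection method,
#' evaluate against the reference, and write the comparison report. All
#' artifacts land in `config$out_dir` together with a manifest from which
#' the run is reproducible.
#'
#' @param config a `run_config` from [validate_config()], or a plain list
#'   that will be validated.
#' @return Invisibly, a list with the scene, reference, per-method
#'   detections and metrics, and the report.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  verb <- config$verbosity

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- config$seed
    sim <- stage("simulate", {
      simcfg <- do.call(simulation_config, sim_args)
      simulate_scene(simcfg)
    }, verb)
    scene <- sim$scene
    truth <- sim$truth
    stage("write-scene", {
      write_scene(scene, file.path(config$out_dir, "scene"))
      write_annotations(truth$annotations,
                        file.path(config$out_dir, "truth.geojson"))
    }, verb)
    reference <- truth_reference(truth)
  } else {
    scene <- stage("read-scene", read_scene(config$scene), verb)
    truth <- NULL
    reference <- stage("read-reference", {
      if (is.null(config$reference)) stop("no reference annotations given")
      read_annotations(config$reference)
    }, verb)
  }

  detections <- list(); metrics <- list(); thresholds <- list()
  for (m in config$methods) {
    det <- stage(paste0("detect-", m), {
      d <- config$detection
      detect_whales(scene, method = m, threshold = d$threshold,
                    connectivity = d$connectivity, k = d$k,
                    truth = truth, match_radius_m = config$match_radius_m,
                    min_len_m = d$min_len_m, max_len_m = d$max_len_m,
                    max_aspect = d$max_aspect, min_pixels = d$min_pixels,
                    weak_contrast_sigma = d$weak_contrast_sigma,
                    candidate_k_sd = d$candidate_k_sd)
    }, verb)
    detections[[m]] <- det
    thresholds[[m]] <- attr(det, "threshold_dn")
    stage(paste0("write-detections-", m), {
      write_detections(det, file.path(config$out_dir,
                                      paste0("detections_", m, ".geojson")),
                       scene = scene)
      write_detections(det, file.path(config$out_dir,
                                      paste0("detections_", m, ".csv")))
    }, verb)
    metrics[[m]] <- stage(paste0("evaluate-", m), {
      mt <- match_detections(det, reference, config$match_radius_m)
      compute_metrics(confusion_counts(mt, reference, method = m))
    }, verb)
  }

  report <- stage("report", {
    rep <- table1_report(metrics, csv_path = file.path(config$out_dir,
                                                       "report.csv"))
    txt <- utils::capture.output(print(rep))
    writeLines(txt, file.path(config$out_dir, "report.txt"))
    rep
  }, verb)

  stage("manifest", {
    manifest <- list(
      package = "whalesat",
      version = as.character(utils::packageVersion("whalesat")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = unclass(config),
      thresholds = thresholds,
      metrics = lapply(metrics, function(m)
        m[c("total_found", "pct_found", "pct_of_probable", "total_missed",
            "pct_missed", "pct_false_positives", "pct_good")]))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }, verb)

  invisible(list(scene = scene, truth = truth, reference = reference,
                 detections = detections, metrics = metrics,
                 report = report))
}
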