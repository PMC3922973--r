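## Scene data model: dual-resolution multiband rasters and reference
## annotations.
##
## Raster convention used throughout the package: 0-based (row, col),
## origin at the upper-left corner of the scene, pixel-centre registration,
## row increasing southward (world y decreasing), col increasing eastward
## (world x increasing). World coordinates are metres in a local frame.

#' WorldView2-style band table
#'
#' Returns the band table assumed by the package: eight multispectral (MS)
#' bands at `ms_gsd_m` ground sample distance plus one panchromatic band at
#' a quarter of that. Band 5 is the coastal band (400–450 nm), the far-blue
#' band that penetrates the water column; band 1 is red and band 8 is NIR2,
#' matching the 1-8-5 false-colour display convention for whale imagery.
#' The remaining wavelength ranges follow the standard WorldView2 band set;
#' only those three band roles are load-bearing for detection.
#'
#' @param ms_gsd_m ground sample distance of the multispectral bands, metres.
#' @param pan_gsd_m ground sample distance of the panchromatic band, metres;
#'   must be `ms_gsd_m / 4`.
#' @return A data.frame with columns `band` ("1".."8", "pan"), `name`,
#'   `wavelength_lo_nm`, `wavelength_hi_nm`, `gsd_m`.
#' @export
#' @examples
#' wv2_band_specs()
wv2_band_specs <- function(ms_gsd_m = 2, pan_gsd_m = ms_gsd_m / 4) {
  if (!isTRUE(all.equal(ms_gsd_m, 4 * pan_gsd_m)))
    stop("band spec incomplete: multispectral gsd must be 4x the panchromatic gsd")
  data.frame(
    band = c(as.character(1:8), "pan"),
    name = c("red", "blue", "green", "yellow", "coastal",
             "red_edge", "nir1", "nir2", "pan"),
    wavelength_lo_nm = c(630, 450, 510, 585, 400, 705, 770, 860, 450),
    wavelength_hi_nm = c(690, 510, 580, 625, 450, 745, 895, 1040, 800),
    gsd_m = c(rep(ms_gsd_m, 8), pan_gsd_m),
    stringsAsFactors = FALSE
  )
}

#' Detection class vocabulary
#'
#' The three manual classes used for digitized whale-like features:
#' `probable` (whale-shaped and whale-sized), `possible` (weaker signals,
#' bubble slicks, some seabird groups), and `band5_only` (features visible
#' only in the water-penetrating coastal band).
#' @export
detection_classes <- function() c("probable", "possible", "band5_only")

#' Construct a dual-resolution multiband scene
#'
#' Bundles eight multispectral digital-number (DN) grids, one panchromatic
#' grid at 4x linear resolution, and the georeferencing needed to move
#' between world metres and pixels.
#'
#' @param ms numeric array `rows x cols x 8` of DN values.
#' @param pan numeric matrix, exactly `4*rows x 4*cols`.
#' @param origin_xy_m world coordinates (x, y) of the scene's upper-left
#'   corner, metres.
#' @param band_specs band table as from [wv2_band_specs()].
#' @param dn_max maximum representable DN (default 2047, 11-bit radiometry).
#' @return An object of class `multiband_scene`.
#' @export
multiband_scene <- function(ms, pan, origin_xy_m = c(0, 0),
                            band_specs = wv2_band_specs(), dn_max = 2047) {
  if (length(dim(ms)) != 3L || dim(ms)[3] != 8L)
    stop("band spec incomplete: 'ms' must be a rows x cols x 8 array")
  if (!is.matrix(pan))
    stop("resolution mismatch: 'pan' must be a matrix")
  if (!identical(dim(pan), 4L * dim(ms)[1:2]))
    stop(sprintf("resolution mismatch: pan grid is %d x %d but must be 4x the MS grid (%d x %d)",
                 nrow(pan), ncol(pan), dim(ms)[1], dim(ms)[2]))
  req <- c("band", "name", "wavelength_lo_nm", "wavelength_hi_nm", "gsd_m")
  if (!is.data.frame(band_specs) || !all(req %in% names(band_specs)) ||
      nrow(band_specs) != 9L)
    stop("band spec incomplete: band table needs 9 rows and columns ",
         paste(req, collapse = ", "))
  rng <- range(ms, pan)
  if (rng[1] < 0 || rng[2] > dn_max)
    stop(sprintf("DN values outside [0, %d]", dn_max))
  structure(
    list(ms = ms, pan = pan, origin_xy_m = as.numeric(origin_xy_m),
         band_specs = band_specs, dn_max = dn_max),
    class = "multiband_scene"
  )
}

#' @export
print.multiband_scene <- function(x, ...) {
  d <- dim(x$ms)
  cat("<multiband_scene>\n")
  cat(sprintf("  MS grid : %d x %d px at %.2g m (8 bands)\n", d[1], d[2], ms_gsd(x)))
  cat(sprintf("  pan grid: %d x %d px at %.2g m\n", nrow(x$pan), ncol(x$pan), pan_gsd(x)))
  cat(sprintf("  extent  : %.0f x %.0f m, origin (%.1f, %.1f)\n",
              d[2] * ms_gsd(x), d[1] * ms_gsd(x),
              x$origin_xy_m[1], x$origin_xy_m[2]))
  cat(sprintf("  DN range: 0..%d (observed %d..%d)\n", x$dn_max,
              round(min(x$ms, x$pan)), round(max(x$ms, x$pan))))
  invisible(x)
}

#' Display one band of a scene
#'
#' @param x a `multiband_scene`.
#' @param band band selector as in [scene_band()].
#' @param ... passed to [graphics::image()].
#' @export
plot.multiband_scene <- function(x, band = "pan", ...) {
  g <- scene_band(x, band)
  # transpose/flip so the image displays north-up
  image(t(g[nrow(g):1, , drop = FALSE]), col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = nrow(g) / ncol(g),
        main = sprintf("band %s", as.character(band)), ...)
  invisible(x)
}

ms_gsd  <- function(scene) scene$band_specs$gsd_m[1]
pan_gsd <- function(scene) scene$band_specs$gsd_m[scene$band_specs$band == "pan"]

#' Extract one band grid from a scene
#'
#' @param scene a `multiband_scene`.
#' @param band 1–8, `"pan"`, or `"coastal"` (alias for band 5).
#' @return The DN matrix of that band, on its own grid.
#' @export
scene_band <- function(scene, band) {
  if (identical(band, "pan")) return(scene$pan)
  if (identical(band, "coastal")) band <- 5
  b <- as.integer(band)
  if (is.na(b) || b < 1 || b > 8) stop("unknown band: ", band)
  scene$ms[, , b]
}

#' @rdname scene_band
#' @export
band_gsd <- function(scene, band) {
  if (identical(band, "pan")) pan_gsd(scene) else ms_gsd(scene)
}

#' Scene extent in world coordinates
#'
#' MS and pan grids cover the identical extent.
#' @param scene a `multiband_scene`.
#' @return Named vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
scene_extent <- function(scene) {
  d <- dim(scene$ms)
  w <- d[2] * ms_gsd(scene)
  h <- d[1] * ms_gsd(scene)
  c(xmin = scene$origin_xy_m[1], xmax = scene$origin_xy_m[1] + w,
    ymin = scene$origin_xy_m[2] - h, ymax = scene$origin_xy_m[2])
}

#' Convert world coordinates to pixel indices and back
#'
#' `world_to_pixel()` returns the 0-based (row, col) of the pixel containing
#' each point; `pixel_to_world()` returns pixel-centre world coordinates.
#' The two compose to within half a ground sample distance.
#'
#' @param scene a `multiband_scene`.
#' @param xy_m numeric vector `c(x, y)` or an `n x 2` matrix, metres.
#' @param grid `"ms"` or `"pan"`.
#' @return `world_to_pixel`: an `n x 2` matrix of 0-based (row, col);
#'   `pixel_to_world`: an `n x 2` matrix of (x, y) metres.
#' @export
world_to_pixel <- function(scene, xy_m, grid = c("ms", "pan")) {
  grid <- match.arg(grid)
  xy <- if (is.matrix(xy_m)) xy_m else matrix(xy_m, ncol = 2)
  gsd <- if (grid == "ms") ms_gsd(scene) else pan_gsd(scene)
  ext <- scene_extent(scene)
  if (any(xy[, 1] < ext["xmin"] | xy[, 1] > ext["xmax"] |
          xy[, 2] < ext["ymin"] | xy[, 2] > ext["ymax"]))
    stop("outside scene")
  col <- floor((xy[, 1] - scene$origin_xy_m[1]) / gsd)
  row <- floor((scene$origin_xy_m[2] - xy[, 2]) / gsd)
  nd <- if (grid == "ms") dim(scene$ms)[1:2] else dim(scene$pan)
  # points exactly on the lower/right edge belong to the last pixel
  row <- pmin(row, nd[1] - 1)
  col <- pmin(col, nd[2] - 1)
  cbind(row = row, col = col)
}

#' @rdname world_to_pixel
#' @param rowcol numeric vector `c(row, col)` or an `n x 2` matrix, 0-based.
#' @export
pixel_to_world <- function(scene, rowcol, grid = c("ms", "pan")) {
  grid <- match.arg(grid)
  rc <- if (is.matrix(rowcol)) rowcol else matrix(rowcol, ncol = 2)
  gsd <- if (grid == "ms") ms_gsd(scene) else pan_gsd(scene)
  cbind(x = scene$origin_xy_m[1] + (rc[, 2] + 0.5) * gsd,
        y = scene$origin_xy_m[2] - (rc[, 1] + 0.5) * gsd)
}

## ---- scene IO --------------------------------------------------------------
##
## A scene travels as a TIFF pair (<base>_ms.tif, 8 pages; <base>_pan.tif)
## plus a JSON sidecar (<base>_meta.json) carrying the georeferencing, DN
## ceiling and band table. 16-bit samples preserve 11-bit DN exactly.

scene_paths <- function(path) {
  base <- sub("\\.(tif|tiff|json)$", "", path)
  base <- sub("_(ms|pan|meta)$", "", base)
  list(ms = paste0(base, "_ms.tif"), pan = paste0(base, "_pan.tif"),
       meta = paste0(base, "_meta.json"))
}

#' Write / read a scene
#'
#' @param scene a `multiband_scene`.
#' @param path base path; `_ms.tif`, `_pan.tif` and `_meta.json` suffixes are
#'   appended (a path carrying one of those suffixes is also accepted).
#' @return `read_scene` returns a `multiband_scene`; `write_scene` returns
#'   `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  p <- scene_paths(path)
  pages <- lapply(1:8, function(b) scene$ms[, , b] / 65535)
  tiff::writeTIFF(pages, p$ms, bits.per.sample = 16)
  tiff::writeTIFF(scene$pan / 65535, p$pan, bits.per.sample = 16)
  meta <- list(origin_xy_m = scene$origin_xy_m, dn_max = scene$dn_max,
               ms_shape = dim(scene$ms)[1:2], band_specs = scene$band_specs)
  jsonlite::write_json(meta, p$meta, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  p <- scene_paths(path)
  for (f in unlist(p)) if (!file.exists(f))
    stop("band spec incomplete: missing scene file ", f)
  meta <- jsonlite::read_json(p$meta, simplifyVector = TRUE)
  pages <- tiff::readTIFF(p$ms, all = TRUE)
  if (length(pages) != 8L)
    stop("band spec incomplete: expected 8 multispectral pages, found ",
         length(pages))
  ms <- array(0, dim = c(dim(pages[[1]]), 8))
  for (b in 1:8) ms[, , b] <- round(pages[[b]] * 65535)
  pan <- round(tiff::readTIFF(p$pan) * 65535)
  specs <- as.data.frame(meta$band_specs, stringsAsFactors = FALSE)
  multiband_scene(ms, pan, origin_xy_m = meta$origin_xy_m,
                  band_specs = specs, dn_max = meta$dn_max)
}

## ---- annotation IO ---------------------------------------------------------

annotation_cols <- c("object_id", "x_m", "y_m", "length_m", "class_label",
                     "depth_m", "category")

#' Coerce and validate a reference-annotation table
#'
#' Reference annotations are manually digitized (or simulated-truth) objects:
#' a centroid in world metres, a length, and one of the three manual classes
#' (see [detection_classes()]). `depth_m` and `category` are simulator-truth
#' extras; `class_label` may be `NA` for truth objects that a manual
#' digitizer would not record as whale-like (boats, rocks).
#'
#' @param df a data.frame with at least `object_id, x_m, y_m, length_m,
#'   class_label`.
#' @return A data.frame with the canonical column set.
#' @export
as_annotations <- function(df) {
  if (nrow(df) == 0)
    return(stats::setNames(
      data.frame(character(), numeric(), numeric(), numeric(), character(),
                 numeric(), character(), stringsAsFactors = FALSE),
      annotation_cols))
  for (col in c("depth_m", "category")) if (is.null(df[[col]])) df[[col]] <- NA
  miss <- setdiff(annotation_cols, names(df))
  if (length(miss)) stop("annotation columns missing: ", paste(miss, collapse = ", "))
  bad <- !is.na(df$class_label) & !(df$class_label %in% detection_classes())
  if (any(bad))
    stop("unknown class: ", paste(unique(df$class_label[bad]), collapse = ", "))
  df <- df[annotation_cols]
  df$object_id <- as.character(df$object_id)
  rownames(df) <- NULL
  df
}

#' Write / read reference annotations
#'
#' GeoJSON (`.geojson`/`.json`: point features with properties) or CSV
#' (columns `object_id, x_m, y_m, length_m, class_label, depth_m, category`).
#' Coordinates are world metres so one annotation set serves both grids.
#'
#' @param annotations a data.frame as from [as_annotations()].
#' @param path output path; format chosen by extension.
#' @return `read_annotations` returns the annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  ann <- as_annotations(annotations)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(ann, path, row.names = FALSE, na = "")
  } else if (ext %in% c("geojson", "json")) {
    features <- lapply(seq_len(nrow(ann)), function(i) {
      props <- as.list(ann[i, setdiff(annotation_cols, c("x_m", "y_m"))])
      props <- lapply(props, function(v) if (is.na(v)) NULL else v)
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(ann$x_m[i], ann$y_m[i])),
           properties = props)
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else stop("unsupported annotation format: .", ext)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(object_id = "character"))
    if (nrow(df) == 0) return(as_annotations(df[0, , drop = FALSE]))
    df$class_label[!is.na(df$class_label) & df$class_label == ""] <- NA
    if (!is.null(df$category))
      df$category[!is.na(df$category) & df$category == ""] <- NA
    return(as_annotations(df))
  }
  if (!(ext %in% c("geojson", "json")))
    stop("unsupported annotation format: .", ext)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  if (is.null(feats) || length(feats) == 0) return(as_annotations(data.frame()))
  rows <- lapply(feats, function(f) {
    pr <- f$properties
    grab <- function(k, default = NA) if (is.null(pr[[k]])) default else pr[[k]]
    data.frame(object_id = as.character(grab("object_id", "")),
               x_m = f$geometry$coordinates[[1]],
               y_m = f$geometry$coordinates[[2]],
               length_m = as.numeric(grab("length_m")),
               class_label = as.character(grab("class_label")),
               depth_m = as.numeric(grab("depth_m")),
               category = as.character(grab("category")),
               stringsAsFactors = FALSE)
  })
  as_annotations(do.call(rbind, rows))
}
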