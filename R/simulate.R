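## Synthetic WorldView2-like scenes with known truth.
##
## The generator reproduces the band phenomenology the detection method
## relies on: all bands respond to surface features (the panchromatic band
## most strongly, and most noisily), while submerged features survive only
## in the coastal band. Submersion is modelled as a two-way exponential
## (Beer-Lambert-like) attenuation of the whale's surface DN contrast with
## a per-band diffuse attenuation coefficient K_d, minimal in the coastal
## band. The paper trail for the real image gives only the qualitative
## contrast behaviour, so K_d is a simulator construct, not a measured
## quantity; defaults are ordered by wavelength the way clear-water optics
## orders attenuation, and make all three visibility regimes (all-band,
## weak-pan, coastal-only) realisable.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_scene()]. Defaults describe a calm
#' sheltered bay imaged with 11-bit radiometry: a flat water background with
#' small Gaussian sensor noise (larger in the panchromatic band, which shows
#' a higher noise ratio at its finer resolution), a low-frequency surface
#' texture, and right-whale-sized ellipsoidal targets of 5–15 m with a
#' bright callus spot at the head end.
#'
#' @param ms_shape (rows, cols) of the multispectral grids; pan is 4x each.
#' @param water_mean_dn mean water DN, scalar or length 9 (8 MS bands + pan).
#' @param water_noise_sd per-pixel Gaussian noise sd in the MS bands, DN.
#' @param pan_noise_sd noise sd in the panchromatic band, DN (larger).
#' @param surface_texture_amplitude_dn sd of the shared low-frequency
#'   background field, DN.
#' @param correlation_length_m correlation length of that field, metres.
#' @param n_whales number of whales.
#' @param whale_length_range_m whale length interval, metres (within 5–16).
#' @param whale_aspect_range minor/major axis ratio interval.
#' @param depth_range_m submersion depth interval, metres.
#' @param whale_surface_contrast_dn DN contrast of a whale at depth 0.
#' @param attenuation_coeff_per_band two-way diffuse attenuation K_d per
#'   metre, length 9 (bands 1–8 then pan); the coastal band (5) must be the
#'   strict minimum.
#' @param callus_contrast_dn extra DN of the bright head spot.
#' @param callus_fraction fraction of the semi-major axis occupied by it.
#' @param n_seabird_clusters,n_bubble_slicks,n_boats,n_rocks confounder
#'   counts (the confounder taxonomy observed in real imagery).
#' @param whale_pair_fraction fraction of whales rendered as a touching
#'   pair (mother-and-calf ambiguity); a pair is one truth annotation.
#' @param glint_fraction fraction of pan pixels hit by specular glint
#'   speckle; 0 by default (scenes emulate a calm sea state).
#' @param min_separation_m minimum centroid separation between objects.
#' @param max_place_retries rejection-sampling retries per object before a
#'   "placement failure" error.
#' @param seed integer seed; the scene is a deterministic function of the
#'   config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(ms_shape = c(150, 150),
                              water_mean_dn = 180,
                              water_noise_sd = 8,
                              pan_noise_sd = 20,
                              surface_texture_amplitude_dn = 4,
                              correlation_length_m = 60,
                              n_whales = 10,
                              whale_length_range_m = c(5, 15),
                              whale_aspect_range = c(0.25, 0.45),
                              depth_range_m = c(0, 3),
                              whale_surface_contrast_dn = 250,
                              attenuation_coeff_per_band = c(
                                1.6, 0.5, 0.7, 1.1, 0.25, 2.5, 4.0, 5.0, 1.0),
                              callus_contrast_dn = 150,
                              callus_fraction = 0.15,
                              n_seabird_clusters = 0,
                              n_bubble_slicks = 0,
                              n_boats = 0,
                              n_rocks = 0,
                              whale_pair_fraction = 0,
                              glint_fraction = 0,
                              min_separation_m = 20,
                              max_place_retries = 1000,
                              seed = 1L) {
  cfg <- list(ms_shape = as.integer(ms_shape),
              water_mean_dn = rep_len(water_mean_dn, 9),
              water_noise_sd = water_noise_sd, pan_noise_sd = pan_noise_sd,
              surface_texture_amplitude_dn = surface_texture_amplitude_dn,
              correlation_length_m = correlation_length_m,
              n_whales = as.integer(n_whales),
              whale_length_range_m = whale_length_range_m,
              whale_aspect_range = whale_aspect_range,
              depth_range_m = depth_range_m,
              whale_surface_contrast_dn = whale_surface_contrast_dn,
              attenuation_coeff_per_band = attenuation_coeff_per_band,
              callus_contrast_dn = callus_contrast_dn,
              callus_fraction = callus_fraction,
              n_seabird_clusters = as.integer(n_seabird_clusters),
              n_bubble_slicks = as.integer(n_bubble_slicks),
              n_boats = as.integer(n_boats), n_rocks = as.integer(n_rocks),
              whale_pair_fraction = whale_pair_fraction,
              glint_fraction = glint_fraction,
              min_separation_m = min_separation_m,
              max_place_retries = as.integer(max_place_retries),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  k <- cfg$attenuation_coeff_per_band
  if (length(k) != 9)
    stop("attenuation_coeff_per_band must have 9 entries (bands 1-8, pan)")
  if (!all(k[5] < k[-5]))
    stop("the coastal band (band 5) must have the strictly smallest attenuation coefficient")
  if (cfg$whale_length_range_m[1] < 0 ||
      cfg$whale_length_range_m[2] > 16 ||
      diff(cfg$whale_length_range_m) < 0)
    stop("whale_length_range_m must be an increasing interval within [0, 16] m")
  if (any(cfg$depth_range_m < 0)) stop("invalid depth")
  counts <- c(cfg$n_whales, cfg$n_seabird_clusters, cfg$n_bubble_slicks,
              cfg$n_boats, cfg$n_rocks)
  if (any(counts < 0)) stop("object counts must be non-negative")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  MS grid %d x %d (%.0f x %.0f m), seed %d\n",
              x$ms_shape[1], x$ms_shape[2],
              x$ms_shape[2] * 2, x$ms_shape[1] * 2, x$seed))
  cat(sprintf("  water %g DN, noise sd %g (pan %g), texture %g DN\n",
              x$water_mean_dn[1], x$water_noise_sd, x$pan_noise_sd,
              x$surface_texture_amplitude_dn))
  cat(sprintf("  %d whales %g-%g m at depth %g-%g m, contrast %g DN\n",
              x$n_whales, x$whale_length_range_m[1], x$whale_length_range_m[2],
              x$depth_range_m[1], x$depth_range_m[2],
              x$whale_surface_contrast_dn))
  cat(sprintf("  confounders: %d seabird clusters, %d bubble slicks, %d boats, %d rocks\n",
              x$n_seabird_clusters, x$n_bubble_slicks, x$n_boats, x$n_rocks))
  invisible(x)
}

kd_for_band <- function(config, band) {
  if (identical(band, "pan")) return(config$attenuation_coeff_per_band[9])
  if (identical(band, "coastal")) band <- 5
  if (is.list(band) || is.data.frame(band)) band <- band$band
  if (identical(as.character(band), "pan"))
    return(config$attenuation_coeff_per_band[9])
  config$attenuation_coeff_per_band[as.integer(band)]
}

noise_sd_for_band <- function(config, band) {
  if (identical(band, "pan") ||
      identical(as.character(if (is.list(band)) band$band else band), "pan"))
    config$pan_noise_sd else config$water_noise_sd
}

#' Whale DN contrast at depth
#'
#' The simulator's attenuation law: a whale with surface contrast `S`
#' submerged to depth `d` contributes `S * exp(-K_d(band) * d)` DN in each
#' band, where `K_d` is the per-band two-way diffuse attenuation
#' coefficient. Contrast is monotonically non-increasing in depth and the
#' coastal band always retains the most.
#'
#' @param surface_contrast_dn DN contrast at depth 0.
#' @param depth_m depth, metres (non-negative).
#' @param band band selector: 1–8, `"pan"`, `"coastal"`, or a row of the
#'   band table.
#' @param config a [simulation_config()].
#' @return DN contrast at depth.
#' @export
#' @examples
#' cfg <- simulation_config()
#' whale_dn_contrast(250, 0, 5, cfg)   # surface: full contrast
#' whale_dn_contrast(250, 6, 5, cfg)   # coastal band at 6 m
#' whale_dn_contrast(250, 6, "pan", cfg)
whale_dn_contrast <- function(surface_contrast_dn, depth_m, band, config) {
  if (any(depth_m < 0)) stop("invalid depth")
  surface_contrast_dn * exp(-kd_for_band(config, band) * depth_m)
}

#' Depth window in which a whale is visible only in the coastal band
#'
#' Solves the two exponential inequalities: the coastal-band contrast must
#' stay at or above `2 * water_noise_sd` while every other band's contrast
#' falls below `1 *` its own noise sd. Whales placed at depths inside the
#' returned interval are "band 5 only" features.
#'
#' @param config a [simulation_config()].
#' @return `c(lo, hi)` in metres, or `c(NA, NA)` if the window is empty or
#'   undefined (e.g. zero noise).
#' @export
band5_only_depth_window <- function(config) {
  S <- config$whale_surface_contrast_dn
  sd5 <- config$water_noise_sd
  if (sd5 <= 0 || S <= 2 * sd5) return(c(NA_real_, NA_real_))
  hi <- log(S / (2 * sd5)) / kd_for_band(config, 5)
  others <- c(setdiff(1:8, 5), "pan")
  lo <- max(vapply(others, function(b) {
    sdb <- noise_sd_for_band(config, b)
    if (sdb <= 0 || S <= sdb) return(Inf)
    log(S / sdb) / kd_for_band(config, b)
  }, numeric(1)))
  if (!is.finite(lo) || lo >= hi) return(c(NA_real_, NA_real_))
  c(lo = lo, hi = hi)
}

## Emulates the manual digitizer's three-class coding for a simulated whale.
manual_whale_class <- function(depth_m, length_m, config) {
  pan_sd <- config$pan_noise_sd
  pan_contrast <- whale_dn_contrast(config$whale_surface_contrast_dn,
                                    depth_m, "pan", config)
  if (pan_contrast >= 2 * max(pan_sd, .Machine$double.eps)) return("probable")
  w <- band5_only_depth_window(config)
  if (!is.na(w[1]) && depth_m >= w[1] && depth_m <= w[2]) return("band5_only")
  "possible"
}

## ---- low-level field helpers ----------------------------------------------

bilinear_upsample <- function(coarse, nr, nc) {
  m <- nrow(coarse); n <- ncol(coarse)
  rr <- seq(1, m, length.out = nr)
  cc <- seq(1, n, length.out = nc)
  i0 <- pmin(floor(rr), m - 1); fr <- rr - i0
  j0 <- pmin(floor(cc), n - 1); fc <- cc - j0
  coarse[i0, j0]         * ((1 - fr) %o% (1 - fc)) +
    coarse[i0 + 1, j0]     * (fr %o% (1 - fc)) +
    coarse[i0, j0 + 1]     * ((1 - fr) %o% fc) +
    coarse[i0 + 1, j0 + 1] * (fr %o% fc)
}

block_mean_4 <- function(x) {
  nr <- nrow(x) / 4L; nc <- ncol(x) / 4L
  a <- array(x, dim = c(4L, nr, 4L, nc))
  rowMeans(aperm(a, c(2L, 4L, 1L, 3L)), dims = 2L)
}

## Pixel-centre coordinates and ellipse membership within a bounding box.
## Returns 1-based row/col plus the along-major-axis coordinate u.
ellipse_pixels <- function(scene, grid, centre_xy_m, a, b, theta,
                           soft = FALSE) {
  gsd <- if (grid == "ms") ms_gsd(scene) else pan_gsd(scene)
  nd <- if (grid == "ms") dim(scene$ms)[1:2] else dim(scene$pan)
  x0 <- scene$origin_xy_m[1]; y0 <- scene$origin_xy_m[2]
  r0 <- max(1L, floor((y0 - (centre_xy_m[2] + a)) / gsd) + 1L)
  r1 <- min(nd[1], ceiling((y0 - (centre_xy_m[2] - a)) / gsd))
  c0 <- max(1L, floor(((centre_xy_m[1] - a) - x0) / gsd) + 1L)
  c1 <- min(nd[2], ceiling(((centre_xy_m[1] + a) - x0) / gsd))
  if (r0 > r1 || c0 > c1)
    return(data.frame(row = integer(), col = integer(), u = numeric(),
                      v = numeric(), w = numeric()))
  rows <- r0:r1; cols <- c0:c1
  px <- x0 + (rep(cols, each = length(rows)) - 0.5) * gsd
  py <- y0 - (rep(rows, times = length(cols)) - 0.5) * gsd
  dx <- px - centre_xy_m[1]; dy <- py - centre_xy_m[2]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  keep <- r2 <= 1
  data.frame(row = rep(rows, times = length(cols))[keep],
             col = rep(cols, each = length(rows))[keep],
             u = u[keep], v = v[keep],
             w = if (soft) pmax(0, 1 - r2[keep]) else rep(1, sum(keep)))
}

add_to_band <- function(scene, band, px, amount) {
  if (nrow(px) == 0) return(scene)
  if (identical(band, "pan")) {
    idx <- cbind(px$row, px$col)
    scene$pan[idx] <- scene$pan[idx] + amount * px$w
  } else {
    idx <- cbind(px$row, px$col, as.integer(band))
    scene$ms[idx] <- scene$ms[idx] + amount * px$w
  }
  scene
}

all_bands <- function() c(as.list(1:8), list("pan"))

## Render an elliptical patch into all nine grids with mixed-pixel physics:
## membership is evaluated on the fine pan grid and MS pixels receive the
## area-weighted (4x4 block) fraction, so a sub-pixel object still deposits
## proportional DN in the coarse bands instead of vanishing.
## `contrasts` is numeric length 9 (bands 1-8 then pan); `clip` optionally
## restricts the footprint via a predicate on the (u, v) pixel frame.
render_patch <- function(scene, centre, a, b, theta, contrasts,
                         soft = FALSE, clip = NULL) {
  px <- ellipse_pixels(scene, "pan", centre, a, b, theta, soft = soft)
  if (!is.null(clip)) px <- px[clip(px), , drop = FALSE]
  if (nrow(px) == 0) return(list(scene = scene, pan_pixels = px))
  scene <- add_to_band(scene, "pan", px, contrasts[9])
  nr <- dim(scene$ms)[1]
  ms_idx <- ((px$row - 1L) %/% 4L + 1L) + ((px$col - 1L) %/% 4L) * nr
  agg <- rowsum(px$w, ms_idx)
  ii <- as.integer(rownames(agg))
  rr <- (ii - 1L) %% nr + 1L
  cc <- (ii - 1L) %/% nr + 1L
  frac <- agg[, 1] / 16
  for (b in 1:8)
    scene$ms[cbind(rr, cc, b)] <- scene$ms[cbind(rr, cc, b)] +
      contrasts[b] * frac
  list(scene = scene, pan_pixels = px)
}

band_contrasts <- function(surface_contrast_dn, depth_m, config) {
  vapply(all_bands(), function(b)
    whale_dn_contrast(surface_contrast_dn, depth_m, b, config), numeric(1))
}

## ---- object renderers ------------------------------------------------------

#' Render one whale into a scene
#'
#' Adds an elliptical DN bump to every band, with per-band contrast given by
#' [whale_dn_contrast()], plus a brighter callus sub-spot at one semi-major
#' end. The scene is modified copy-on-write and returned.
#'
#' @param scene a `multiband_scene`.
#' @param centre_xy_m whale centroid, world metres.
#' @param length_m body length, metres; must lie within the config's range.
#' @param aspect minor/major axis ratio.
#' @param orientation_rad major-axis orientation, radians from east.
#' @param depth_m submersion depth, metres.
#' @param config a [simulation_config()].
#' @return `list(scene = modified scene, pan_pixels = 0-based (row, col)
#'   matrix of the pan-grid footprint)`.
#' @export
render_whale <- function(scene, centre_xy_m, length_m, aspect,
                         orientation_rad, depth_m, config) {
  if (depth_m < 0) stop("invalid depth")
  rng <- config$whale_length_range_m
  if (length_m < rng[1] || length_m > rng[2])
    stop("invalid whale geometry: length outside configured range")
  a <- length_m / 2; b <- aspect * length_m / 2
  ext <- scene_extent(scene)
  if (centre_xy_m[1] - a < ext["xmin"] || centre_xy_m[1] + a > ext["xmax"] ||
      centre_xy_m[2] - a < ext["ymin"] || centre_xy_m[2] + a > ext["ymax"])
    stop("invalid whale geometry: ellipse outside scene extent")
  S <- config$whale_surface_contrast_dn
  u_callus <- a * (1 - 2 * config$callus_fraction)
  body <- render_patch(scene, centre_xy_m, a, b, orientation_rad,
                       band_contrasts(S, depth_m, config))
  cal <- render_patch(body$scene, centre_xy_m, a, b, orientation_rad,
                      band_contrasts(config$callus_contrast_dn, depth_m,
                                     config),
                      clip = function(px) px$u >= u_callus)
  list(scene = cal$scene,
       pan_pixels = cbind(row = body$pan_pixels$row - 1L,
                          col = body$pan_pixels$col - 1L))
}

render_surface_patch <- function(scene, centre, a, b, theta, contrast,
                                 soft = FALSE, clip = NULL) {
  render_patch(scene, centre, a, b, theta, rep(contrast, 9),
               soft = soft, clip = clip)$scene
}

render_seabird_cluster <- function(scene, centre, config) {
  n_dots <- sample(5:12, 1)
  pg <- pan_gsd(scene)
  contrast <- 1.2 * config$whale_surface_contrast_dn
  placed <- matrix(numeric(0), ncol = 2)
  for (d in seq_len(n_dots)) {
    for (try in 1:100) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 8)
      p <- centre + rad * c(cos(ang), sin(ang))
      if (nrow(placed) == 0 ||
          min(sqrt(colSums((t(placed) - p)^2))) >= 3 * pg) break
    }
    placed <- rbind(placed, p)
    rc <- world_to_pixel(scene, p, "pan") + 1L
    two_px <- runif(1) < 0.5 && rc[2] < ncol(scene$pan)
    cols <- if (two_px) c(rc[2], rc[2] + 1L) else rc[2]
    px <- data.frame(row = rep(rc[1], length(cols)), col = cols,
                     u = 0, w = 1)
    scene <- add_to_band(scene, "pan", px, contrast)
    # a 1-pan-pixel dot covers 1/16 of an MS pixel
    rcm <- world_to_pixel(scene, p, "ms") + 1L
    mpx <- data.frame(row = rcm[1], col = rcm[2], u = 0, w = 1)
    for (band in 1:8)
      scene <- add_to_band(scene, band, mpx, contrast * length(cols) / 16)
  }
  scene
}

render_bubble_slick <- function(scene, centre, config) {
  a <- runif(1, 10, 30)
  b <- a * runif(1, 0.15, 0.3)
  theta <- runif(1, 0, pi)
  amp <- 1.5 * config$water_noise_sd + 2
  list(scene = render_surface_patch(scene, centre, a, b, theta, amp,
                                    soft = TRUE),
       length_m = 2 * a)
}

render_boat <- function(scene, centre, config) {
  L <- runif(1, 20, 30); W <- runif(1, 4, 6)
  theta <- runif(1, 0, pi)
  contrast <- config$whale_surface_contrast_dn + config$callus_contrast_dn + 100
  rad <- sqrt((L / 2)^2 + (W / 2)^2)
  # hull: uniform bright rectangle cut from a covering disc
  scene <- render_surface_patch(
    scene, centre, rad, rad, theta, contrast,
    clip = function(px) abs(px$u) <= L / 2 & abs(px$v) <= W / 2)
  # linear wake astern: 1.5 boat lengths, 2 m wide
  scene <- render_surface_patch(
    scene, centre, 2.1 * L, 2.1 * L, theta,
    0.3 * config$whale_surface_contrast_dn,
    clip = function(px) px$u <= -L / 2 & px$u >= -2 * L & abs(px$v) <= 1)
  list(scene = scene, length_m = L)
}

render_rock <- function(scene, centre, config) {
  a <- runif(1, 2, 5)
  b <- a * runif(1, 0.5, 0.9)
  theta <- runif(1, 0, pi)
  # static shallow feature: identical contrast in every band, no attenuation
  list(scene = render_surface_patch(scene, centre, a, b, theta,
                                    0.8 * config$whale_surface_contrast_dn),
       length_m = 2 * a)
}

## ---- placement -------------------------------------------------------------

place_objects <- function(n, margin_m, existing_xy, ext, config) {
  out <- matrix(numeric(0), ncol = 2)
  all_xy <- existing_xy
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(config$max_place_retries)) {
      p <- c(runif(1, ext["xmin"] + margin_m, ext["xmax"] - margin_m),
             runif(1, ext["ymin"] + margin_m, ext["ymax"] - margin_m))
      if (nrow(all_xy) == 0 ||
          min(sqrt(colSums((t(all_xy) - p)^2))) >= config$min_separation_m) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement failure")
    out <- rbind(out, p)
    all_xy <- rbind(all_xy, p)
  }
  out
}

## ---- confounders -----------------------------------------------------------

#' Render the confounder taxonomy into a scene
#'
#' Adds the confusable feature types observed in real imagery: seabird
#' clusters (scattered 1–2-pan-pixel bright dots), bubble slicks (diffuse
#' low-contrast elongated patches), boats (uniform bright rectangles, longer
#' than any whale and brighter than any whale pixel, with a linear wake) and
#' subsurface rocks (static bright patches with identical contrast in every
#' band). Counts come from the config. Consumes the current RNG stream; seed
#' it (or call via [simulate_scene()]) for reproducibility.
#'
#' @param scene a `multiband_scene`.
#' @param config a [simulation_config()].
#' @param avoid_xy optional matrix of existing object centroids to keep the
#'   minimum separation from.
#' @return `list(scene, annotations)` where `annotations` is a reference-
#'   annotation data.frame (seabird clusters and bubble slicks carry the
#'   manual class "possible"; boats and rocks are not whale-like and carry
#'   `NA`).
#' @export
render_confounders <- function(scene, config, avoid_xy = NULL) {
  ext <- scene_extent(scene)
  existing <- if (is.null(avoid_xy)) matrix(numeric(0), ncol = 2) else avoid_xy
  rows <- list()
  add_ann <- function(id, p, len, cls, cat) {
    rows[[length(rows) + 1]] <<- data.frame(
      object_id = id, x_m = p[1], y_m = p[2], length_m = len,
      class_label = cls, depth_m = NA_real_, category = cat,
      stringsAsFactors = FALSE)
  }
  specs <- list(
    list(n = config$n_seabird_clusters, margin = 12, cat = "seabird_cluster"),
    list(n = config$n_bubble_slicks, margin = 32, cat = "bubble_slick"),
    list(n = config$n_boats, margin = 35, cat = "boat"),
    list(n = config$n_rocks, margin = 8, cat = "rock"))
  for (sp in specs) {
    if (sp$n == 0) next
    pos <- place_objects(sp$n, sp$margin, existing, ext, config)
    existing <- rbind(existing, pos)
    for (i in seq_len(sp$n)) {
      p <- pos[i, ]
      id <- sprintf("%s_%02d", sp$cat, i)
      if (sp$cat == "seabird_cluster") {
        scene <- render_seabird_cluster(scene, p, config)
        add_ann(id, p, 16, "possible", sp$cat)
      } else if (sp$cat == "bubble_slick") {
        r <- render_bubble_slick(scene, p, config)
        scene <- r$scene
        add_ann(id, p, r$length_m, "possible", sp$cat)
      } else if (sp$cat == "boat") {
        r <- render_boat(scene, p, config)
        scene <- r$scene
        add_ann(id, p, r$length_m, NA_character_, sp$cat)
      } else {
        r <- render_rock(scene, p, config)
        scene <- r$scene
        add_ann(id, p, r$length_m, NA_character_, sp$cat)
      }
    }
  }
  ann <- if (length(rows)) as_annotations(do.call(rbind, rows))
         else as_annotations(data.frame())
  list(scene = scene, annotations = ann)
}

## ---- scene generator -------------------------------------------------------

#' Simulate a WorldView2-like scene with known truth
#'
#' Generates the dual-resolution scene and a truth table of every rendered
#' object. Draw order is fixed (background, whales, then confounders in
#' taxonomy order) so a given `(config, seed)` always produces bit-identical
#' output. Whale truth classes emulate the manual digitizer: pan-visible
#' whales are "probable", whales in the coastal-band-only depth window (see
#' [band5_only_depth_window()]) are "band5_only", intermediate depths
#' "possible".
#'
#' @param config a [simulation_config()].
#' @return `list(scene = multiband_scene, truth = list(annotations, config))`
#'   of class `scene_truth`.
#' @export
#' @examples
#' sim <- simulate_scene(simulation_config(ms_shape = c(60, 60), n_whales = 3))
#' sim$truth$annotations
simulate_scene <- function(config) {
  validate_simulation_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nr <- config$ms_shape[1]; nc <- config$ms_shape[2]
  pr <- 4L * nr; pc <- 4L * nc
  specs <- wv2_band_specs()
  width_m <- nc * specs$gsd_m[1]; height_m <- nr * specs$gsd_m[1]

  ## background: shared low-frequency surface texture + per-band white noise
  tex_pan <- matrix(0, pr, pc)
  if (config$surface_texture_amplitude_dn > 0) {
    nodes_r <- max(2L, ceiling(height_m / config$correlation_length_m) + 1L)
    nodes_c <- max(2L, ceiling(width_m / config$correlation_length_m) + 1L)
    coarse <- matrix(rnorm(nodes_r * nodes_c,
                           sd = config$surface_texture_amplitude_dn),
                     nodes_r, nodes_c)
    tex_pan <- bilinear_upsample(coarse, pr, pc)
  }
  tex_ms <- block_mean_4(tex_pan)

  ms <- array(0, dim = c(nr, nc, 8))
  for (b in 1:8)
    ms[, , b] <- config$water_mean_dn[b] + tex_ms +
      if (config$water_noise_sd > 0)
        matrix(rnorm(nr * nc, sd = config$water_noise_sd), nr, nc) else 0
  pan <- config$water_mean_dn[9] + tex_pan +
    if (config$pan_noise_sd > 0)
      matrix(rnorm(pr * pc, sd = config$pan_noise_sd), pr, pc) else 0
  if (config$glint_fraction > 0) {
    n_g <- round(config$glint_fraction * pr * pc)
    idx <- sample.int(pr * pc, n_g)
    pan[idx] <- pan[idx] + runif(n_g, 0.5, 1) * config$whale_surface_contrast_dn
  }

  # build on an unclipped scene; round and clip once at the end
  scene <- structure(
    list(ms = ms, pan = pan, origin_xy_m = c(0, height_m),
         band_specs = specs, dn_max = 2047),
    class = "multiband_scene")
  ext <- scene_extent(scene)

  ## whales
  rows <- list()
  whale_xy <- matrix(numeric(0), ncol = 2)
  if (config$n_whales > 0) {
    margin <- config$whale_length_range_m[2] / 2 + 2
    pos <- place_objects(config$n_whales, margin, whale_xy, ext, config)
    for (i in seq_len(config$n_whales)) {
      len <- runif(1, config$whale_length_range_m[1],
                   config$whale_length_range_m[2])
      aspect <- runif(1, config$whale_aspect_range[1],
                      config$whale_aspect_range[2])
      theta <- runif(1, 0, pi)
      depth <- runif(1, config$depth_range_m[1], config$depth_range_m[2])
      r <- render_whale(scene, pos[i, ], len, aspect, theta, depth, config)
      scene <- r$scene
      if (runif(1) < config$whale_pair_fraction) {
        # touching calf alongside; the pair is one truth annotation
        calf_len <- max(config$whale_length_range_m[1], 0.5 * len)
        off <- (aspect * len / 2 + aspect * calf_len / 2) *
          c(-sin(theta), cos(theta))
        calf_centre <- pos[i, ] + off
        r2 <- try(render_whale(scene, calf_centre, calf_len, aspect, theta,
                               depth, config), silent = TRUE)
        if (!inherits(r2, "try-error")) scene <- r2$scene
      }
      rows[[length(rows) + 1]] <- data.frame(
        object_id = sprintf("whale_%02d", i),
        x_m = pos[i, 1], y_m = pos[i, 2], length_m = len,
        class_label = manual_whale_class(depth, len, config),
        depth_m = depth, category = "whale", stringsAsFactors = FALSE)
    }
    whale_xy <- pos
  }

  ## confounders
  conf <- render_confounders(scene, config, avoid_xy = whale_xy)
  scene <- conf$scene

  ## quantize to the 11-bit DN range
  scene$ms <- array(pmin(pmax(round(scene$ms), 0), scene$dn_max), dim(scene$ms))
  scene$pan <- matrix(pmin(pmax(round(scene$pan), 0), scene$dn_max),
                      nrow(scene$pan), ncol(scene$pan))

  whale_ann <- if (length(rows)) as_annotations(do.call(rbind, rows))
               else as_annotations(data.frame())
  truth <- structure(list(annotations = rbind(whale_ann, conf$annotations),
                          config = config),
                     class = "scene_truth")
  list(scene = scene, truth = truth)
}

#' Evaluation reference from simulator truth
#'
#' The manual digitization recorded whale-like features only; boats and
#' rocks were identified visually and excluded. This helper subsets a truth
#' table to the rows a manual digitizer would have recorded (those with a
#' non-`NA` class label).
#'
#' @param truth a `scene_truth` or its annotations data.frame.
#' @return Annotation data.frame usable as an evaluation reference.
#' @export
truth_reference <- function(truth) {
  ann <- if (inherits(truth, "scene_truth")) truth$annotations else truth
  ann[!is.na(ann$class_label), , drop = FALSE]
}
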