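test_that("component labelling handles connectivity and matches flood fill", {
  expect_equal(max(label_components(matrix(FALSE, 5, 5))), 0)
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(max(label_components(diagm, 8)), 1)
  expect_equal(max(label_components(diagm, 4)), 2)
  set.seed(101)
  for (rep in 1:100) {
    mask <- matrix(runif(400) < runif(1, 0.2, 0.6), 20, 20)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      ref <- flood_fill_label(mask, conn)
      expect_equal(max(got), max(ref))
      # identical partition: labels agree up to renaming
      if (max(ref) > 0)
        expect_equal(got[mask], ref[mask])
    }
  }
})

test_that("a single blob yields one multi-pixel component and a high threshold", {
  x <- matrix(100, 30, 30)
  x[10:11, 10:14] <- 500  # 10-pixel blob
  res <- optimize_threshold(x)
  expect_gt(res$threshold_dn, 100)
  expect_lt(res$threshold_dn, 500)
  expect_equal(res$n_multi_pixel_components, 1)
  expect_equal(res$n_single_pixel_components, 0)
  expect_equal(res$ratio, 1)
})

test_that("isolated bright noise pixels push the optimal threshold above them", {
  set.seed(3)
  x <- matrix(100, 60, 60)
  x[20:22, 20:26] <- 500
  # 200 isolated single pixels at DN 400 on a sparse lattice
  free <- which(x == 100)
  lattice <- intersect(free, which(row(x) %% 3 == 1 & col(x) %% 3 == 1))
  x[sample(lattice, 200)] <- 400
  res <- optimize_threshold(x)
  expect_gte(res$threshold_dn, 400)
  expect_equal(res$n_multi_pixel_components, 1)
  expect_equal(res$n_single_pixel_components, 0)
})

test_that("threshold optimization errors on empty or signal-free input", {
  x <- matrix(100, 5, 5)
  expect_error(optimize_threshold(x, candidate_thresholds = numeric(0)),
               "empty candidate set")
  expect_error(optimize_threshold(x), "no signal above threshold")
})

test_that("optimize_threshold equals exhaustive search on simulated bands", {
  for (s in 1:10) {
    sim <- simulate_scene(simulation_config(
      ms_shape = c(40, 40), n_whales = 3, seed = 300 + s))
    g <- scene_band(sim$scene, 5)
    cand <- seq(floor(median(g)), ceiling(max(g)))
    got <- optimize_threshold(g, cand)
    ref <- exhaustive_threshold(g, cand)
    expect_equal(got$threshold_dn, ref$threshold)
    expect_equal(got$ratio, unname(ref$ratio))
    expect_equal(got$n_multi_pixel_components, unname(ref$multi))
    expect_equal(got$n_single_pixel_components, unname(ref$single))
  }
})

test_that("threshold segmentation extracts objects with correct measures", {
  x <- matrix(100, 30, 30)
  x[10:11, 10:14] <- 500
  det <- threshold_segment(x, 300, gsd_m = 2)
  expect_equal(nrow(det), 1)
  expect_equal(det$area_m2, 10 * 4)
  expect_equal(det$n_pixels, 10)
  # nothing above the DN ceiling
  expect_equal(nrow(threshold_segment(x, 2047)), 0)
})

test_that("second-moment axes recover a rasterized ellipse within 20%", {
  cfg <- simulation_config(ms_shape = c(60, 60), n_whales = 0,
                           water_noise_sd = 0, pan_noise_sd = 0,
                           surface_texture_amplitude_dn = 0, seed = 1)
  sim <- simulate_scene(cfg)
  r <- render_whale(sim$scene, c(60, 60), 12, 1 / 3, pi / 7, 0, cfg)
  det <- threshold_segment(r$scene$pan, cfg$water_mean_dn[9] + 10,
                           gsd_m = 0.5, origin_xy_m = r$scene$origin_xy_m,
                           grid = "pan")
  expect_equal(nrow(det), 1)
  expect_equal(det$major_axis_m, 12, tolerance = 0.2)
  expect_equal(det$minor_axis_m, 4, tolerance = 0.2)
  expect_equal(det$centroid_x_m, 60, tolerance = 0.5)
  expect_equal(det$centroid_y_m, 60, tolerance = 0.5)
})

test_that("the shape filter keeps whales, flags weak objects, rejects boats", {
  mk <- function(major, minor, n) {
    d <- empty_detections()
    d[1, c("id", "grid", "n_pixels", "centroid_x_m", "centroid_y_m",
           "area_m2", "major_axis_m", "minor_axis_m", "orientation_rad",
           "mean_dn", "contrast_sigma", "source", "detection_class")] <-
      list(1L, "ms", n, 0, 0, n * 4, major, minor, 0, 400, 10, "test",
           NA_character_)
    d$pixels <- list(cbind(row = rep(0, n), col = seq_len(n) - 1))
    d
  }
  whale <- shape_filter(mk(10, 3, 8))
  expect_equal(nrow(whale$kept), 1)
  expect_true(whale$kept$shape_pass)
  boat <- shape_filter(mk(30, 5, 60))
  expect_equal(nrow(boat$kept), 0)
  expect_equal(nrow(boat$rejected), 1)
  single <- shape_filter(mk(2, 2, 1))
  expect_equal(nrow(single$kept), 1)      # single pixels survive...
  expect_false(single$kept$shape_pass)    # ...but cannot be "probable"
})

test_that("cross-sections sample all nine bands at the requested length", {
  sim <- simulate_scene(simulation_config(ms_shape = c(60, 60), n_whales = 0,
                                          water_noise_sd = 0, pan_noise_sd = 0,
                                          surface_texture_amplitude_dn = 0,
                                          seed = 1))
  xs <- band_cross_section(sim$scene, c(10, 60), c(110, 60), n_samples = 75)
  expect_equal(dim(xs$profiles), c(75, 9))
  expect_true(all(apply(xs$profiles, 2, function(p) all(p == p[1]))))
  expect_error(band_cross_section(sim$scene, c(-10, 60), c(50, 60)),
               "outside scene")
})

test_that("cross-sections separate surface whales from submerged ones", {
  cfg <- simulation_config(ms_shape = c(60, 60), n_whales = 0, seed = 4)
  sim <- simulate_scene(cfg)
  w <- band5_only_depth_window(cfg)
  centre <- c(60, 60)
  band_sd <- c(rep(cfg$water_noise_sd, 8), cfg$pan_noise_sd)
  surf <- render_whale(sim$scene, centre, 14, 0.35, 0, 0, cfg)
  xs <- band_cross_section(surf$scene, centre - c(30, 0), centre + c(30, 0),
                           n_samples = 120, width_m = 2, n_lines = 5)
  sc <- section_contrast(xs, span = c(0.4, 0.6), noise_sd = band_sd)
  expect_true(all(sc$contrast_sigma >= 2))  # every band sees a surface whale
  deep <- render_whale(sim$scene, centre, 14, 0.35, 0, mean(w), cfg)
  xs2 <- band_cross_section(deep$scene, centre - c(30, 0), centre + c(30, 0),
                            n_samples = 120, width_m = 2, n_lines = 5)
  sc2 <- section_contrast(xs2, span = c(0.4, 0.6), noise_sd = band_sd)
  expect_gte(sc2$contrast_sigma[sc2$band == "band5"], 2)
  expect_true(all(sc2$contrast_sigma[sc2$band != "band5"] < 1))
})

test_that("cluster maps reduce to candidate masks of bright non-water clusters", {
  x <- matrix(100, 40, 40)
  x[5:8, 5:10] <- 400
  labels <- kmeans_segment(x, k = 2)
  mask <- cluster_to_candidates(labels, x)
  expect_true(all(x[mask] == 400))
  expect_equal(sum(mask), 24)
  # uniform scene: single cluster, empty mask
  u <- matrix(100, 20, 20)
  expect_equal(sum(cluster_to_candidates(kmeans_segment(u, 1), u)), 0)
  # mask is always a subset of pixels above the water mean
  set.seed(12)
  n <- matrix(rnorm(1600, 100, 5), 40, 40)
  n[5:8, 5:10] <- 400
  lab <- suppressWarnings(kmeans_segment(n, 3))  # far cluster may empty out
  m2 <- cluster_to_candidates(lab, n)
  water <- which.max(tabulate(lab))
  expect_true(all(n[m2] > mean(n[lab == water])))
})

test_that("detection classing applies the three-class rules", {
  cfg <- simulation_config(ms_shape = c(100, 100), n_whales = 0, seed = 6)
  sim <- simulate_scene(cfg)
  w <- band5_only_depth_window(cfg)
  s <- sim$scene
  s <- render_whale(s, c(50, 60), 12, 0.35, 0.4, 0, cfg)$scene        # surface
  s <- render_whale(s, c(150, 140), 12, 0.35, 1.2, mean(w), cfg)$scene # deep
  s$ms <- array(pmin(pmax(round(s$ms), 0), 2047), dim(s$ms))
  s$pan <- matrix(pmin(pmax(round(s$pan), 0), 2047), nrow(s$pan), ncol(s$pan))
  det <- detect_whales(s, "threshold_band5")
  near <- function(x, y) which(sqrt((det$centroid_x_m - x)^2 +
                                    (det$centroid_y_m - y)^2) < 8)
  expect_equal(det$detection_class[near(50, 60)], "probable")
  # the submerged whale may fragment at the threshold, but every piece is
  # coastal-band-only and none is promoted to probable
  deep_cls <- det$detection_class[near(150, 140)]
  expect_gte(length(deep_cls), 1)
  expect_true(all(deep_cls == "band5_only"))
})

test_that("end-to-end detection is deterministic and empty scenes yield nothing", {
  quiet <- simulate_scene(quiet_config(seed = 2))
  expect_equal(nrow(detect_whales(quiet$scene, "threshold_band5")), 0)
  expect_equal(nrow(detect_whales(quiet$scene, "threshold_pan")), 0)
  sim <- simulate_scene(simulation_config(ms_shape = c(80, 80), n_whales = 6,
                                          depth_range_m = c(0, 0), seed = 14))
  d1 <- detect_whales(sim$scene, "threshold_band5")
  d2 <- detect_whales(sim$scene, "threshold_band5")
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(sort(unique(d1$source)), "threshold_band5")
})

test_that("surface whales are recovered by coastal-band thresholding", {
  # zero noise: recall is exact
  cfg0 <- simulation_config(ms_shape = c(120, 120), n_whales = 20,
                            depth_range_m = c(0, 0), water_noise_sd = 0,
                            pan_noise_sd = 0,
                            surface_texture_amplitude_dn = 0, seed = 31)
  sim0 <- simulate_scene(cfg0)
  det0 <- detect_whales(sim0$scene, "threshold_band5")
  ref0 <- truth_reference(sim0$truth)
  m0 <- match_detections(det0, ref0)
  expect_equal(nrow(m0$pairs), 20)
})
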