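test_that("the same config and seed give bit-identical scenes and truth", {
  cfg <- simulation_config(ms_shape = c(60, 60), n_whales = 5,
                           n_seabird_clusters = 2, n_bubble_slicks = 1,
                           n_boats = 1, n_rocks = 1, seed = 99)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$scene$ms, b$scene$ms)
  expect_identical(a$scene$pan, b$scene$pan)
  expect_identical(a$truth$annotations, b$truth$annotations)
})

test_that("a background-only scene matches the configured water statistics", {
  cfg <- simulation_config(ms_shape = c(80, 80), n_whales = 0,
                           surface_texture_amplitude_dn = 0, seed = 5)
  sim <- simulate_scene(cfg)
  for (b in 1:8) {
    g <- sim$scene$ms[, , b]
    se_mean <- cfg$water_noise_sd / sqrt(length(g))
    expect_lt(abs(mean(g) - cfg$water_mean_dn[b]), 3 * se_mean + 0.5)
    expect_lt(abs(sd(g) - cfg$water_noise_sd), 3 * cfg$water_noise_sd)
  }
  g <- sim$scene$pan
  expect_lt(abs(mean(g) - cfg$water_mean_dn[9]),
            3 * cfg$pan_noise_sd / sqrt(length(g)) + 0.5)
  # pan is noisier than the MS bands, by construction
  expect_gt(sd(sim$scene$pan), sd(sim$scene$ms[, , 1]))
})

test_that("whale contrast attenuates exponentially and the coastal band wins", {
  cfg <- simulation_config()
  # depth 0: full surface contrast in every band
  for (b in c(as.list(1:8), list("pan")))
    expect_equal(whale_dn_contrast(250, 0, b, cfg), 250)
  # any positive depth: coastal band retains strictly the most
  for (d in c(0.5, 2, 5, 10)) {
    c5 <- whale_dn_contrast(250, d, 5, cfg)
    for (b in c(setdiff(1:8, 5), "pan"))
      expect_lt(whale_dn_contrast(250, d, b, cfg), c5)
  }
  # monotone non-increasing in depth
  depths <- seq(0, 12, by = 0.5)
  cc <- whale_dn_contrast(250, depths, 5, cfg)
  expect_true(all(diff(cc) <= 0))
  expect_error(whale_dn_contrast(250, -1, 5, cfg), "invalid depth")
})

test_that("the coastal-band-only depth window is non-empty and correct", {
  cfg <- simulation_config()
  w <- band5_only_depth_window(cfg)
  expect_false(any(is.na(w)))
  expect_lt(w["lo"], w["hi"])
  S <- cfg$whale_surface_contrast_dn
  d <- mean(w)
  # inside the window: coastal contrast >= 2 sd, all others < 1 sd
  expect_gte(whale_dn_contrast(S, d, 5, cfg), 2 * cfg$water_noise_sd)
  for (b in setdiff(1:8, 5))
    expect_lt(whale_dn_contrast(S, d, b, cfg), cfg$water_noise_sd)
  expect_lt(whale_dn_contrast(S, d, "pan", cfg), cfg$pan_noise_sd)
  # at the endpoints the binding constraints are tight
  expect_equal(whale_dn_contrast(S, w[["hi"]], 5, cfg),
               2 * cfg$water_noise_sd, tolerance = 1e-8)
})

test_that("surface whales in a noise-free scene are countable components", {
  cfg <- simulation_config(ms_shape = c(120, 120), n_whales = 20,
                           depth_range_m = c(0, 0), water_noise_sd = 0,
                           pan_noise_sd = 0, surface_texture_amplitude_dn = 0,
                           seed = 21)
  sim <- simulate_scene(cfg)
  mask <- sim$scene$pan > cfg$water_mean_dn[9]
  sizes <- tabulate(label_components(mask, 8))
  expect_equal(sum(sizes >= 2), 20)
  expect_equal(length(sim$truth$annotations$object_id), 20)
})

test_that("rendered whales have the right footprint and callus", {
  cfg <- simulation_config(ms_shape = c(60, 60), n_whales = 0,
                           water_noise_sd = 0, pan_noise_sd = 0,
                           surface_texture_amplitude_dn = 0, seed = 1)
  sim <- simulate_scene(cfg)
  r <- render_whale(sim$scene, c(60, 60), 15, 0.3, 0, 0, cfg)
  px <- r$pan_pixels
  # 15 m at 0.5 m gsd: major axis ~30 pan pixels
  expect_equal(diff(range(px[, 2])) + 1, 30, tolerance = 0.05)
  # footprint area within 15% of the ellipse area
  area_m2 <- nrow(px) * 0.5^2
  expect_equal(area_m2, pi * 7.5 * (0.3 * 7.5), tolerance = 0.15)
  # the callus is the brightest pan pixel of the footprint
  vals <- r$scene$pan[px + 1L]
  bright <- px[which.max(vals), ]
  expect_gt(max(vals), cfg$water_mean_dn[9] + cfg$whale_surface_contrast_dn)
  # callus sits at the +u end (east, since orientation 0)
  expect_gt(bright[2], mean(range(px[, 2])))
  expect_error(render_whale(sim$scene, c(60, 60), 20, 0.3, 0, 0, cfg),
               "invalid whale geometry")
})

test_that("confounders render with their distinguishing features", {
  cfg <- simulation_config(ms_shape = c(120, 120), n_whales = 0,
                           n_seabird_clusters = 3, n_boats = 2, n_rocks = 1,
                           n_bubble_slicks = 1, water_noise_sd = 0,
                           pan_noise_sd = 0, surface_texture_amplitude_dn = 0,
                           seed = 8)
  sim <- simulate_scene(cfg)
  ann <- sim$truth$annotations
  expect_equal(nrow(ann), 7)
  expect_setequal(unique(ann$category),
                  c("seabird_cluster", "boat", "rock", "bubble_slick"))
  # boats are brighter than any whale surface pixel could be
  boat_peak <- cfg$water_mean_dn[9] + cfg$whale_surface_contrast_dn +
    cfg$callus_contrast_dn
  expect_gt(max(sim$scene$pan), boat_peak)
  # seabird-only scene: no connected component above 3 pan pixels
  cfg2 <- simulation_config(ms_shape = c(100, 100), n_whales = 0,
                            n_seabird_clusters = 4, water_noise_sd = 0,
                            pan_noise_sd = 0,
                            surface_texture_amplitude_dn = 0, seed = 9)
  sim2 <- simulate_scene(cfg2)
  sizes <- tabulate(label_components(
    sim2$scene$pan > cfg2$water_mean_dn[9], 8))
  expect_lte(max(sizes), 3)
  # zero requested confounders -> no confounder annotations
  sim3 <- simulate_scene(simulation_config(ms_shape = c(40, 40),
                                           n_whales = 1, seed = 2))
  expect_equal(sum(sim3$truth$annotations$category != "whale"), 0)
})

test_that("truth annotations are complete and placement failures raise", {
  cfg <- simulation_config(ms_shape = c(100, 100), n_whales = 6,
                           n_seabird_clusters = 2, n_rocks = 2, seed = 33)
  sim <- simulate_scene(cfg)
  expect_equal(nrow(sim$truth$annotations), 6 + 2 + 2)
  # far too many objects for the extent at 20 m separation
  cramped <- simulation_config(ms_shape = c(30, 30), n_whales = 50,
                               max_place_retries = 50, seed = 1)
  expect_error(simulate_scene(cramped), "placement failure")
})

test_that("whale truth classes follow depth: surface probable, window band5_only", {
  cfg <- simulation_config(seed = 1)
  w <- band5_only_depth_window(cfg)
  deep_cfg <- simulation_config(ms_shape = c(80, 80), n_whales = 6,
                                depth_range_m = unname(w) + c(0.2, -0.2),
                                seed = 13)
  sim <- simulate_scene(deep_cfg)
  expect_true(all(sim$truth$annotations$class_label == "band5_only"))
  surf <- simulate_scene(simulation_config(ms_shape = c(80, 80), n_whales = 6,
                                           depth_range_m = c(0, 0), seed = 13))
  expect_true(all(surf$truth$annotations$class_label == "probable"))
})
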