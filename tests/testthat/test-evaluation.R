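# The published four-method comparison, loaded from the packaged count
# fixtures (counts are inputs; every percentage is recomputed).
load_table1 <- function() {
  counts <- read.csv(system.file("extdata", "table1_counts.csv",
                                 package = "whalesat"))
  ref <- read.csv(system.file("extdata", "table1_reference.csv",
                              package = "whalesat"))
  list(counts = counts, ref_totals = ref$count[match(
    detection_classes(), ref$class_label)])
}

test_that("detections match references one-to-one by nearest centroid", {
  det <- empty_detections()
  det[1:2, c("centroid_x_m", "centroid_y_m")] <- cbind(c(100, 103), c(50, 50))
  det$id <- 1:2
  ref <- as_annotations(data.frame(
    object_id = "a", x_m = 100, y_m = 50, length_m = 10,
    class_label = "probable", stringsAsFactors = FALSE))
  m <- match_detections(det, ref, 10)
  # exactly one of the two nearby detections is matched, the nearer one
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$det_idx, 1)
  expect_equal(m$pairs$dist_m, 0)
  expect_equal(m$unmatched_detections, 2)
  # outside the radius nothing matches
  far <- match_detections(det, within <- transform(ref, x_m = 500), 10)
  expect_equal(nrow(far$pairs), 0)
})

test_that("greedy matching is within one pair of the optimal assignment", {
  set.seed(70)
  for (rep in 1:30) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    axy <- cbind(runif(na, 0, 60), runif(na, 0, 60))
    bxy <- cbind(runif(nb, 0, 60), runif(nb, 0, 60))
    det <- empty_detections()
    det[seq_len(na), c("centroid_x_m", "centroid_y_m")] <- axy
    ref <- as_annotations(data.frame(
      object_id = as.character(seq_len(nb)), x_m = bxy[, 1], y_m = bxy[, 2],
      length_m = 10, class_label = "probable", stringsAsFactors = FALSE))
    got <- nrow(match_detections(det, ref, 10)$pairs)
    opt <- optimal_match_count(axy, bxy, 10)
    expect_lte(opt - got, 1)
    expect_lte(got, opt)
  }
})

test_that("confusion counts split matches by the reference class", {
  set.seed(71)
  cls <- c(rep("probable", 5), rep("possible", 3), rep("band5_only", 2))
  ref <- as_annotations(data.frame(
    object_id = as.character(1:10), x_m = seq(10, 300, length.out = 10),
    y_m = 50, length_m = 10, class_label = cls, stringsAsFactors = FALSE))
  det <- empty_detections()
  # detect the first 4 probables, 2 possibles, 1 band5, plus 3 strays
  hit <- c(1:4, 6:7, 9)
  det[seq_len(10), c("centroid_x_m", "centroid_y_m")] <-
    cbind(c(ref$x_m[hit] + 1, c(500, 520, 540)), 50)
  m <- match_detections(det, ref, 10)
  cc <- confusion_counts(m, ref, "demo")
  expect_equal(cc$probable_matches, 4)
  expect_equal(cc$possible_matches, 2)
  expect_equal(cc$band5_matches, 1)
  expect_equal(cc$false_positives, 3)
  expect_equal(cc$method_total_signals, 10)
  expect_equal(unname(cc$reference_totals), c(5, 3, 2))
  # empty detections: no matches, no false positives
  cc0 <- confusion_counts(match_detections(empty_detections(), ref), ref)
  expect_equal(cc0$method_total_signals, 0)
  expect_equal(cc0$false_positives, 0)
})

test_that("count invariants are enforced", {
  expect_error(as_confusion_counts(list(
    probable_matches = 5, possible_matches = 0, band5_matches = 0,
    false_positives = 0, reference_totals = c(3, 2, 1))),
    "must not exceed")
  expect_error(as_confusion_counts(list(
    probable_matches = 1, possible_matches = 1, band5_matches = 1,
    false_positives = 1, total_signals = 5, reference_totals = c(3, 2, 1))),
    "total_signals")
})

test_that("metrics reproduce the published coastal-band column exactly", {
  t1 <- load_table1()
  row <- t1$counts[t1$counts$method == "threshold_band5", ]
  cc <- as_confusion_counts(c(as.list(row), list(
    reference_totals = t1$ref_totals)))
  m <- compute_metrics(cc)
  expect_equal(m$total_found, 77)
  expect_equal(m$pct_found, 84.6)
  expect_equal(m$pct_of_probable, 89.1)
  expect_equal(m$total_missed, 14)
  expect_equal(m$pct_missed, 15.4)
  expect_equal(m$pct_false_positives, 23.8)
  expect_equal(m$pct_good, 76.2)
})

test_that("metrics reproduce the published iso-means column exactly", {
  t1 <- load_table1()
  row <- t1$counts[t1$counts$method == "isodata", ]
  m <- compute_metrics(as_confusion_counts(c(as.list(row), list(
    reference_totals = t1$ref_totals))))
  expect_equal(m$total_found, 61)
  expect_equal(m$pct_found, 67.0)
  expect_equal(m$pct_false_positives, 61.4)
  expect_equal(m$pct_good, 38.6)
})

test_that("perfect detection gives 100% found and 100% good", {
  m <- compute_metrics(as_confusion_counts(list(
    probable_matches = 55, possible_matches = 23, band5_matches = 13,
    false_positives = 0, reference_totals = c(55, 23, 13))))
  expect_equal(m$pct_found, 100.0)
  expect_equal(m$pct_good, 100.0)
  expect_equal(m$total_missed, 0)
})

test_that("degenerate references and empty outputs are rejected", {
  expect_error(compute_metrics(as_confusion_counts(list(
    probable_matches = 0, possible_matches = 0, band5_matches = 0,
    false_positives = 0, reference_totals = c(0, 0, 0)))),
    "empty reference")
  expect_error(compute_metrics(as_confusion_counts(list(
    probable_matches = 0, possible_matches = 0, band5_matches = 0,
    false_positives = 0, reference_totals = c(5, 3, 1)))),
    "empty method output")
})

test_that("the report lays out all four methods and round-trips as CSV", {
  t1 <- load_table1()
  metrics <- lapply(seq_len(nrow(t1$counts)), function(i) {
    compute_metrics(as_confusion_counts(c(as.list(t1$counts[i, ]), list(
      reference_totals = t1$ref_totals))))
  })
  td <- withr::local_tempdir()
  p <- file.path(td, "report.csv")
  rep <- table1_report(metrics, csv_path = p)
  expect_equal(nrow(rep), 12)
  expect_equal(rep$manual[1:4], c(91, 55, 23, 13))
  back <- read.csv(p, check.names = FALSE)
  expect_equal(back[["threshold_band5"]],
               c(101, 49, 15, 13, 77, 84.6, 89.1, 14, 15.4, 24, 23.8, 76.2))
  expect_equal(back[["kmeans"]][6], 58.2)
  expect_equal(back[["threshold_pan"]][12], 89.1)
  # single-method report renders two numeric columns
  rep1 <- table1_report(metrics[[1]])
  expect_equal(ncol(rep1), 3)  # statistic + manual + method
})

test_that("metrics do not depend on detection order", {
  set.seed(72)
  sim <- simulate_scene(simulation_config(ms_shape = c(80, 80), n_whales = 6,
                                          depth_range_m = c(0, 1), seed = 73))
  det <- detect_whales(sim$scene, "threshold_band5")
  ref <- truth_reference(sim$truth)
  m1 <- compute_metrics(confusion_counts(match_detections(det, ref), ref))
  perm <- det[sample(nrow(det)), , drop = FALSE]
  m2 <- compute_metrics(confusion_counts(match_detections(perm, ref), ref))
  expect_equal(m1$pct_found, m2$pct_found)
  expect_equal(m1$pct_false_positives, m2$pct_false_positives)
})

test_that("half-up rounding follows the published convention", {
  # 23.76 -> 23.8 (the table's value, not the text's truncated 23.7)
  expect_equal(whalesat:::round_half_up(100 * 24 / 101), 23.8)
  expect_equal(whalesat:::round_half_up(10.95), 11.0)
  expect_equal(whalesat:::round_half_up(10.94), 10.9)
})
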