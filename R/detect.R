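## End-to-end detection and three-class labelling.

segment_band <- function(scene, band, threshold = NULL, connectivity = 8,
                         source = paste0("threshold_", band)) {
  g <- scene_band(scene, band)
  thr <- if (is.null(threshold)) {
    opt <- tryCatch(optimize_threshold(g, connectivity = connectivity,
                                       band = band),
                    error = function(e) {
                      if (grepl("no signal", conditionMessage(e)))
                        NULL else stop(e)
                    })
    if (is.null(opt)) {
      # featureless band: nothing exceeds the background median
      out <- empty_detections()
      attr(out, "threshold_dn") <- max(g)
      return(out)
    }
    opt$threshold_dn
  } else threshold
  det <- threshold_segment(
    g, thr, connectivity = connectivity,
    gsd_m = band_gsd(scene, band),
    origin_xy_m = scene$origin_xy_m,
    grid = if (identical(band, "pan")) "pan" else "ms",
    source = source)
  attr(det, "threshold_dn") <- thr
  det
}

greedy_pairs <- function(axy, bxy, radius) {
  # one-to-one greedy pairing by ascending centroid distance
  if (nrow(axy) == 0 || nrow(bxy) == 0)
    return(data.frame(a = integer(), b = integer(), dist_m = numeric()))
  dmat <- sqrt(outer(axy[, 1], bxy[, 1], "-")^2 +
               outer(axy[, 2], bxy[, 2], "-")^2)
  cand <- which(dmat <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(a = integer(), b = integer(), dist_m = numeric()))
  dd <- dmat[cand]
  ord <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; dd <- dd[ord]
  used_a <- logical(nrow(axy)); used_b <- logical(nrow(bxy))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE; keep[i] <- TRUE
    }
  }
  data.frame(a = cand[keep, 1], b = cand[keep, 2], dist_m = dd[keep])
}

#' Assign the three detection classes
#'
#' Formalizes the manual three-class coding for automatic detections.
#' Detections from the panchromatic (or any surface-responding) band are
#' matched one-to-one with coastal-band detections by centroid distance.
#' Objects that pass the whale size/shape filter with adequate contrast are
#' "probable"; objects failing shape criteria, single pixels, or weak
#' signals are "possible"; coastal-band detections with no panchromatic
#' counterpart are "band5_only" — the subsurface class that can never be
#' "probable".
#'
#' @param pan_detections `whale_detections` from a surface band.
#' @param band5_detections `whale_detections` from the coastal band.
#' @param match_radius_m counterpart matching radius, metres.
#' @param min_len_m,max_len_m,max_aspect,min_pixels shape-filter settings.
#' @param weak_contrast_sigma contrast (in background sd units) below which
#'   a shape-passing object is still only "possible".
#' @param primary which detection list the returned objects come from:
#'   `"pan"` (surface method; unmatched coastal detections are not its
#'   signals and are dropped) or `"band5"` (coastal method; all its
#'   detections are returned, unmatched ones as "band5_only").
#' @return A classed `whale_detections` data.frame (shape-rejected objects
#'   such as boats are removed).
#' @export
classify_detections <- function(pan_detections, band5_detections,
                                match_radius_m = 10,
                                min_len_m = 5, max_len_m = 16,
                                max_aspect = 6, min_pixels = 2,
                                weak_contrast_sigma = 2,
                                primary = c("band5", "pan")) {
  primary <- match.arg(primary)
  prim <- if (primary == "pan") pan_detections else band5_detections
  other <- if (primary == "pan") band5_detections else pan_detections
  sf <- shape_filter(prim, min_len_m, max_len_m, max_aspect, min_pixels)
  kept <- sf$kept
  if (nrow(kept) == 0) return(kept)
  pairs <- greedy_pairs(
    cbind(kept$centroid_x_m, kept$centroid_y_m),
    if (nrow(other)) cbind(other$centroid_x_m, other$centroid_y_m)
    else matrix(numeric(0), ncol = 2),
    match_radius_m)
  has_counterpart <- seq_len(nrow(kept)) %in% pairs$a
  cls <- ifelse(kept$shape_pass & kept$contrast_sigma >= weak_contrast_sigma,
                "probable", "possible")
  if (primary == "band5") cls[!has_counterpart] <- "band5_only"
  kept$detection_class <- cls
  kept
}

#' Detect whale-like objects in a scene
#'
#' End-to-end automatic detection: segment (by the chosen method), extract
#' connected components, filter to whale size and shape, and label each
#' detection probable / possible / band5_only. Deterministic given the
#' scene and settings.
#'
#' Methods:
#' \describe{
#'   \item{`threshold_pan`}{optimized thresholding of the panchromatic
#'     band (0.5 m); surface features only.}
#'   \item{`threshold_band5`}{optimized thresholding of the coastal band
#'     (2 m), the water-penetrating method; coastal detections with no
#'     panchromatic counterpart are classed "band5_only".}
#'   \item{`kmeans`, `isodata`}{unsupervised classification of the 8-band
#'     MS stack; bright non-water clusters become the candidate mask.}
#'   \item{`maxlike`}{maximum-likelihood classification of the MS stack
#'     from water/whale signatures (supply `signatures`, or `truth`
#'     annotations to derive them from).}
#' }
#'
#' @param scene a `multiband_scene`.
#' @param method one of `"threshold_pan"`, `"threshold_band5"`, `"kmeans"`,
#'   `"isodata"`, `"maxlike"`.
#' @param threshold fixed DN threshold; `NULL` (default) optimizes it via
#'   [optimize_threshold()].
#' @param connectivity component connectivity, 4 or 8.
#' @param k clusters for the unsupervised methods.
#' @param signatures list of [class_signature()] for `maxlike`.
#' @param truth optional `scene_truth` used to derive `maxlike` signatures.
#' @param match_radius_m,min_len_m,max_len_m,max_aspect,min_pixels,weak_contrast_sigma
#'   passed to [classify_detections()].
#' @param candidate_k_sd brightness margin for [cluster_to_candidates()].
#' @return A classed `whale_detections` data.frame; attribute
#'   `threshold_dn` records any threshold used.
#' @export
detect_whales <- function(scene,
                          method = c("threshold_band5", "threshold_pan",
                                     "kmeans", "isodata", "maxlike"),
                          threshold = NULL, connectivity = 8, k = 5,
                          signatures = NULL, truth = NULL,
                          match_radius_m = 10, min_len_m = 5, max_len_m = 16,
                          max_aspect = 6, min_pixels = 2,
                          weak_contrast_sigma = 2, candidate_k_sd = 2) {
  method <- match.arg(method)
  thr_used <- NA_real_

  if (method %in% c("threshold_pan", "threshold_band5")) {
    if (method == "threshold_pan") {
      pan_det <- segment_band(scene, "pan", threshold, connectivity,
                              source = "threshold_pan")
      thr_used <- attr(pan_det, "threshold_dn")
      b5_det <- empty_detections()
      out <- classify_detections(pan_det, b5_det, match_radius_m,
                                 min_len_m, max_len_m, max_aspect,
                                 min_pixels, weak_contrast_sigma,
                                 primary = "pan")
    } else {
      b5_det <- segment_band(scene, 5, threshold, connectivity,
                             source = "threshold_band5")
      thr_used <- attr(b5_det, "threshold_dn")
      pan_det <- tryCatch(
        segment_band(scene, "pan", NULL, connectivity, source = "aux_pan"),
        error = function(e) empty_detections())
      out <- classify_detections(pan_det, b5_det, match_radius_m,
                                 min_len_m, max_len_m, max_aspect,
                                 min_pixels, weak_contrast_sigma,
                                 primary = "band5")
    }
  } else {
    labels <- switch(method,
      kmeans = kmeans_segment(scene$ms, k = k),
      isodata = isodata_segment(scene$ms, k_init = k,
                                min_cluster_size = 16, split_sd = 12,
                                merge_dist = 4),
      maxlike = {
        if (is.null(signatures)) {
          if (is.null(truth))
            stop("maxlike needs 'signatures' or 'truth' annotations")
          signatures <- signatures_from_annotations(
            scene, truth_reference(truth))
        }
        maxlike_segment(scene$ms, signatures)
      })
    intensity <- apply(scene$ms, c(1, 2), mean)
    mask <- cluster_to_candidates(labels, intensity, k_sd = candidate_k_sd)
    comp <- label_components(mask, connectivity)
    det <- components_to_detections(
      comp, intensity, ms_gsd(scene), scene$origin_xy_m, "ms", method,
      bg_med = median(intensity[!mask]),
      bg_sd = stats::mad(intensity[!mask]))
    out <- classify_detections(det, empty_detections(), match_radius_m,
                               min_len_m, max_len_m, max_aspect,
                               min_pixels, weak_contrast_sigma,
                               primary = "pan")
    ## a cluster detection whose contrast lives only in the coastal band is
    ## a subsurface feature
    if (nrow(out) > 0) {
      med <- vapply(1:8, function(b) median(scene$ms[, , b]), numeric(1))
      bsd <- vapply(1:8, function(b) stats::mad(scene$ms[, , b]), numeric(1))
      others <- setdiff(1:8, 5)
      for (i in seq_len(nrow(out))) {
        idx <- out$pixels[[i]] + 1L
        contr <- vapply(1:8, function(b) {
          mean(scene$ms[, , b][idx]) - med[b]
        }, numeric(1))
        if (bsd[5] > 0 && contr[5] >= 2 * bsd[5] &&
            all(contr[others] < bsd[others]))
          out$detection_class[i] <- "band5_only"
      }
    }
  }
  attr(out, "threshold_dn") <- thr_used
  attr(out, "method") <- method
  out
}
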