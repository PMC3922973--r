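## Scoring automatic detections against manually digitized reference
## annotations, with the exact arithmetic that regenerates the published
## comparison-table percentages from its count rows.

round_half_up <- function(x, digits = 1) {
  # round-half-up (53.45 -> 53.5), unlike R's round-half-even
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Match detections to reference annotations
#'
#' One-to-one greedy pairing by ascending centroid distance, cut at
#' `match_radius_m`: each detection and each reference object is used at
#' most once. Greedy nearest-first matching is order-stable and within one
#' pair of the optimal assignment at realistic whale densities.
#'
#' @param detections `whale_detections` (needs `centroid_x_m/_y_m`).
#' @param reference annotation data.frame (needs `x_m`, `y_m`).
#' @param match_radius_m maximum pairing distance, metres (default 10 m,
#'   about a whale half-length plus an MS pixel of slack).
#' @return `list(pairs, unmatched_detections, unmatched_reference,
#'   n_detections, n_reference)` of class `detection_matching`; `pairs` has
#'   columns `det_idx`, `ref_idx`, `dist_m`.
#' @export
match_detections <- function(detections, reference, match_radius_m = 10) {
  axy <- if (nrow(detections))
    cbind(detections$centroid_x_m, detections$centroid_y_m)
  else matrix(numeric(0), ncol = 2)
  bxy <- if (nrow(reference)) cbind(reference$x_m, reference$y_m)
  else matrix(numeric(0), ncol = 2)
  pr <- greedy_pairs(axy, bxy, match_radius_m)
  structure(
    list(pairs = data.frame(det_idx = pr$a, ref_idx = pr$b,
                            dist_m = pr$dist_m),
         unmatched_detections = setdiff(seq_len(nrow(detections)), pr$a),
         unmatched_reference = setdiff(seq_len(nrow(reference)), pr$b),
         n_detections = nrow(detections), n_reference = nrow(reference)),
    class = "detection_matching")
}

#' Tally a matching into confusion counts
#'
#' Matched detections are split by the reference object's manual class (a
#' match counts toward the class the digitizer gave it, not the detector's
#' own label); unmatched detections are false positives.
#'
#' @param matching a `detection_matching` from [match_detections()].
#' @param reference the annotation data.frame the matching was made against.
#' @param method method name recorded on the result.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(matching, reference, method = "method") {
  cls <- reference$class_label[matching$pairs$ref_idx]
  ref_tot <- table(factor(reference$class_label,
                          levels = detection_classes()))
  as_confusion_counts(list(
    method = method,
    probable_matches = sum(cls == "probable"),
    possible_matches = sum(cls == "possible"),
    band5_matches = sum(cls == "band5_only"),
    false_positives = length(matching$unmatched_detections),
    reference_totals = as.integer(ref_tot)))
}

#' Construct confusion counts directly
#'
#' Builds the count object from already-tallied numbers, e.g. the printed
#' count rows of a published comparison table.
#'
#' @param x list (or single-row data.frame) with `probable_matches`,
#'   `possible_matches`, `band5_matches`, `false_positives`,
#'   `reference_totals` (length 3: probable, possible, band5_only), and
#'   optionally `method` and `total_signals` (validated if supplied).
#' @return A `confusion_counts` object.
#' @export
as_confusion_counts <- function(x) {
  need <- c("probable_matches", "possible_matches", "band5_matches",
            "false_positives", "reference_totals")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing count fields: ", paste(miss, collapse = ", "))
  ref <- as.integer(unlist(x$reference_totals))
  if (length(ref) != 3) stop("reference_totals must have 3 entries")
  matches <- c(x$probable_matches, x$possible_matches, x$band5_matches)
  if (any(matches > ref))
    stop("each match count must not exceed its reference total")
  total <- sum(matches) + x$false_positives
  if (!is.null(x$total_signals) && x$total_signals != total)
    stop(sprintf("total_signals (%d) != matches + false positives (%d)",
                 x$total_signals, total))
  structure(
    list(method = if (is.null(x$method)) "method" else x$method,
         method_total_signals = as.integer(total),
         probable_matches = as.integer(x$probable_matches),
         possible_matches = as.integer(x$possible_matches),
         band5_matches = as.integer(x$band5_matches),
         false_positives = as.integer(x$false_positives),
         reference_totals = stats::setNames(ref, detection_classes())),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s: %d signals\n", x$method,
              x$method_total_signals))
  cat(sprintf("  matches: %d probable, %d possible, %d band-5; %d false positives\n",
              x$probable_matches, x$possible_matches, x$band5_matches,
              x$false_positives))
  cat(sprintf("  reference: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$reference_totals),
                            x$reference_totals), collapse = ", "),
              sum(x$reference_totals)))
  invisible(x)
}

#' Detection metrics from confusion counts
#'
#' The published arithmetic: percentages of matches are taken over the
#' manual reference grand total, the probable percentage over the manual
#' probable total, and the false-positive percentage over the method's own
#' total signals; `pct_good` is its complement. All percentages are rounded
#' half-up to one decimal.
#'
#' @param counts a `confusion_counts` object.
#' @return A `whale_metrics` object: `total_found`, `pct_found`,
#'   `pct_of_probable`, `total_missed`, `pct_missed`,
#'   `pct_false_positives`, `pct_good`, plus the input counts.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  grand <- sum(counts$reference_totals)
  if (grand == 0) stop("empty reference")
  if (counts$method_total_signals == 0) stop("empty method output")
  total_found <- counts$probable_matches + counts$possible_matches +
    counts$band5_matches
  structure(
    list(method = counts$method,
         counts = counts,
         total_found = total_found,
         pct_found = round_half_up(100 * total_found / grand),
         pct_of_probable = unname(round_half_up(
           100 * counts$probable_matches /
             counts$reference_totals[["probable"]])),
         total_missed = grand - total_found,
         pct_missed = round_half_up(100 * (grand - total_found) / grand),
         pct_false_positives = round_half_up(
           100 * counts$false_positives / counts$method_total_signals),
         pct_good = round_half_up(
           100 - 100 * counts$false_positives / counts$method_total_signals)),
    class = "whale_metrics")
}

#' @export
print.whale_metrics <- function(x, ...) {
  cat(sprintf("<whale_metrics> %s\n", x$method))
  cat(sprintf("  found %d/%d (%.1f%%), %.1f%% of probable; missed %d (%.1f%%)\n",
              x$total_found, sum(x$counts$reference_totals), x$pct_found,
              x$pct_of_probable, x$total_missed, x$pct_missed))
  cat(sprintf("  false positives %d (%.1f%%); %.1f%% good\n",
              x$counts$false_positives, x$pct_false_positives, x$pct_good))
  invisible(x)
}

table1_rows <- c("total signals", "probable matches", "possible matches",
                 "band 5 matches", "total found", "% found", "% of probable",
                 "total missed", "% missed", "false positives",
                 "% false positives", "% good")

#' Render the method-comparison table
#'
#' The 12-row layout comparing detection methods against the manual
#' reference: the four count rows, the derived totals, and the five
#' percentage rows, with the manual class totals as the leading column.
#'
#' @param metrics a `whale_metrics` object or (possibly named) list of them.
#' @param csv_path optional path; the table is also written as CSV.
#' @return A `detection_report` data.frame (rows = statistics, one column
#'   per method plus the manual reference).
#' @export
table1_report <- function(metrics, csv_path = NULL) {
  if (inherits(metrics, "whale_metrics")) metrics <- list(metrics)
  if (length(metrics) < 1) stop("need at least one method")
  ref <- metrics[[1]]$counts$reference_totals
  for (m in metrics)
    if (!identical(m$counts$reference_totals, ref))
      stop("metrics were computed against different references")
  manual <- c(sum(ref), ref[["probable"]], ref[["possible"]],
              ref[["band5_only"]], rep(NA, 8))
  cols <- lapply(metrics, function(m) {
    c(m$counts$method_total_signals, m$counts$probable_matches,
      m$counts$possible_matches, m$counts$band5_matches,
      m$total_found, m$pct_found, m$pct_of_probable,
      m$total_missed, m$pct_missed, m$counts$false_positives,
      m$pct_false_positives, m$pct_good)
  })
  names(cols) <- vapply(metrics, function(m) m$method, "")
  out <- data.frame(statistic = table1_rows, manual = manual, cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("detection_report", "data.frame")
  if (!is.null(csv_path)) write.csv(out, csv_path, row.names = FALSE, na = "")
  out
}

#' @export
print.detection_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- df[, -1, drop = FALSE]
  fmt <- apply(num, 2, function(v) ifelse(is.na(v), "",
                                          formatC(v, format = "g")))
  fmt <- matrix(fmt, nrow = nrow(df), dimnames = dimnames(num))
  wid <- max(nchar(df$statistic))
  cw <- pmax(8, nchar(colnames(num)))
  pad <- function(v) paste(vapply(seq_along(v), function(j)
    formatC(v[j], width = cw[j]), ""), collapse = "  ")
  cat(formatC("", width = wid), " ", pad(colnames(num)), "\n", sep = "")
  for (i in seq_len(nrow(df)))
    cat(formatC(df$statistic[i], width = wid, flag = "-"), " ",
        pad(fmt[i, ]), "\n", sep = "")
  invisible(x)
}
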