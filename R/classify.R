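## Per-pixel classifiers: the unsupervised and supervised baselines the
## thresholding method is compared against.

as_pixel_matrix <- function(x) {
  if (is.matrix(x)) {
    list(X = matrix(as.numeric(x), ncol = 1), dims = dim(x))
  } else if (length(dim(x)) == 3) {
    d <- dim(x)
    list(X = matrix(as.numeric(x), nrow = d[1] * d[2], ncol = d[3]),
         dims = d[1:2])
  } else stop("'x' must be a matrix (one band) or a rows x cols x bands array")
}

## Evenly spaced initial means along the diagonal of the data range: the
## deterministic initialization described for the k-means baseline, so no
## seed is involved in classification.
even_init_means <- function(X, k) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  tt <- if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
  m <- vapply(tt, function(t) lo + t * (hi - lo), numeric(ncol(X)))
  matrix(m, nrow = k, ncol = ncol(X), byrow = TRUE)
}

assign_nearest <- function(X, means) {
  # squared Euclidean distance to each mean, vectorized
  d2 <- outer(rowSums(X^2), rep(1, nrow(means))) -
    2 * X %*% t(means) +
    outer(rep(1, nrow(X)), rowSums(means^2))
  max.col(-d2, ties.method = "first")
}

within_ss <- function(X, means, lab) {
  sum((X - means[lab, , drop = FALSE])^2)
}

#' k-means pixel classification
#'
#' Lloyd iterations with deterministic initial means evenly distributed in
#' the data space (along the diagonal from the per-band minimum to maximum),
#' iterating assignment to the nearest class mean until the means move less
#' than `tol` or `max_iter` is reached. Empty clusters are dropped
#' deterministically with a warning.
#'
#' @param x DN matrix (one band) or `rows x cols x bands` array.
#' @param k number of clusters.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the largest mean displacement, DN.
#' @return Integer label matrix with attributes `means` (cluster x band),
#'   `objective` (within-cluster sum of squares after each assignment;
#'   non-increasing), and `iterations`.
#' @export
kmeans_segment <- function(x, k = 5, max_iter = 100, tol = 1e-4) {
  if (k < 1) stop("k must be >= 1")
  pm <- as_pixel_matrix(x)
  X <- pm$X
  if (k > nrow(unique(X)))
    warning("k exceeds the number of distinct pixel values; empty clusters will be dropped")
  means <- even_init_means(X, k)
  obj <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    lab <- assign_nearest(X, means)
    sizes <- tabulate(lab, nrow(means))
    if (any(sizes == 0)) {
      warning("dropping ", sum(sizes == 0), " empty cluster(s)")
      keep <- which(sizes > 0)
      means <- means[keep, , drop = FALSE]
      lab <- assign_nearest(X, means)
      sizes <- tabulate(lab, nrow(means))
    }
    obj <- c(obj, within_ss(X, means, lab))
    new_means <- rowsum(X, lab) / sizes
    shift <- max(abs(new_means - means))
    means <- new_means
    if (shift < tol || iter >= max_iter) break
  }
  lab <- assign_nearest(X, means)
  obj <- c(obj, within_ss(X, means, lab))
  out <- matrix(lab, pm$dims[1], pm$dims[2])
  attr(out, "means") <- means
  attr(out, "objective") <- obj
  attr(out, "iterations") <- iter
  out
}

#' ISODATA pixel classification
#'
#' The self-organizing variant of k-means used as the second unsupervised
#' baseline: a k-means core augmented with structural moves that find the
#' natural grouping of the data — clusters smaller than `min_cluster_size`
#' are discarded, clusters whose largest per-band standard deviation
#' exceeds `split_sd` are split in two along that band, and cluster pairs
#' whose means are closer than `merge_dist` are merged. With splitting and
#' merging disabled (`split_sd = Inf`, `merge_dist = 0`,
#' `min_cluster_size <= 1`) the procedure reduces exactly to
#' [kmeans_segment()].
#'
#' @param x DN matrix or `rows x cols x bands` array.
#' @param k_init initial number of clusters.
#' @param max_iter maximum outer iterations.
#' @param min_cluster_size clusters smaller than this are discarded.
#' @param split_sd split threshold on the per-band standard deviation, DN.
#' @param merge_dist merge threshold on the distance between means, DN.
#' @param tol convergence tolerance on mean displacement, DN.
#' @return Integer label matrix with attributes as in [kmeans_segment()].
#' @export
isodata_segment <- function(x, k_init = 5, max_iter = 100,
                            min_cluster_size = 1, split_sd = Inf,
                            merge_dist = 0, tol = 1e-4) {
  if (k_init < 1) stop("k_init must be >= 1")
  if (min_cluster_size < 0 || merge_dist < 0) stop("parameters must be positive")
  pm <- as_pixel_matrix(x)
  X <- pm$X
  means <- even_init_means(X, k_init)
  obj <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    lab <- assign_nearest(X, means)
    sizes <- tabulate(lab, nrow(means))
    drop <- sizes == 0 | (sizes < min_cluster_size & nrow(means) > 1)
    if (any(drop)) {
      if (any(sizes == 0)) warning("dropping ", sum(sizes == 0), " empty cluster(s)")
      means <- means[!drop, , drop = FALSE]
      lab <- assign_nearest(X, means)
      sizes <- tabulate(lab, nrow(means))
    }
    obj <- c(obj, within_ss(X, means, lab))
    new_means <- rowsum(X, lab) / sizes
    shift <- max(abs(new_means - means))
    means <- new_means
    structural <- FALSE

    ## split clusters with excessive spread
    if (is.finite(split_sd)) {
      add <- list()
      for (i in seq_len(nrow(means))) {
        sel <- lab == i
        if (sum(sel) < 2 * max(min_cluster_size, 2)) next
        sds <- apply(X[sel, , drop = FALSE], 2, sd)
        j <- which.max(sds)
        if (sds[j] > split_sd) {
          off <- numeric(ncol(X)); off[j] <- 0.5 * sds[j]
          add[[length(add) + 1]] <- rbind(means[i, ] - off, means[i, ] + off)
          means[i, ] <- NA
          structural <- TRUE
        }
      }
      if (length(add))
        means <- rbind(means[!is.na(means[, 1]), , drop = FALSE],
                       do.call(rbind, add))
    }

    ## merge clusters with close means (closest pair first)
    if (merge_dist > 0 && nrow(means) > 1) {
      repeat {
        dm <- as.matrix(stats::dist(means))
        dm[upper.tri(dm, diag = TRUE)] <- Inf
        if (min(dm) >= merge_dist) break
        ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]  # row > col
        hi <- ij[1]; lo <- ij[2]
        s <- sizes[c(hi, lo)]
        if (sum(s) == 0) s <- c(1, 1)
        means[lo, ] <- (s[1] * means[hi, ] + s[2] * means[lo, ]) / sum(s)
        sizes[lo] <- sum(sizes[c(hi, lo)])
        means <- means[-hi, , drop = FALSE]
        sizes <- sizes[-hi]
        structural <- TRUE
        if (nrow(means) == 1) break
      }
    }

    if ((!structural && shift < tol) || iter >= max_iter) break
  }
  lab <- assign_nearest(X, means)
  obj <- c(obj, within_ss(X, means, lab))
  out <- matrix(lab, pm$dims[1], pm$dims[2])
  attr(out, "means") <- means
  attr(out, "objective") <- obj
  attr(out, "iterations") <- iter
  out
}

## ---- maximum likelihood ----------------------------------------------------

#' Class signature for supervised classification
#'
#' @param class_name class label.
#' @param mean_dn_per_band numeric mean vector.
#' @param covariance covariance matrix of DN across bands (symmetric
#'   positive semi-definite).
#' @return Object of class `class_signature`.
#' @export
class_signature <- function(class_name, mean_dn_per_band, covariance) {
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))))
    stop("covariance must be symmetric")
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <
          -1e-8 * max(abs(covariance), 1)))
    stop("covariance must be positive semi-definite")
  structure(list(class_name = class_name,
                 mean_dn_per_band = as.numeric(mean_dn_per_band),
                 covariance = covariance),
            class = "class_signature")
}

#' Maximum-likelihood supervised classification
#'
#' Assigns every pixel to the class whose multivariate-normal signature
#' gives it the highest log-likelihood. Singular covariances are
#' ridge-regularized (a small multiple of the mean diagonal added) with a
#' warning.
#'
#' @param x DN matrix or `rows x cols x bands` array.
#' @param signatures list of [class_signature()] objects (at least 2).
#' @param ridge_eps relative ridge used when a covariance is singular.
#' @return Integer label matrix (index into `signatures`) with attribute
#'   `classes` (the class names).
#' @export
maxlike_segment <- function(x, signatures, ridge_eps = 1e-6) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  pm <- as_pixel_matrix(x)
  X <- pm$X
  ll <- matrix(-Inf, nrow(X), length(signatures))
  for (j in seq_along(signatures)) {
    sig <- signatures[[j]]
    mu <- sig$mean_dn_per_band
    S <- sig$covariance
    if (length(mu) != ncol(X))
      stop("signature dimension does not match the number of bands")
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      warning("singular covariance for class '", sig$class_name,
              "'; ridge-regularized")
      S <- S + diag(mean(diag(S)) * ridge_eps + 1e-12, ncol(S))
      ch <- chol(S)
    }
    Z <- backsolve(ch, t(X) - mu, transpose = TRUE)
    maha <- colSums(Z^2)
    logdet <- 2 * sum(log(diag(ch)))
    ll[, j] <- -0.5 * (maha + logdet + ncol(X) * log(2 * pi))
  }
  lab <- max.col(ll, ties.method = "first")
  out <- matrix(lab, pm$dims[1], pm$dims[2])
  attr(out, "classes") <- vapply(signatures, `[[`, "", "class_name")
  out
}

#' Derive class signatures from annotations
#'
#' Builds a water signature from pixels away from any annotated object and
#' a whale signature from pixels near annotation centroids, for use with
#' [maxlike_segment()] on the MS stack.
#'
#' @param scene a `multiband_scene`.
#' @param annotations annotation data.frame (whale-like rows are used).
#' @param radius_m radius around each centroid sampled as object pixels.
#' @return list of two [class_signature()] objects, `water` and `whale`.
#' @export
signatures_from_annotations <- function(scene, annotations, radius_m = 4) {
  d <- dim(scene$ms)
  X <- matrix(as.numeric(scene$ms), nrow = d[1] * d[2], ncol = 8)
  obj_idx <- integer(0)
  ann <- annotations[!is.na(annotations$class_label), , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    px <- ellipse_pixels(scene, "ms", c(ann$x_m[i], ann$y_m[i]),
                         radius_m, radius_m, 0)
    obj_idx <- c(obj_idx, px$row + (px$col - 1) * d[1])
  }
  obj_idx <- unique(obj_idx)
  if (length(obj_idx) < 9) stop("too few annotated pixels for a signature")
  water_idx <- setdiff(seq_len(nrow(X)), obj_idx)
  list(water = class_signature("water", colMeans(X[water_idx, ]),
                               cov(X[water_idx, ])),
       whale = class_signature("whale", colMeans(X[obj_idx, ]),
                               cov(X[obj_idx, ])))
}

#' Reduce a cluster map to a candidate mask
#'
#' Identifies the water background as the modal (largest) cluster and
#' selects every cluster whose mean intensity exceeds the water mean by
#' `k_sd` background standard deviations; the union of those clusters,
#' intersected with pixels above the water mean, is the binary candidate
#' mask fed to component extraction.
#'
#' @param labels integer label matrix from a classifier.
#' @param intensity DN matrix on the same grid used to score clusters.
#' @param k_sd brightness margin in background standard deviations.
#' @return Logical candidate mask (possibly empty).
#' @export
cluster_to_candidates <- function(labels, intensity, k_sd = 2) {
  if (!identical(dim(labels), dim(intensity)))
    stop("resolution mismatch: labels and intensity grids differ in shape")
  sizes <- tabulate(labels, max(labels))
  water <- which.max(sizes)
  water_px <- intensity[labels == water]
  water_mean <- mean(water_px)
  water_sd <- sd(water_px)
  keep <- integer(0)
  for (l in seq_len(max(labels))) {
    if (l == water || sizes[l] == 0) next
    if (mean(intensity[labels == l]) > water_mean + k_sd * water_sd)
      keep <- c(keep, l)
  }
  mask <- matrix(labels %in% keep, nrow(labels), ncol(labels))
  mask & intensity > water_mean
}
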