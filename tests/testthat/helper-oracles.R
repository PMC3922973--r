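# Independent oracles, deliberately implemented with different machinery
# than the package internals (BFS flood fill, igraph graph components,
# per-pixel likelihood loops, exhaustive/optimal search).

# Breadth-first flood fill labelling, pure R.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nbr <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nbr <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] > 0) next
    lab <- lab + 1L
    queue <- list(c(i, j))
    labels[i, j] <- lab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        ni <- p[1] + nbr[k, 1]; nj <- p[2] + nbr[k, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && labels[ni, nj] == 0) {
          labels[ni, nj] <- lab
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  labels
}

# Component sizes via igraph: vertices are foreground pixels, edges join
# adjacent foreground pixels.
igraph_component_sizes <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- (idx - 1L) %% nr; ci <- (idx - 1L) %/% nr   # 0-based
  lut <- rep(NA_integer_, nr * nc)
  lut[idx] <- seq_along(idx)
  offs <- if (connectivity == 8)
    list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1)) else list(c(1, 0), c(0, 1))
  edges <- integer(0)
  for (o in offs) {
    r2 <- ri + o[1]; c2 <- ci + o[2]
    ok <- r2 >= 0 & r2 < nr & c2 >= 0 & c2 < nc
    j <- lut[c2[ok] * nr + r2[ok] + 1L]
    i <- seq_along(idx)[ok][!is.na(j)]
    j <- j[!is.na(j)]
    if (length(i)) edges <- c(edges, rbind(i, j))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  as.integer(table(igraph::components(g)$membership))
}

# Exhaustive threshold search with the igraph labeller, applying the same
# eligibility rule as the package (candidates keeping more than max_fill of
# the pixels are background-percolation regimes and excluded).
exhaustive_threshold <- function(x, candidates, connectivity = 8,
                                 max_fill = 0.05) {
  stats <- t(vapply(candidates, function(t) {
    sz <- igraph_component_sizes(x > t, connectivity)
    c(multi = sum(sz >= 2), single = sum(sz == 1))
  }, c(multi = 0, single = 0)))
  ratio <- stats[, "multi"] / pmax(stats[, "single"], 1)
  fill <- vapply(candidates, function(t) mean(x > t), numeric(1))
  eligible <- fill <= max_fill
  if (!any(eligible)) eligible <- fill <= min(fill)
  r_el <- ifelse(eligible, ratio, -Inf)
  best <- max(which(r_el == max(r_el)))
  list(threshold = candidates[best], ratio = ratio[best],
       multi = stats[best, "multi"], single = stats[best, "single"])
}

# Per-pixel multivariate normal log density, naive loop.
naive_mvn_loglik <- function(x, mu, S) {
  p <- length(mu)
  d <- x - mu
  -0.5 * (t(d) %*% solve(S) %*% d + log(det(S)) + p * log(2 * pi))[1, 1]
}

# Maximum-cardinality matching within a radius via igraph bipartite
# matching; gives the optimal number of pairs greedy matching is compared
# against.
optimal_match_count <- function(axy, bxy, radius) {
  if (nrow(axy) == 0 || nrow(bxy) == 0) return(0L)
  dmat <- sqrt(outer(axy[, 1], bxy[, 1], "-")^2 +
               outer(axy[, 2], bxy[, 2], "-")^2)
  cand <- which(dmat <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  na <- nrow(axy)
  g <- igraph::make_graph(t(cbind(cand[, 1], na + cand[, 2])),
                          n = na + nrow(bxy), directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, na), rep(TRUE, nrow(bxy)))
  igraph::max_bipartite_match(g)$matching_size
}

# Small ready-made configs used across tests.
quiet_config <- function(...) {
  simulation_config(ms_shape = c(60, 60), water_noise_sd = 0,
                    pan_noise_sd = 0, surface_texture_amplitude_dn = 0,
                    n_whales = 0, ...)
}

default_small_config <- function(...) {
  simulation_config(ms_shape = c(100, 100), ...)
}
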