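# shared fixtures: small scenes and hand-built rasters

small_scene_config <- function(...) {
  scene_config(width = 320, height = 320, n_stars = 5,
               disc_radius_range = c(9, 14),
               arm_length_range = c(20, 32),
               min_center_separation = 60, seed = 1L, ...)
}

# an axis-aligned filled rectangle polygon (pixel-centre coordinates)
rect_polygon <- function(x0, y0, x1, y1, variant = "disc") {
  polygon_annotation(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
                     variant = variant)
}

# binary matrix with a filled circle
disc_mask <- function(H, W, cy, cx, r) {
  m <- matrix(0L, H, W)
  for (row in seq_len(H)) {
    d2 <- r^2 - (row - 1 - cy)^2
    if (d2 < 0) next
    lo <- ceiling(cx - sqrt(d2)); hi <- floor(cx + sqrt(d2))
    lo <- max(0, lo); hi <- min(W - 1, hi)
    if (hi >= lo) m[row, (lo + 1):(hi + 1)] <- 1L
  }
  m
}

# brute-force Euclidean distance transform (independent oracle)
edt_bruteforce <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, H, W)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(bg) == 0) return(out + Inf)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# independent two-seed flood fill on -EDT for watershed cross-checks:
# iterative uniform-cost growth assigning each pixel to the seed reached
# with the smallest maximum elevation along the path (computed by
# Dijkstra on the elevation surface)
flood_from_seeds <- function(mask, seeds_rc, elev) {
  H <- nrow(mask); W <- ncol(mask)
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  # O(n^2) Dijkstra on the elevation surface (fixtures are small)
  dist <- matrix(Inf, H, W)
  lab2 <- matrix(0L, H, W)
  visited <- matrix(FALSE, H, W)
  for (s in seq_len(nrow(seeds_rc))) {
    r <- seeds_rc[s, 1]; c <- seeds_rc[s, 2]
    dist[r, c] <- elev[r, c]
    lab2[r, c] <- s
  }
  repeat {
    idx <- which(!visited & is.finite(dist))
    if (length(idx) == 0) break
    i <- idx[which.min(dist[idx])]
    visited[i] <- TRUE
    r <- (i - 1) %% H + 1; c <- (i - 1) %/% H + 1
    for (k in 1:8) {
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (mask[r2, c2] == 0 || visited[r2, c2]) next
      nd <- max(dist[r, c], elev[r2, c2])
      if (nd < dist[r2, c2]) {
        dist[r2, c2] <- nd
        lab2[r2, c2] <- lab2[r, c]
      }
    }
  }
  lab2
}
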