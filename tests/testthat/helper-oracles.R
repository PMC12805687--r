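# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (O(n^2), explicit loops) so they check the optimized
# implementations rather than mirroring them.

# all-pairs Euclidean distance from every voxel to the nearest TRUE voxel
brute_edt <- function(feature, voxel_size = 1) {
  d <- dim(feature)
  idx <- which(feature)
  stopifnot(length(idx) > 0)
  fc <- arrayInd(idx, d)
  out <- array(NA_real_, d)
  all_c <- arrayInd(seq_len(prod(d)), d)
  for (i in seq_len(prod(d))) {
    dd <- (fc[, 1] - all_c[i, 1])^2 + (fc[, 2] - all_c[i, 2])^2 +
      (fc[, 3] - all_c[i, 3])^2
    out[i] <- sqrt(min(dd))
  }
  out * voxel_size
}

# quadratic fixed-radius neighbor counts (inclusive boundary)
brute_neighbors <- function(coords, radius) {
  n <- nrow(coords)
  cnt <- integer(n)
  if (n < 2) return(cnt)
  dm <- as.matrix(dist(coords))
  for (i in seq_len(n)) cnt[i] <- sum(dm[i, -i] <= radius)
  cnt
}

# connected components by breadth-first flood fill, labels in order of
# first (column-major) voxel occurrence
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- arrayInd(start, d)
    lab[start] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(off))) {
        w <- v + unlist(off[r, ])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (standard doubled one-sided convention, capped at 1)
enum_mann_whitney <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  splits <- combn(length(pool), n1)
  us <- apply(splits, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  uo <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = uo, p = min(1, 2 * min(mean(us <= uo), mean(us >= uo))))
}

# voxel-center-in-sphere mask, written independently of the package
sphere_mask <- function(dims, centers, diams, voxel_size) {
  m <- array(FALSE, dims)
  cc <- arrayInd(seq_len(prod(dims)), dims)
  for (i in seq_len(nrow(centers))) {
    d2 <- ((cc[, 1] - 1) * voxel_size - centers[i, 1])^2 +
      ((cc[, 2] - 1) * voxel_size - centers[i, 2])^2 +
      ((cc[, 3] - 1) * voxel_size - centers[i, 3])^2
    m[d2 <= (diams[i] / 2)^2] <- TRUE
  }
  m
}

# planar-epithelium cortex geometry (epithelium: z < thickness)
plane_geom <- function(dims, voxel_size = 2.28, thickness = 10,
                       cortex_depth = 1000) {
  zc <- (seq_len(dims[3]) - 1) * voxel_size
  epi <- array(rep(zc < thickness, each = dims[1] * dims[2]), dim = dims)
  build_cortex(epi, !epi, voxel_size, cortex_depth)
}
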