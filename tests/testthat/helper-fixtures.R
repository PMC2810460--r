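# Shared fixtures and brute-force oracles used across test files.

# deterministic random test image in [0, 255]
randImage <- function(h, w, seed = 1) {
  set.seed(seed)
  GrayImage(matrix(runif(h * w, 0, 255), h, w))
}

# nested-loop oracle for the ED8 point-singularity feature (replicate pad)
ed8Loop <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      s <- 0
      for (k2 in -1:1) {
        for (k1 in -1:1) {
          ii <- min(max(i + k2, 1), h)
          jj <- min(max(j + k1, 1), w)
          s <- s + abs(m[ii, jj] - m[i, j])
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# double-loop oracle for the local-maximum rank feature
rankLoop <- function(m, window) {
  r <- (window - 1) / 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      cnt <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          if (di == 0 && dj == 0) next
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          if (m[ii, jj] < m[i, j]) cnt <- cnt + 1
        }
      }
      out[i, j] <- cnt / (window^2 - 1)
    }
  }
  out
}

# independent Otsu oracle: minimize the within-class variance criterion
# w0 * var0 + w1 * var1 (equivalent to maximizing between-class variance)
otsuWithinLoop <- function(values) {
  v <- round(pmin(pmax(values, 0), 255))
  best <- Inf; bestT <- NA
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) {
      wcv <- if (length(lo) == 0) mean((hi - mean(hi))^2) else
        mean((lo - mean(lo))^2)
    } else {
      w0 <- length(lo) / length(v)
      wcv <- w0 * mean((lo - mean(lo))^2) +
        (1 - w0) * mean((hi - mean(hi))^2)
    }
    if (wcv < best - 1e-12) { best <- wcv; bestT <- t }
  }
  bestT
}

# phantom seeds whose planted clusters sit at NMD >= 0.1 (the working
# condition for the end-to-end study); scans deterministically from `from`
phantomSeedsWithNmd <- function(tissue, n, from, shape = c(512L, 512L),
                                minNmd = 0.1) {
  seeds <- integer(0); s <- from
  while (length(seeds) < n && s < from + 50L) {
    ph <- generatePhantom(phantomSpec(shape = shape, tissue = tissue,
                                      seed = s))
    if (phantomNmd(ph$image, ph$truth, ph$breast) >= minNmd)
      seeds <- c(seeds, s)
    s <- s + 1L
  }
  stopifnot(length(seeds) == n)
  seeds
}

# tiny valid cluster spec helper
clusterSpec <- function(center, n = 3L, rr = c(1, 2), crad = 12) {
  list(center = center, n_mcs = n, mc_radius_range = rr, cluster_radius = crad)
}
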