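# Separable 2-D discrete wavelet transform (filter-bank implementation,
# symmetric half-sample boundary extension). Decomposition keeps the
# redundant boundary coefficients (floor((n + L - 1) / 2) per level), which
# makes the synthesis bank an exact inverse. The db4 filter bank (8 taps,
# 4 vanishing moments) is the default analysis filter for the highpass
# microcalcification feature.

# db4 orthogonal filter bank (decomposition lowpass; the rest follow by
# quadrature-mirror relations)
.db4_dec_lo <- c(-0.010597401785069032,  0.0328830116668852,
                  0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854,  0.6308807679298589,
                  0.7148465705529157,    0.2303778133088965)

.waveletBank <- function(family = "db4") {
  if (!identical(family, "db4"))
    stop("unsupported wavelet family '", family, "' (db4 available)")
  lo <- .db4_dec_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L))         # QMF
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = L)
}

# symmetric (half-sample) extension of each column by p rows on both ends
.symExtRows <- function(m, p) {
  n <- nrow(m)
  if (p > n) stop("signal too short for filter length")
  rbind(m[p:1, , drop = FALSE], m, m[n:(n - p + 1), , drop = FALSE])
}

# analysis along the row dimension of every column; returns
# floor((n + L - 1)/2) x ncol coefficients
.dwtCols <- function(m, f) {
  n <- nrow(m); L <- length(f)
  ext <- .symExtRows(m, L - 1L)
  ne <- nrow(ext)
  full <- matrix(0, ne + L - 1L, ncol(m))
  for (i in seq_len(L))
    full[i:(i + ne - 1L), ] <- full[i:(i + ne - 1L), ] + ext * f[i]
  idx <- seq(L + 1L, by = 2L, length.out = (n + L - 1L) %/% 2L)
  full[idx, , drop = FALSE]
}

# synthesis along the row dimension: invert (.dwtCols lo, .dwtCols hi)
.idwtCols <- function(a, d, outlen, lo, hi) {
  m <- nrow(a); L <- length(lo)
  up <- 2L * m - 1L
  ua <- matrix(0, up, ncol(a)); ua[seq(1L, by = 2L, length.out = m), ] <- a
  ud <- matrix(0, up, ncol(d)); ud[seq(1L, by = 2L, length.out = m), ] <- d
  full <- matrix(0, up + L - 1L, ncol(a))
  for (i in seq_len(L))
    full[i:(i + up - 1L), ] <- full[i:(i + up - 1L), ] + ua * lo[i] + ud * hi[i]
  full[(L - 1L):(L - 2L + outlen), , drop = FALSE]
}

# multilevel separable 2-D analysis; returns list(approx, details) where
# details[[l]] holds LH/HL/HH and the sub-image size entering level l
.wavedec2 <- function(m, levels, bank) {
  stopifnot(levels >= 1)
  details <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    if (min(dim(cur)) < bank$length)
      stop("image too small for ", levels, "-level decomposition")
    sz <- dim(cur)
    Lr <- .dwtCols(cur, bank$dec_lo)
    Hr <- .dwtCols(cur, bank$dec_hi)
    LL <- t(.dwtCols(t(Lr), bank$dec_lo))
    LH <- t(.dwtCols(t(Lr), bank$dec_hi))
    HL <- t(.dwtCols(t(Hr), bank$dec_lo))
    HH <- t(.dwtCols(t(Hr), bank$dec_hi))
    details[[l]] <- list(LH = LH, HL = HL, HH = HH, size = sz)
    cur <- LL
  }
  list(approx = cur, details = details)
}

# exact inverse of .wavedec2
.waverec2 <- function(dec, bank) {
  cur <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    Lr <- t(.idwtCols(t(cur), t(d$LH), d$size[2], bank$rec_lo, bank$rec_hi))
    Hr <- t(.idwtCols(t(d$HL), t(d$HH), d$size[2], bank$rec_lo, bank$rec_hi))
    cur <- .idwtCols(Lr, Hr, d$size[1], bank$rec_lo, bank$rec_hi)
  }
  cur
}
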