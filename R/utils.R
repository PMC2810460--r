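# Shared raster helpers: padding, small-kernel convolution, 8-connected
# component labeling (EBImage::bwlabel is 4-connected; diagonal-touching
# labels are merged with a union-find over the label graph).

#' Normalized 2-D Gaussian kernel
#'
#' @param size odd kernel edge length.
#' @param sigma standard deviation in pixels.
#' @return size x size matrix summing to 1.
#' @export
gaussianKernel <- function(size = 3, sigma = 0.8) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  r <- (size - 1) / 2
  d <- outer((-r):r, (-r):r, function(i, j) i^2 + j^2)
  k <- exp(-d / (2 * sigma^2))
  k / sum(k)
}

# replicate-pad a matrix by r rows/cols on every side
.padReplicate <- function(m, r) {
  if (r == 0) return(m)
  ri <- pmin(pmax(seq(1 - r, nrow(m) + r), 1), nrow(m))
  ci <- pmin(pmax(seq(1 - r, ncol(m) + r), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

# direct 2-D convolution with replicate boundary; kernel must be odd-sized
.conv2Replicate <- function(m, k) {
  kr <- (nrow(k) - 1) / 2
  kc <- (ncol(k) - 1) / 2
  stopifnot(kr == round(kr), kc == round(kc))
  r <- max(kr, kc)
  p <- .padReplicate(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      rr <- (r - kr + i - 1) + seq_len(nrow(m))
      cc <- (r - kc + j - 1) + seq_len(ncol(m))
      out <- out + k[nrow(k) - i + 1, ncol(k) - j + 1] * p[rr, cc]
    }
  }
  out
}

# binary dilation by the footprint of kernel k (any nonzero entry)
.dilateByFootprint <- function(mask, k) {
  fp <- matrix(as.numeric(k != 0), nrow(k), ncol(k))
  out <- .conv2Replicate(mask, fp)
  (out > 1e-9) * 1
}

# 8-connected labeling of a binary matrix; returns integer label matrix
.label8 <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]       # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]      # down-left diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  }
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  sel <- lab > 0L
  lab[sel] <- remap[lab[sel]]
  lab
}

# centroids and areas of labeled components: data.frame(id, row, col, area)
.componentCentroids <- function(lab) {
  sel <- which(lab > 0L)
  if (length(sel) == 0L)
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      area = integer()))
  ids <- lab[sel]
  rows <- (sel - 1L) %% nrow(lab) + 1L
  cols <- (sel - 1L) %/% nrow(lab) + 1L
  data.frame(
    id   = sort(unique(ids)),
    row  = as.numeric(tapply(rows, ids, mean)),
    col  = as.numeric(tapply(cols, ids, mean)),
    area = as.integer(tapply(rows, ids, length)))
}

# coordinates (n x 2 matrix, row/col) of nonzero mask entries
.maskCoords <- function(mask) {
  sel <- which(mask != 0)
  cbind(row = (sel - 1L) %% nrow(mask) + 1L,
        col = (sel - 1L) %/% nrow(mask) + 1L)
}

# filled disc rasterized onto an existing matrix; returns modified matrix
.stampDisc <- function(mask, r0, c0, radius, value = 1) {
  rr <- max(1L, floor(r0 - radius)):min(nrow(mask), ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(ncol(mask), ceiling(c0 + radius))
  if (length(rr) == 0L || length(cc) == 0L) return(mask)
  d2 <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2)
  mask[rr, cc][d2 <= radius^2] <- value
  mask
}

# derive a child seed deterministically from a base seed and a stage tag
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483629L
}
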