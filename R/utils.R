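# Internal conventions: images are base-R numeric matrices/arrays indexed
# [row, col(, channel)], 1-based, intensities on the 0-255 scale. EBImage is
# called through to_unit()/from_unit(); all kernels used are symmetric so the
# row/col vs x/y transposition of EBImage is immaterial.

to_unit <- function(x) x / 255
from_unit <- function(x) x * 255

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' @importFrom EBImage bwlabel
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1) return(relabel_seq(lab))
  # bwlabel is 4-connected; merge labels touching diagonally via union-find
  n <- max(lab)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  }
  root <- vapply(seq_len(n), findp, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  relabel_seq(lab)
}

relabel_seq <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# discrete disk {(dr,dc): dr^2 + dc^2 <= r^2} as a (2r+1)^2 0/1 kernel
disk_kernel <- function(radius) {
  stopifnot(radius > 0)
  r <- as.integer(ceiling(radius))
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

# vectorized bilinear interpolation of matrix img at fractional (row, col)
bilinear <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- img[cbind(r0, c0)];     i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# exact 3x3 median via a 19-comparator sorting network (replicate borders);
# much faster than a general median filter at this kernel size
median3x3 <- function(x) {
  p <- vector("list", 9)
  k <- 0
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1
    s <- shift_mat(x, dr, dc)
    s[is.na(s)] <- x[is.na(s)]
    p[[k]] <- s
  }
  op <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  seq_ops <- list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
                  c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
                  c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
                  c(5, 3))
  for (o in seq_ops) op(o[1], o[2])
  p[[5]]
}

# derive a per-item 32-bit seed from a master seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
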