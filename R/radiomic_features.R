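# Radiomic texture features: 93 per image form (18 first-order + 75
# gray-matrix: GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5), computed on
# 9 forms of the green ROI channel. Definitions follow the standard
# radiomics (IBSI-style) formulary. The within-form order lists the
# families alphabetically with alphabetical feature order inside each, so
# the two published anchor indices round-trip: index 15 is skewness and
# index 79 is the GLSZM large-area low-gray-level emphasis.

fo_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
              "Percentile90", "Maximum", "Mean", "Median",
              "InterquartileRange", "Range", "MeanAbsoluteDeviation",
              "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
              "Kurtosis", "Variance", "Uniformity")
glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy",
                "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
                "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
                "JointEntropy", "MaximumProbability", "Mcc", "SumAverage",
                "SumEntropy", "SumSquares")
gldm_names <- c("DependenceEntropy", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "DependenceVariance",
                "GrayLevelNonUniformity", "GrayLevelVariance",
                "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                "LargeDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LowGrayLevelEmphasis", "SmallDependenceEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis")
glrlm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                 "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                 "RunEntropy", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "RunVariance", "ShortRunEmphasis",
                 "ShortRunHighGrayLevelEmphasis",
                 "ShortRunLowGrayLevelEmphasis")
glszm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                 "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                 "ZonePercentage", "ZoneVariance")
ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                 "Strength")
form_names <- c("original", "log-sigma-1", "log-sigma-2", "log-sigma-3",
                "wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
                "lbp")
morph_names <- c("MeanArea", "TotalArea", "MeanPerimeterAreaRatio",
                 "TotalPerimeterAreaRatio", "MeanCircularity",
                 "MeanPerimeter", "TotalPerimeter",
                 "MinRectAspectRatio", "Number")

# discretize in-mask values to 1..n_bins over their own range
discretize <- function(vals, n_bins) {
  rng <- range(vals)
  if (diff(rng) < 1e-12) return(rep.int(1L, length(vals)))
  pmin(as.integer(floor((vals - rng[1]) / (diff(rng) / n_bins))) + 1L,
       n_bins)
}

entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' First-order statistical features
#'
#' The standard 18-feature radiomics first-order set computed on the raw
#' in-mask intensities; entropy and uniformity use a fixed-bin-count
#' histogram. Skewness and kurtosis use population moments; skewness is 0
#' and kurtosis 0 under zero variance.
#'
#' @param form gray matrix (any image form).
#' @param mask logical matrix of pixels to include.
#' @param n_bins histogram bin count for entropy/uniformity.
#' @return named numeric vector of length 18.
#' @export
first_order <- function(form, mask, n_bins = 32) {
  v <- form[mask]
  if (!length(v)) stop("empty mask")
  p <- tabulate(discretize(v, n_bins), n_bins) / length(v)
  m <- mean(v); vr <- mean((v - m)^2)
  q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rob <- v[v >= q[1] & v <= q[5]]
  sk <- if (vr > 1e-12) mean((v - m)^3) / vr^1.5 else 0
  ku <- if (vr > 1e-12) mean((v - m)^4) / vr^2 else 0
  stats::setNames(c(
    sum(v^2), sum(v^2), entropy2(p), min(v), q[1], q[5], max(v), m, q[3],
    q[4] - q[2], max(v) - min(v), mean(abs(v - m)),
    mean(abs(rob - mean(rob))), sqrt(mean(v^2)), sk, ku, vr, sum(p^2)),
    fo_names)
}

# ---- GLCM -------------------------------------------------------------------

offsets4 <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

glcm_matrix <- function(lev, mask, Ng, offset) {
  a <- matrix(NA_real_, nrow(mask), ncol(mask)); a[mask] <- lev
  b <- shift_mat(a, offset[1], offset[2])
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  cnt <- tabulate((a[ok] - 1) * Ng + b[ok], Ng * Ng)
  P <- matrix(cnt, Ng, Ng, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

glcm_features_one <- function(P, Ng) {
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(Ng) * px)
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  # diagonal-band and anti-diagonal marginals
  k_d <- 0:(Ng - 1)
  p_d <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * Ng)
  p_s <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_d * p_d)
  hxy <- entropy2(P)
  pxpy <- outer(px, px)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- entropy2(pxpy)
  hx <- entropy2(px)
  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 1e-12) (sum(i * j * P) - mu^2) / sig2 else 1
  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2) 1 else {
      Pk <- P[keep, keep, drop = FALSE]; pxk <- px[keep]
      A <- Pk / pxk                    # rows scaled by 1/px(i)
      C <- sweep(Pk, 2, pxk, "/")      # cols scaled by 1/px(k)
      ev <- sort(Re(eigen(A %*% t(C), only.values = TRUE)$values),
                 decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
  }
  stats::setNames(c(
    sum(i * j * P),                       # Autocorrelation
    sum((i + j - 2 * mu)^4 * P),          # ClusterProminence
    sum((i + j - 2 * mu)^3 * P),          # ClusterShade
    sum((i + j - 2 * mu)^2 * P),          # ClusterTendency
    sum((i - j)^2 * P),                   # Contrast
    corr,
    da,                                   # DifferenceAverage
    entropy2(p_d),                        # DifferenceEntropy
    sum((k_d - da)^2 * p_d),              # DifferenceVariance
    sum(p_d / (1 + k_d)),                 # Id
    sum(p_d / (1 + k_d^2)),               # Idm
    sum(P / (1 + (i - j)^2 / Ng^2)),      # Idmn
    sum(P / (1 + abs(i - j) / Ng)),       # Idn
    imc1, imc2,
    sum(p_d[-1] / k_d[-1]^2),             # InverseVariance
    mu,                                   # JointAverage
    sum(P^2),                             # JointEnergy
    hxy,                                  # JointEntropy
    max(P),                               # MaximumProbability
    mcc,
    sum(k_s * p_s),                       # SumAverage
    entropy2(p_s),                        # SumEntropy
    sum((i - mu)^2 * P)),                 # SumSquares
    glcm_names)
}

glcm_features <- function(lev, mask, Ng) {
  per <- vapply(offsets4,
                function(o) glcm_features_one(glcm_matrix(lev, mask, Ng, o),
                                              Ng),
                numeric(24))
  stats::setNames(rowMeans(per), glcm_names)
}

# ---- GLRLM ------------------------------------------------------------------

# run-length counts along one direction; lines are broken at mask gaps.
# Diagonal directions are sheared into columns so each direction reduces to
# a single rle over a separator-delimited vector.
glrlm_matrix <- function(lev, mask, Ng, offset) {
  nr <- nrow(mask); nc <- ncol(mask)
  a <- matrix(0L, nr, nc); a[mask] <- lev
  v <- if (identical(offset, c(0L, 1L))) {
    as.vector(t(cbind(a, 0L)))
  } else if (identical(offset, c(1L, 0L))) {
    as.vector(rbind(a, 0L))
  } else {
    S <- matrix(0L, nr, nc + nr)
    cols <- if (identical(offset, c(1L, 1L))) {
      rep(seq_len(nc), each = nr) + nr - rep(seq_len(nr), nc)
    } else {
      rep(seq_len(nc), each = nr) + rep(seq_len(nr), nc) - 1L
    }
    S[cbind(rep(seq_len(nr), nc), cols)] <- a
    as.vector(rbind(S, 0L))
  }
  r <- rle(v)
  keep <- r$values > 0
  maxlen <- max(nr, nc)
  cnt <- tabulate((r$values[keep] - 1L) * maxlen +
                    pmin(r$lengths[keep], maxlen), Ng * maxlen)
  matrix(cnt, Ng, maxlen, byrow = TRUE)
}

rl_type_features <- function(R, Np) {
  # shared formulary for run-length-style matrices R(gray level, size)
  Nr <- sum(R)
  if (Nr == 0) return(numeric(16))
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  p <- R / Nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(GLN = sum(rowSums(R)^2) / Nr,
    GLNN = sum(rowSums(R)^2) / Nr^2,
    GLV = sum((i - mu_i)^2 * p),
    HGLE = sum(i^2 * p),
    LE = sum(j^2 * p),
    LHGLE = sum(i^2 * j^2 * p),
    LLGLE = sum(j^2 / i^2 * p),
    LGLE = sum(p / i^2),
    ENT = entropy2(p),
    SN = sum(colSums(R)^2) / Nr,
    SNN = sum(colSums(R)^2) / Nr^2,
    PCT = Nr / Np,
    SV = sum((j - mu_j)^2 * p),
    SE = sum(p / j^2),
    SHGLE = sum(i^2 / j^2 * p),
    SLGLE = sum(p / (i^2 * j^2)))
}

glrlm_features <- function(lev, mask, Ng) {
  Np <- sum(mask)
  per <- vapply(offsets4, function(o)
    rl_type_features(glrlm_matrix(lev, mask, Ng, o), Np),
    numeric(16))
  stats::setNames(rowMeans(per), glrlm_names)
}

# ---- GLSZM ------------------------------------------------------------------

glszm_features <- function(lev, mask, Ng) {
  a <- matrix(0L, nrow(mask), ncol(mask)); a[mask] <- lev
  sizes <- list()
  for (g in sort(unique(lev))) {
    sel <- a == g
    idx <- which(sel, arr.ind = TRUE)
    rs <- range(idx[, 1]); cs <- range(idx[, 2])
    lab <- label_components(sel[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE], 8)
    if (max(lab) > 0) sizes[[as.character(g)]] <- tabulate(lab[lab > 0], max(lab))
  }
  if (!length(sizes)) return(stats::setNames(numeric(16), glszm_names))
  maxs <- max(unlist(sizes))
  S <- matrix(0, Ng, maxs)
  for (g in names(sizes)) {
    tb <- tabulate(sizes[[g]], maxs)
    S[as.integer(g), ] <- S[as.integer(g), ] + tb
  }
  f <- rl_type_features(S, sum(mask))
  # map the shared formulary onto the GLSZM naming (alphabetical)
  stats::setNames(c(f["GLN"], f["GLNN"], f["GLV"], f["HGLE"], f["LE"],
                    f["LHGLE"], f["LLGLE"], f["LGLE"], f["SN"], f["SNN"],
                    f["SE"], f["SHGLE"], f["SLGLE"], f["ENT"], f["PCT"],
                    f["SV"]),
                  glszm_names)
}

# ---- NGTDM / GLDM -----------------------------------------------------------

offsets8 <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

ngtdm_features <- function(lev, mask, Ng) {
  a <- matrix(NA_real_, nrow(mask), ncol(mask)); a[mask] <- lev
  nsum <- matrix(0, nrow(mask), ncol(mask))
  ncnt <- matrix(0, nrow(mask), ncol(mask))
  for (o in offsets8) {
    s <- shift_mat(a, o[1], o[2])
    ok <- !is.na(s)
    nsum[ok] <- nsum[ok] + s[ok]
    ncnt <- ncnt + ok
  }
  valid <- mask & ncnt > 0
  Nvp <- sum(valid)
  if (Nvp == 0) return(stats::setNames(numeric(5), ngtdm_names))
  A <- nsum[valid] / ncnt[valid]
  lv <- a[valid]
  s_i <- vapply(seq_len(Ng), function(g) sum(abs(g - A[lv == g])), numeric(1))
  n_i <- tabulate(lv, Ng)
  p_i <- n_i / Nvp
  act <- which(n_i > 0)
  Ngp <- length(act)
  ii <- rep(act, each = length(act)); jj <- rep(act, length(act))
  pi_ <- p_i[ii]; pj <- p_i[jj]
  busy_den <- sum(abs(ii * pi_ - jj * pj))
  contrast <- if (Ngp > 1)
    sum(pi_ * pj * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp else 0
  complexity <- sum(abs(ii - jj) * (pi_ * s_i[ii] + pj * s_i[jj]) /
                      (pi_ + pj)) / Nvp
  strength <- if (sum(s_i) > 0)
    sum((pi_ + pj) * (ii - jj)^2) / sum(s_i) else 0
  coars_den <- sum(p_i * s_i)
  stats::setNames(c(
    if (busy_den > 0) sum(p_i * s_i) / busy_den else 0,   # Busyness
    if (coars_den > 0) 1 / coars_den else 1e6,            # Coarseness
    complexity, contrast, strength), ngtdm_names)
}

gldm_features <- function(lev, mask, Ng, alpha = 0) {
  a <- matrix(NA_real_, nrow(mask), ncol(mask)); a[mask] <- lev
  dep <- matrix(0L, nrow(mask), ncol(mask))
  for (o in offsets8) {
    s <- shift_mat(a, o[1], o[2])
    dep <- dep + (!is.na(a) & !is.na(s) & abs(a - s) <= alpha)
  }
  lv <- a[mask]; dv <- dep[mask] + 1L   # dependence size bins start at 1
  maxd <- 9L
  D <- matrix(tabulate((lv - 1L) * maxd + dv, Ng * maxd), Ng, maxd,
              byrow = TRUE)
  f <- rl_type_features(D, sum(mask))
  # map the shared formulary onto the GLDM naming (alphabetical)
  stats::setNames(c(f["ENT"], f["SN"], f["SNN"], f["SV"], f["GLN"],
                    f["GLV"], f["HGLE"], f["LE"], f["LHGLE"], f["LLGLE"],
                    f["LGLE"], f["SE"], f["SHGLE"], f["SLGLE"]),
                  gldm_names)
}

#' The 75 gray-matrix texture features of one image form
#'
#' Computes GLCM (24, direction-averaged over the four 2-D directions at
#' distance 1), GLDM (14), GLRLM (16, direction-averaged), GLSZM (16) and
#' NGTDM (5) features after fixed-bin-count discretization of the in-mask
#' intensities. Degenerate single-level images yield the defined one-level
#' limits, never NaN.
#'
#' @param form gray matrix.
#' @param mask logical matrix.
#' @param n_bins gray-level bin count.
#' @return named numeric vector of length 75.
#' @export
matrix_features <- function(form, mask, n_bins = 32) {
  lev <- discretize(form[mask], n_bins)
  Ng <- n_bins
  c(glcm_features(lev, mask, Ng), gldm_features(lev, mask, Ng),
    glrlm_features(lev, mask, Ng), glszm_features(lev, mask, Ng),
    ngtdm_features(lev, mask, Ng))
}

# ---- image forms ------------------------------------------------------------

log_kernel <- function(sigma, max_half = Inf) {
  half <- min(ceiling(4 * sigma), max_half)
  d <- seq(-half, half)
  r2 <- outer(d^2, d^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)   # zero response on flat fields
}

haar_subbands <- function(x) {
  nr <- 2 * floor(nrow(x) / 2); nc <- 2 * floor(ncol(x) / 2)
  x <- x[seq_len(nr), seq_len(nc)]
  a <- x[seq(1, nr, 2), seq(1, nc, 2)]; b <- x[seq(1, nr, 2), seq(2, nc, 2)]
  cc <- x[seq(2, nr, 2), seq(1, nc, 2)]; d <- x[seq(2, nr, 2), seq(2, nc, 2)]
  list(LL = (a + b + cc + d) / 2, LH = (a - b + cc - d) / 2,
       HL = (a + b - cc - d) / 2, HH = (a - b - cc + d) / 2)
}

lbp_code <- function(x) {
  # rotation-invariant uniform LBP, radius 1, 8 neighbours (discrete ring)
  nbr <- lapply(offsets8, function(o) {
    s <- shift_mat(x, o[1], o[2])
    s[is.na(s)] <- x[is.na(s)]   # replicate border
    s >= x
  })
  ord <- c(2, 3, 5, 8, 7, 6, 4, 1)  # circular order of offsets8
  bits <- nbr[ord]
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_len(8), function(i)
    bits[[i]] != bits[[if (i == 8) 1 else i + 1]]))
  out <- ifelse(trans <= 2, ones, 9)
  matrix(as.numeric(out), nrow(x), ncol(x))
}

#' The nine image forms of the ROI
#'
#' Original image, Laplacian-of-Gaussian at sigma 1, 2, 3 px, the four
#' subbands of a one-level 2-D Haar wavelet decomposition, and the
#' rotation-invariant uniform local-binary-pattern code image (radius 1,
#' 8 neighbours). Wavelet subbands are half-resolution and carry a
#' correspondingly downsampled mask.
#'
#' @param roi gray matrix (green channel of the normalized ROI).
#' @param mask logical ROI mask.
#' @return list of 9 elements `list(name, pixels, mask)` in canonical order.
#' @export
make_forms <- function(roi, mask = matrix(TRUE, nrow(roi), ncol(roi))) {
  if (nrow(roi) < 2 || ncol(roi) < 2) stop("ROI smaller than 2x2")
  logf <- function(s)
    EBImage::filter2(roi,
                     log_kernel(s, max_half = (min(dim(roi)) - 1) %/% 2),
                     boundary = "replicate")
  wav <- haar_subbands(roi)
  mhalf <- haar_subbands(mask * 1)$LL > 0.99  # all four pixels in mask
  if (!any(mhalf)) mhalf <- haar_subbands(mask * 1)$LL > 0
  forms <- list(
    list(name = "original", pixels = roi, mask = mask),
    list(name = "log-sigma-1", pixels = logf(1), mask = mask),
    list(name = "log-sigma-2", pixels = logf(2), mask = mask),
    list(name = "log-sigma-3", pixels = logf(3), mask = mask),
    list(name = "wavelet-LL", pixels = wav$LL, mask = mhalf),
    list(name = "wavelet-LH", pixels = wav$LH, mask = mhalf),
    list(name = "wavelet-HL", pixels = wav$HL, mask = mhalf),
    list(name = "wavelet-HH", pixels = wav$HH, mask = mhalf),
    list(name = "lbp", pixels = lbp_code(roi), mask = mask))
  stopifnot(length(forms) == 9)
  forms
}

#' The 837 texture features of one ROI
#'
#' 93 features (18 first-order + 75 gray-matrix) on each of the nine image
#' forms, named `texture-<form index>-<feature index>`.
#'
#' @param roi gray ROI matrix.
#' @param mask logical ROI mask.
#' @param n_bins gray-level bin count.
#' @return named numeric vector of length 837.
#' @export
texture_block <- function(roi, mask, n_bins = 32) {
  forms <- make_forms(roi, mask)
  out <- lapply(seq_along(forms), function(f) {
    v <- c(first_order(forms[[f]]$pixels, forms[[f]]$mask, n_bins),
           matrix_features(forms[[f]]$pixels, forms[[f]]$mask, n_bins))
    stopifnot(length(v) == 93)
    stats::setNames(v, sprintf("texture-%d-%d", f, seq_len(93)))
  })
  out <- unlist(out)
  stopifnot(length(out) == 837, !anyNA(out))
  out
}

# minimum-area external rectangle aspect ratio (short/long), rotating
# calipers over the convex hull of the region's pixel centres; each pixel
# contributes a unit footprint
min_rect_aspect <- function(pts) {
  if (nrow(pts) == 1) return(1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  best <- Inf; best_asp <- 1
  n <- nrow(hp)
  for (k in seq_len(n)) {
    e <- hp[if (k == n) 1 else k + 1, ] - hp[k, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- pts %*% u; pv <- pts %*% v
    w <- diff(range(pu)) + 1; hgt <- diff(range(pv)) + 1
    if (w * hgt < best) {
      best <- w * hgt
      best_asp <- min(w, hgt) / max(w, hgt)
    }
  }
  best_asp
}

#' The nine morphological features of the stain regions
#'
#' Per-region area, perimeter, circularity `4*pi*A/P^2` and
#' minimum-external-rectangle aspect ratio (short/long), aggregated as:
#' mean area, total area, mean perimeter-to-area ratio, total
#' perimeter-to-area ratio (total perimeter over total area), mean
#' circularity, mean perimeter, total perimeter, mean aspect ratio, and
#' region count. An empty stain map yields all zeros.
#'
#' @param stains a [stain_map()].
#' @return named numeric vector of length 9, names `morphology-1..9`.
#' @export
morph_block <- function(stains) {
  nm <- sprintf("morphology-%d", 1:9)
  if (stains$n == 0) return(stats::setNames(numeric(9), nm))
  A <- stains$areas; P <- stains$perimeters
  P_safe <- pmax(P, 1e-9)
  circ <- pmin(4 * pi * A / P_safe^2, 1.2)
  asp <- vapply(seq_len(stains$n), function(i)
    min_rect_aspect(which(stains$labels == i, arr.ind = TRUE)),
    numeric(1))
  stats::setNames(c(mean(A), sum(A), mean(P_safe / A), sum(P) / sum(A),
                    mean(circ), mean(P), sum(P), mean(asp), stains$n), nm)
}

#' Canonical names of the 974-feature signature
#' @return character vector: 837 texture, 9 morphology, 128 topology names.
#' @export
cfs_feature_names <- function() {
  c(sprintf("texture-%d-%d", rep(1:9, each = 93), rep(1:93, 9)),
    sprintf("morphology-%d", 1:9),
    sprintf("topology-%d-%d", rep(1:16, each = 8), rep(1:8, 16)))
}

#' Human-readable definitions of all 974 features
#' @return data frame with columns `name`, `definition`.
#' @export
feature_dictionary <- function() {
  within_form <- c(paste("first-order", fo_names),
                   paste("GLCM", glcm_names), paste("GLDM", gldm_names),
                   paste("GLRLM", glrlm_names), paste("GLSZM", glszm_names),
                   paste("NGTDM", ngtdm_names))
  topo_long <- c("number of subgraphs", "average vertex degree",
                 "maximum vertex degree", "average vertex eccentricity",
                 "diameter", "average clustering coefficient",
                 "giant connected component ratio",
                 "percentage of isolated points")
  defs <- c(
    paste0(rep(within_form, 9), " of ", rep(form_names, each = 93), " form"),
    paste("morphology", morph_names),
    paste0(rep(topo_long, 16), " at dilation scale ",
           rep(seq(4, 64, 4), each = 8)))
  data.frame(name = cfs_feature_names(), definition = defs,
             stringsAsFactors = FALSE)
}
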