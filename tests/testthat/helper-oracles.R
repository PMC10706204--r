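# Independent brute-force oracles. These deliberately share no code with
# the package internals: dilation overlap is decided by enumerating pixel
# pairs and candidate meeting points, graph features by adjacency-matrix
# breadth-first search, AUC by pair counting, and tau-b by an O(n^2) loop.

# minimal disk radius at which the dilations of two pixel sets share an
# integer pixel: min over (a, b, p) of max(|p-a|, |p-b|). Any integer p
# with value at most R + 1 (R = |ab|/2; the rounded midpoint achieves
# that) lies within 1 of the midpoint along the a-b axis and within
# sqrt(2R + 1) along the perpendicular bisector, so scanning that lens
# with a unit-neighbourhood margin is exhaustive.
oracle_connect_radius <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    a <- A[i, ]; b <- B[j, ]
    mid <- (a + b) / 2
    ab <- b - a
    len <- sqrt(sum(ab^2))
    perp <- if (len > 1e-9) c(-ab[2], ab[1]) / len else c(1, 0)
    lmax <- sqrt(len + 1) + 1
    for (t in seq(-lmax, lmax, by = 0.5)) {
      base <- mid + t * perp
      for (dr in -1:1) for (dc in -1:1) {
        p <- c(floor(base[1]) + dr, floor(base[2]) + dc)
        v <- max(sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2)))
        if (v < best) best <- v
      }
    }
  }
  best
}

# edge sets at all scales from pairwise oracle connection radii
oracle_edges <- function(labels, radii) {
  n <- max(labels)
  if (n < 2) return(lapply(radii, function(r) matrix(integer(0), 0, 2)))
  pix <- lapply(seq_len(n), function(i) which(labels == i, arr.ind = TRUE))
  rc <- matrix(Inf, n, n)
  for (u in seq_len(n - 1)) for (v in (u + 1):n)
    rc[u, v] <- oracle_connect_radius(pix[[u]], pix[[v]])
  lapply(radii, function(r) {
    idx <- which(upper.tri(rc) & rc <= r + 1e-7, arr.ind = TRUE)
    matrix(as.integer(idx), ncol = 2)
  })
}

# the eight graph features by hand: BFS distances on an adjacency matrix
oracle_graph_features <- function(n, edges) {
  if (n == 0) return(numeric(8))
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  deg <- rowSums(adj)
  bfs <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & d > d[v] + 1)
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  dists <- t(vapply(seq_len(n), bfs, numeric(n)))
  ecc <- vapply(seq_len(n), function(v) {
    reach <- is.finite(dists[v, ])
    max(dists[v, reach])
  }, numeric(1))
  # components by reachability
  comp_id <- integer(n); cid <- 0
  for (v in seq_len(n)) if (comp_id[v] == 0) {
    cid <- cid + 1
    comp_id[is.finite(dists[v, ])] <- cid
  }
  clust <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  c(cid, mean(deg), max(deg), mean(ecc), max(ecc), mean(clust),
    max(tabulate(comp_id)) / n, mean(deg == 0))
}

# AUC by explicit positive/negative pair counting (ties count 1/2)
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Kendall tau-b by explicit pair enumeration
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# random small stain mask with n_regions compact regions (dots, bars, 2x2)
random_stain_mask <- function(n_regions, nr = 110, nc = 150, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  placed <- 0; guard <- 0
  while (placed < n_regions && guard < 2000) {
    guard <- guard + 1
    r <- sample(4:(nr - 4), 1); c <- sample(4:(nc - 4), 1)
    shape <- sample(3, 1)
    cells <- switch(shape,
                    cbind(r, c),
                    cbind(r + 0:1, c),                     # vertical bar
                    as.matrix(expand.grid(r + 0:1, c + 0:1)))  # 2x2 block
    # keep a 2 px moat so the region count is exact
    rs <- max(1, r - 2):min(nr, max(cells[, 1]) + 2)
    cs <- max(1, c - 2):min(nc, max(cells[, 2]) + 2)
    if (any(m[rs, cs])) next
    m[cells] <- TRUE
    placed <- placed + 1
  }
  m
}

# render a simple flat-background ROI with Gaussian dots (bypasses the
# anatomy pipeline; used for direct segmentation tests)
flat_roi <- function(nr, nc, centers, radius = 4, peak = 150, bg = 60,
                     noise = 0, seed = 1) {
  set.seed(seed)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  g <- matrix(bg, nr, nc)
  if (!is.null(centers) && nrow(centers))
    for (i in seq_len(nrow(centers))) {
      sig <- radius / sqrt(2 * log(2))
      g <- g + peak * exp(-((rr - centers[i, 1])^2 +
                              (cc - centers[i, 2])^2) / (2 * sig^2))
    }
  if (noise > 0) g <- g + matrix(rnorm(nr * nc, 0, noise), nr, nc)
  roi <- array(0, c(nr, nc, 3))
  roi[, , 1] <- bg; roi[, , 2] <- pmin(pmax(g, 0), 255); roi[, , 3] <- bg / 2
  roi
}
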