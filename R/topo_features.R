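#' Dilation scale set
#'
#' Disk radii at which the dilation-overlap graph is built. The default is
#' the 16 scales 4, 8, ..., 64 px; scale index k maps to radius 4k.
#'
#' @param radii strictly increasing positive radii.
#' @return object of class `scale_set`.
#' @export
scale_set <- function(radii = seq(4, 64, by = 4)) {
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")
  structure(list(radii = radii), class = "scale_set")
}

topo_feature_names <- c("n_subgraphs", "avg_degree", "max_degree",
                        "avg_eccentricity", "diameter", "avg_clustering",
                        "giant_ratio", "pct_isolated")

# Minimal connection radius for every region pair: the smallest disk radius
# at which the two regions' dilations share a pixel. With an exact Euclidean
# distance transform, dilation by the discrete disk {|d|^2 <= r^2} is
# {p : dist(p, region) <= r}, so the connection radius is
# min_p max(dist(p,u), dist(p,v)) over the integer plane; a canvas padded by
# the largest radius contains every attainable intersection pixel.
pairwise_connect_radii <- function(stains, max_radius) {
  n <- stains$n
  M <- matrix(Inf, n, n)
  diag(M) <- 0
  if (n < 2) return(M)
  pad <- as.integer(ceiling(max_radius)) + 1L
  nr <- nrow(stains$labels) + 2L * pad
  nc <- ncol(stains$labels) + 2L * pad
  dms <- vector("list", n)
  bbox <- matrix(0L, n, 4)
  for (i in seq_len(n)) {
    m <- matrix(0, nr, nc)
    sel <- stains$labels == i
    m[pad + seq_len(nrow(sel)), pad + seq_len(ncol(sel))] <- sel
    dms[[i]] <- EBImage::distmap(1 - m)
    idx <- which(sel, arr.ind = TRUE)
    bbox[i, ] <- c(range(idx[, 1]), range(idx[, 2])) + pad
  }
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    gap_r <- max(bbox[u, 1], bbox[v, 1]) - min(bbox[u, 2], bbox[v, 2])
    gap_c <- max(bbox[u, 3], bbox[v, 3]) - min(bbox[u, 4], bbox[v, 4])
    if (max(gap_r, 0)^2 + max(gap_c, 0)^2 > (2 * max_radius + 2)^2) next
    # a pixel attaining the optimum lies within M of both boxes; bound M
    # from above by evaluating the mid-point between the two boxes
    mid <- round(c(mean(bbox[u, 1:2]) + mean(bbox[v, 1:2]),
                   mean(bbox[u, 3:4]) + mean(bbox[v, 3:4])) / 2)
    mid <- pmin(pmax(mid, 1L), c(nr, nc))
    ub <- ceiling(max(dms[[u]][mid[1], mid[2]],
                      dms[[v]][mid[1], mid[2]])) + 1L
    w <- min(pad, ub)
    r0 <- max(1L, max(bbox[u, 1], bbox[v, 1]) - w)
    r1 <- min(nr, min(bbox[u, 2], bbox[v, 2]) + w)
    c0 <- max(1L, max(bbox[u, 3], bbox[v, 3]) - w)
    c1 <- min(nc, min(bbox[u, 4], bbox[v, 4]) + w)
    if (r0 > r1 || c0 > c1) next
    M[u, v] <- M[v, u] <- min(pmax(dms[[u]][r0:r1, c0:c1],
                                   dms[[v]][r0:r1, c0:c1]))
  }
  M
}

#' Build the dilation-overlap graph at one scale
#'
#' Vertices are the stain-region centroids; an undirected edge joins two
#' regions exactly when their dilations by the discrete disk of the given
#' radius share at least one pixel. The test is carried out on the actual
#' region masks (via exact distance transforms), not on a centroid-distance
#' shortcut, so irregular patch shapes are honored.
#'
#' @param stains a [stain_map()].
#' @param radius disk radius in px (> 0).
#' @return integer matrix with two columns (vertex indices), one row per
#'   edge.
#' @export
build_graph_at_scale <- function(stains, radius) {
  if (radius <= 0) stop("radius must be positive")
  M <- pairwise_connect_radii(stains, radius)
  edges_at(M, radius)
}

edges_at <- function(M, radius) {
  n <- nrow(M)
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(M) & M <= radius + 1e-7, arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2, dimnames = NULL)
}

#' Multiscale dilation-overlap graph
#'
#' Builds the edge sets of the dilation-overlap graph at every scale at
#' once. The vertex set (region centroids) is identical at all scales and
#' edge sets are monotone non-decreasing with radius.
#'
#' @param stains a [stain_map()].
#' @param scales a [scale_set()].
#' @return object of class `multiscale_graph` with fields `vertices`
#'   (centroids), `radii`, `edges_per_scale` (list of edge matrices) and
#'   `connect_radii` (pairwise minimal connection radii).
#' @export
multiscale_graph <- function(stains, scales = scale_set()) {
  M <- pairwise_connect_radii(stains, max(scales$radii))
  edges <- lapply(scales$radii, function(r) edges_at(M, r))
  names(edges) <- scales$radii
  structure(list(vertices = stains$centroids, radii = scales$radii,
                 edges_per_scale = edges, connect_radii = M),
            class = "multiscale_graph")
}

#' Eight topological features of one graph
#'
#' For an undirected simple graph: number of subgraphs (connected
#' components), average and maximum vertex degree, average vertex
#' eccentricity (within each vertex's own component; isolated vertex 0),
#' diameter (maximum eccentricity over vertices, i.e. the largest component
#' diameter), average local clustering coefficient (vertices of degree < 2
#' contribute 0), giant connected component ratio, and percentage of
#' isolated points. The empty graph returns all zeros.
#'
#' @param n_vertices vertex count.
#' @param edges two-column matrix of vertex indices.
#' @return named numeric vector of length 8.
#' @export
graph_features <- function(n_vertices, edges) {
  out <- stats::setNames(numeric(8), topo_feature_names)
  if (n_vertices == 0) return(out)
  g <- igraph::make_empty_graph(n_vertices, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  ecc <- igraph::eccentricity(g)  # within components; isolated -> 0
  out["n_subgraphs"] <- comp$no
  out["avg_degree"] <- mean(deg)
  out["max_degree"] <- max(deg)
  out["avg_eccentricity"] <- mean(ecc)
  out["diameter"] <- max(ecc)
  out["avg_clustering"] <-
    mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  out["giant_ratio"] <- max(comp$csize) / n_vertices
  out["pct_isolated"] <- mean(deg == 0)
  out
}

#' The 128 multiscale topological features
#'
#' Computes the eight features of [graph_features()] at each of the 16
#' dilation scales, in scale-major order with canonical names
#' `topology-<scale index>-<feature index>` (e.g. `topology-14-5` is the
#' diameter at scale radius 56). An empty stain map yields 128 zeros.
#'
#' @param stains a [stain_map()].
#' @param scales a [scale_set()].
#' @return named numeric vector of length `8 * length(scales$radii)`.
#' @export
topo_block <- function(stains, scales = scale_set()) {
  g <- multiscale_graph(stains, scales)
  vals <- lapply(seq_along(scales$radii), function(k) {
    f <- graph_features(stains$n, g$edges_per_scale[[k]])
    stats::setNames(f, sprintf("topology-%d-%d", k, seq_len(8)))
  })
  unlist(vals)
}
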