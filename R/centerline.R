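#' Extract the lumen centerline of a tubular mesh
#'
#' Computes a medial path between the inlet and outlet of an open tubular
#' surface. Interior medial points are found with the shrinking-ball
#' algorithm: for each sampled surface point, the maximal sphere tangent at
#' that point and empty of other surface samples is found by iterative
#' radius reduction; its center is a medial-axis point and its radius the
#' local inscribed radius. Points below a radius floor (default 10% of the
#' maximum) are discarded, the survivors are linked into a k-nearest-
#' neighbour graph (edges crossing outside the lumen are pruned), and the
#' centerline is the shortest path from inlet to outlet with edge weight
#' `length / meanRadius^p` (default `p = 2`), so the path hugs
#' maximal-inscribed-sphere centers. The path is then smoothed with a
#' centered moving average (window 5, endpoints fixed) and resampled
#' uniformly in arc length.
#'
#' Extraction is fully deterministic: surface subsampling uses a regular
#' stride, and no random numbers are consumed.
#'
#' @param mesh a [TriangleMesh-class], a tubular open surface.
#' @param inlet,outlet optional 3-D seed points; default to the centroids
#'   of the two largest boundary loops (inlet = largest). A supplied seed
#'   farther than 2 x the maximal inscribed radius from any medial point is
#'   a connectivity error.
#' @param nPoints number of output points (default 100, matching the
#'   section count of the diameter sweep).
#' @param radiusFloorFrac discard medial points with inscribed radius below
#'   this fraction of the maximum (default 0.1).
#' @param radiusPower exponent `p` of the inverse-radius edge weight.
#' @param knn neighbours per node in the medial graph.
#' @param smoothWindow centered moving-average window (odd).
#' @param maxSurfaceSamples,maxSeeds caps on surface samples and medial
#'   seeds (regular-stride subsampling) controlling cost on fine meshes.
#' @return A [Centerline-class] with per-point inscribed radii.
#' @examples
#' tube <- makeTube("straight", length = 60, r = 12, nAxial = 30, nCirc = 24)
#' cl <- extractCenterline(tube$mesh)
#' centerlineLength(cl)
#' @export
extractCenterline <- function(mesh, inlet = NULL, outlet = NULL,
                              nPoints = 100, radiusFloorFrac = 0.1,
                              radiusPower = 2, knn = 10, smoothWindow = 5,
                              maxSurfaceSamples = 4000, maxSeeds = 1500) {
  loops <- boundaryLoops(mesh)
  if (is.null(inlet) || is.null(outlet)) {
    if (length(loops) < 2L)
      stop("mesh has fewer than 2 boundary loops; supply inlet/outlet seeds")
    if (is.null(inlet)) inlet <- loops[[1]]@centroid
    if (is.null(outlet)) outlet <- loops[[2]]@centroid
  }
  med <- .medialPoints(mesh, maxSurfaceSamples = maxSurfaceSamples,
                       maxSeeds = maxSeeds)
  keep <- med$radius >= radiusFloorFrac * max(med$radius)
  centers <- med$centers[keep, , drop = FALSE]
  radii <- med$radius[keep]
  # seeds on the same ring collapse onto (nearly) one medial point; merge
  # coincident centers on a voxel grid so the k-NN graph spans the tube
  if (nrow(centers) > 1L) {
    voxel <- max(0.1 * max(radii), 1e-6)
    key <- paste(round(centers[, 1] / voxel), round(centers[, 2] / voxel),
                 round(centers[, 3] / voxel))
    grp <- match(key, unique(key))
    centers <- cbind(tapply0(centers[, 1], grp, max(grp)),
                     tapply0(centers[, 2], grp, max(grp)),
                     tapply0(centers[, 3], grp, max(grp))) /
      as.vector(tapply0(rep(1, length(grp)), grp, max(grp)))
    radii <- as.vector(tapply(radii, grp, max))  # grp levels are 1..G
  }
  if (nrow(centers) < 2L)
    stop("centerline extraction failed: no interior medial points (degenerate or flat mesh?)")
  maxR <- max(radii)
  for (seed in list(inlet, outlet)) {
    dmin <- min(.rowNorms(sweep(centers, 2, seed)))
    if (dmin > 2 * maxR)
      stop("connectivity error: seed point is ", round(dmin, 1),
           " mm from the nearest interior medial point (limit ",
           round(2 * maxR, 1), " mm)")
  }
  surf <- med$surface
  nodes <- rbind(centers, inlet, outlet)
  nodeR <- c(radii,
             min(.rowNorms(sweep(surf$points, 2, inlet))),
             min(.rowNorms(sweep(surf$points, 2, outlet))))
  nn <- nrow(nodes)
  iIn <- nn - 1L; iOut <- nn

  d2 <- as.matrix(stats::dist(nodes))
  diag(d2) <- Inf
  k <- min(knn, nn - 1L)
  edges <- NULL
  ord <- apply(d2, 1, order)[seq_len(k), , drop = FALSE]
  from <- rep(seq_len(nn), each = k)
  to <- as.vector(ord)
  e <- cbind(pmin(from, to), pmax(from, to))
  e <- unique(e)
  # prune edges whose midpoint leaves the lumen
  mids <- (nodes[e[, 1], , drop = FALSE] + nodes[e[, 2], , drop = FALSE]) / 2
  np <- .nearestPoint(mids, surf$points)
  inward <- rowSums((mids - surf$points[np$index, , drop = FALSE]) *
                      surf$normals[np$index, , drop = FALSE]) < 0
  e <- e[inward, , drop = FALSE]
  if (nrow(e) == 0L) stop("connectivity error: empty medial graph")
  len <- .rowNorms(nodes[e[, 1], , drop = FALSE] -
                     nodes[e[, 2], , drop = FALSE])
  # radius term uses the smallest of the endpoint radii and the clearance at
  # the edge midpoint, so chords that leave the medial axis are expensive
  rEdge <- pmin((nodeR[e[, 1]] + nodeR[e[, 2]]) / 2, np$dist[inward])
  w <- len / (rEdge^radiusPower)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nn - igraph::vcount(g)))
  sp <- igraph::shortest_paths(g, from = iIn, to = iOut, weights = w,
                               output = "vpath")
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2L)
    stop("connectivity error: inlet and outlet lie in disconnected interior components")
  pts <- nodes[path, , drop = FALSE]
  pts <- .movingAverage(pts, window = smoothWindow, iterations = 2L)
  pts <- .resamplePolyline(pts, nPoints)
  rad <- .nearestPoint(pts, surf$points)$dist
  rad[rad <= 0] <- 1e-9
  .makeCenterline(pts, rad)
}

# Shrinking-ball medial points of a mesh. Returns interior ball centers,
# their radii, and the (subsampled) surface point/normal field used.
.medialPoints <- function(mesh, maxSurfaceSamples = 4000, maxSeeds = 1500,
                          maxIter = 30L) {
  V <- mesh@vertices
  vn <- .vertexNormals(V, mesh@faces)
  if (!.outwardOriented(mesh)) vn <- -vn
  strideTake <- function(n, kmax) {
    if (n <= kmax) seq_len(n) else
      unique(round(seq(1, n, length.out = kmax)))
  }
  sIdx <- strideTake(nrow(V), maxSurfaceSamples)
  S <- V[sIdx, , drop = FALSE]
  Sn <- vn[sIdx, , drop = FALSE]
  seedIdx <- strideTake(nrow(V), maxSeeds)
  P <- V[seedIdx, , drop = FALSE]
  M <- -vn[seedIdx, , drop = FALSE]        # inward directions
  bb <- apply(V, 2, range)
  r <- rep(0.5 * sqrt(sum((bb[2, ] - bb[1, ])^2)), nrow(P))
  active <- rep(TRUE, nrow(P))
  eps <- 1e-9
  S2 <- rowSums(S^2)
  for (it in seq_len(maxIter)) {
    if (!any(active)) break
    C <- P[active, , drop = FALSE] + r[active] * M[active, , drop = FALSE]
    d2 <- outer(rowSums(C^2), S2, "+") - 2 * tcrossprod(C, S)
    d2[d2 < 0] <- 0
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(C)), j)])
    shrink <- dmin < r[active] - eps
    if (!any(shrink)) { active[active] <- FALSE; break }
    Q <- S[j, , drop = FALSE]
    pq <- Q - P[active, , drop = FALSE]
    denom <- 2 * rowSums(M[active, , drop = FALSE] * pq)
    rNew <- rowSums(pq^2) / denom
    ok <- shrink & is.finite(rNew) & denom > eps & rNew > eps &
      rNew < r[active]
    idxAct <- which(active)
    r[idxAct[ok]] <- rNew[ok]
    newActive <- rep(FALSE, length(active))
    newActive[idxAct[ok]] <- TRUE
    active <- newActive
  }
  centers <- P + r * M
  good <- is.finite(r) & r > eps
  list(centers = centers[good, , drop = FALSE], radius = r[good],
       surface = list(points = S, normals = Sn))
}

# TRUE if face winding gives outward normals (ray-parity vote on a few
# faces: a ray along the outward normal of a correctly oriented closed-ish
# surface exits without re-entering an even number of times).
.outwardOriented <- function(mesh, nProbe = 7L) {
  fn <- .faceNormals(mesh@vertices, mesh@faces)
  fc <- .faceCentroids(mesh@vertices, mesh@faces)
  probes <- unique(round(seq(1, nrow(fc), length.out = nProbe)))
  votes <- vapply(probes, function(i) {
    hits <- .rayMeshIntersections(mesh, fc[i, ] + 1e-6 * fn[i, ], fn[i, ])
    length(hits) %% 2L == 0L
  }, logical(1))
  mean(votes) >= 0.5
}

#' Resample a centerline uniformly in arc length
#'
#' @param centerline a [Centerline-class].
#' @param n number of output points (>= 2); first and last points are
#'   preserved and total arc length is preserved to well under 0.1% for
#'   adequately sampled input.
#' @return A [Centerline-class] with `n` points.
#' @examples
#' tube <- makeTube("straight", length = 60, r = 12, nAxial = 20, nCirc = 16)
#' cl <- extractCenterline(tube$mesh, nPoints = 50)
#' centerlineLength(resampleCenterline(cl, 10))
#' @export
resampleCenterline <- function(centerline, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single integer >= 2")
  n <- as.integer(n)
  pts <- .resamplePolyline(centerline@points, n)
  s <- centerline@arcLength
  seg <- .rowNorms(pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])
  sNew <- c(0, cumsum(seg))
  r <- centerline@radius
  rNew <- if (all(is.na(r))) rep(NA_real_, n) else
    stats::approx(s, r, xout = pmin(sNew / sNew[n] * s[length(s)],
                                    s[length(s)]))$y
  new("Centerline", points = pts, arcLength = sNew, radius = rNew)
}

#' Chord length of a centerline
#'
#' Euclidean distance between the first and last centerline points (the
#' segment C0 used by the tortuosity).
#'
#' @param centerline a [Centerline-class].
#' @return Length in mm.
#' @export
chordLength <- function(centerline) {
  p <- centerline@points
  if (nrow(p) < 2L) stop("centerline must have at least 2 points")
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' Import / export a centerline as 3-column CSV
#'
#' Allows a centerline computed elsewhere (e.g. by VMTK) to be supplied
#' verbatim. Columns: `x, y, z` in mm, ordered inlet to outlet. On import,
#' inscribed radii are computed against `mesh` when given, else left NA.
#'
#' @param path CSV path.
#' @param mesh optional [TriangleMesh-class] used to compute radii.
#' @param centerline a [Centerline-class] (for export).
#' @return `importCenterline()` returns a [Centerline-class];
#'   `exportCenterline()` returns `path` invisibly.
#' @export
importCenterline <- function(path, mesh = NULL) {
  tab <- utils::read.csv(path)
  .checkSchema(tab, c("x", "y", "z"))
  pts <- as.matrix(tab[, c("x", "y", "z")])
  rad <- if (is.null(mesh)) rep(NA_real_, nrow(pts)) else
    .closestPointOnMesh(mesh, pts)$dist
  .makeCenterline(pts, rad)
}

#' @rdname importCenterline
#' @export
exportCenterline <- function(centerline, path) {
  p <- centerline@points
  utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}
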