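# Low-level vectorized geometry helpers shared across modules.

.rowNorms <- function(m) sqrt(rowSums(m^2))

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-14) stop("cannot normalize a zero vector")
  v / n
}

.faceAreas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  0.5 * .rowNorms(.vcross(b - a, cc - a))
}

.faceNormals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  n <- .vcross(b - a, cc - a)
  len <- .rowNorms(n)
  len[len < 1e-300] <- 1
  n / len
}

.faceCentroids <- function(vertices, faces) {
  (vertices[faces[, 1], , drop = FALSE] +
     vertices[faces[, 2], , drop = FALSE] +
     vertices[faces[, 3], , drop = FALSE]) / 3
}

# Area-weighted per-vertex normals (direction set by face winding).
.vertexNormals <- function(vertices, faces) {
  fn <- .faceNormals(vertices, faces)
  fa <- .faceAreas(vertices, faces)
  vn <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    idx <- faces[, j]
    for (d in 1:3)
      vn[, d] <- vn[, d] + unname(tapply0(fn[, d] * fa, idx, nrow(vertices)))
  }
  len <- .rowNorms(vn)
  len[len < 1e-300] <- 1
  vn / len
}

# rowsum-based accumulation into a fixed-length vector
tapply0 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.polylineLength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(.rowNorms(pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]))
}

# Orthonormal in-plane basis (u, v) for a unit normal n.
.planeBasis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(pracmaFreeCross(a, n))
  v <- pracmaFreeCross(n, u)
  list(u = u, v = v)
}

pracmaFreeCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Point-in-polygon (2-D, ray parity), polygon closed implicitly.
.pointInPolygon <- function(pt, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - x) * (pt[2] - y) / (yj - y) + x)
  sum(crosses) %% 2L == 1L
}

# Moving-average smoothing with fixed endpoints.
.movingAverage <- function(pts, window = 5L, iterations = 1L) {
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- nrow(pts)
  h <- (window - 1L) %/% 2L
  if (n < 3L || h == 0L) return(pts)
  for (it in seq_len(iterations)) {
    out <- pts
    for (i in 2:(n - 1L)) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
    }
    pts <- out
  }
  pts
}

# Resample a polyline to n points equally spaced in arc length.
.resamplePolyline <- function(pts, n) {
  if (n < 2L) stop("n must be >= 2")
  seg <- .rowNorms(pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("degenerate polyline (zero length)")
  keep <- c(TRUE, diff(s) > 0)
  pts <- pts[keep, , drop = FALSE]; s <- s[keep]
  target <- seq(0, s[length(s)], length.out = n)
  out <- vapply(1:3, function(d) stats::approx(s, pts[, d], xout = target)$y,
                numeric(n))
  out <- matrix(out, ncol = 3)
  out[1, ] <- pts[1, ]; out[n, ] <- pts[nrow(pts), ]
  out
}

# Nearest surface-sample index and distance for each query point.
.nearestPoint <- function(query, ref) {
  q2 <- rowSums(query^2); r2 <- rowSums(ref^2)
  d2 <- outer(q2, r2, "+") - 2 * tcrossprod(query, ref)
  d2[d2 < 0] <- 0
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, dist = sqrt(d2[cbind(seq_len(nrow(query)), idx)]))
}

# Closest point on each triangle (V1,V2,V3 row-matched matrices) to p;
# Ericson's region classification, vectorized over triangles.
.closestOnTriangles <- function(p, V1, V2, V3) {
  ab <- V2 - V1; ac <- V3 - V1
  ap <- matrix(p, nrow(V1), 3, byrow = TRUE) - V1
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  res <- matrix(NA_real_, nrow(V1), 3)
  done <- d1 <= 0 & d2 <= 0
  res[done, ] <- V1[done, , drop = FALSE]
  bp <- matrix(p, nrow(V1), 3, byrow = TRUE) - V2
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  m <- !done & d3 >= 0 & d4 <= d3
  res[m, ] <- V2[m, , drop = FALSE]; done <- done | m
  vc <- d1 * d4 - d3 * d2
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  v <- d1 / (d1 - d3)
  res[m, ] <- V1[m, , drop = FALSE] + v[m] * ab[m, , drop = FALSE]
  done <- done | m
  cp <- matrix(p, nrow(V1), 3, byrow = TRUE) - V3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  m <- !done & d6 >= 0 & d5 <= d6
  res[m, ] <- V3[m, , drop = FALSE]; done <- done | m
  vb <- d5 * d2 - d1 * d6
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  w <- d2 / (d2 - d6)
  res[m, ] <- V1[m, , drop = FALSE] + w[m] * ac[m, , drop = FALSE]
  done <- done | m
  va <- d3 * d6 - d5 * d4
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  res[m, ] <- V2[m, , drop = FALSE] +
    w[m] * (V3[m, , drop = FALSE] - V2[m, , drop = FALSE])
  done <- done | m
  denom <- va + vb + vc
  denom[denom == 0] <- 1
  v <- vb / denom; w <- vc / denom
  m <- !done
  res[m, ] <- V1[m, , drop = FALSE] + v[m] * ab[m, , drop = FALSE] +
    w[m] * ac[m, , drop = FALSE]
  res
}

# Closest point on a mesh to each row of pts.
.closestPointOnMesh <- function(mesh, pts) {
  V <- mesh@vertices; Fc <- mesh@faces
  V1 <- V[Fc[, 1], , drop = FALSE]
  V2 <- V[Fc[, 2], , drop = FALSE]
  V3 <- V[Fc[, 3], , drop = FALSE]
  out <- matrix(NA_real_, nrow(pts), 3)
  dist <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cp <- .closestOnTriangles(pts[i, ], V1, V2, V3)
    d2 <- rowSums((cp - matrix(pts[i, ], nrow(cp), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    out[i, ] <- cp[j, ]
    dist[i] <- sqrt(d2[j])
  }
  list(points = out, dist = dist)
}

# Moller-Trumbore ray/mesh intersection: all hit parameters t > 0.
.rayMeshIntersections <- function(mesh, origin, direction, tol = 1e-9) {
  V <- mesh@vertices; Fc <- mesh@faces
  V1 <- V[Fc[, 1], , drop = FALSE]
  e1 <- V[Fc[, 2], , drop = FALSE] - V1
  e2 <- V[Fc[, 3], , drop = FALSE] - V1
  d <- matrix(direction, nrow(V1), 3, byrow = TRUE)
  pvec <- .vcross(d, e2)
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > tol
  tvec <- matrix(origin, nrow(V1), 3, byrow = TRUE) - V1
  u <- rowSums(tvec * pvec) / det
  qvec <- .vcross(tvec, e1)
  v <- rowSums(d * qvec) / det
  t <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t > tol
  sort(t[hit])
}

# Connected-component membership for every mesh vertex.
.vertexComponents <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh@vertices) -
                                     igraph::vcount(g)))
  igraph::components(g)$membership
}
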