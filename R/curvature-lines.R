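#' Shortest discrete geodesic between the annulus and ostium boundaries
#'
#' Edge-restricted shortest path on the surface graph (mesh edges weighted
#' by Euclidean length) over all pairs of boundary vertices: every annulus
#' vertex is a source at distance zero (multi-source Dijkstra, equivalent
#' to enumerating all annulus/ostium pairs) and the minimal-distance ostium
#' vertex terminates the search. The raw broken line is the basis of the
#' internal curvature line after smoothing (see [smoothPath()]).
#'
#' @param domain an [AAoDomain-class].
#' @return `list(path, length)`: vertex indices into the surface mesh and
#'   the path length in mm.
#' @examples
#' tube <- makeTube("straight", length = 60, r = 12, nAxial = 30, nCirc = 24)
#' cl <- extractCenterline(tube$mesh)
#' dom <- isolateAscending(tube$mesh, cl, ostiumArc = centerlineLength(cl))
#' shortestGeodesic(dom)$length  # ~60
#' @export
shortestGeodesic <- function(domain) {
  mesh <- domain@surface
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- .rowNorms(mesh@vertices[e[, 1], , drop = FALSE] -
                   mesh@vertices[e[, 2], , drop = FALSE])
  nv <- nrow(mesh@vertices)
  src <- nv + 1L
  aIdx <- domain@annulus@indices
  oIdx <- domain@ostium@indices
  eAll <- rbind(e, cbind(rep(src, length(aIdx)), aIdx))
  wAll <- c(w, rep(0, length(aIdx)))
  g <- igraph::graph_from_edgelist(eAll, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, (nv + 1L) - igraph::vcount(g)))
  dists <- igraph::distances(g, v = src, to = oIdx, weights = wAll)
  if (all(!is.finite(dists)))
    stop("connectivity error: annulus and ostium boundaries lie in different components")
  target <- oIdx[which.min(dists)]
  sp <- igraph::shortest_paths(g, from = src, to = target, weights = wAll,
                               output = "vpath")
  path <- as.integer(sp$vpath[[1]])
  path <- path[path != src]
  list(path = path, length = min(dists))
}

#' Smooth a surface path into the internal curvature line
#'
#' Endpoint-preserving moving-average smoothing of the raw geodesic broken
#' line, with re-projection of the smoothed points onto the surface.
#' Smoothing shortens a broken line; iterations stop before the length
#' drops below 90% of the raw length (over-smoothing guard).
#'
#' @param domain an [AAoDomain-class] (provides the surface for
#'   re-projection).
#' @param geodesic result of [shortestGeodesic()], or an integer vertex
#'   path.
#' @param window odd moving-average window (default 5).
#' @param iterations smoothing passes (default 2).
#' @return A [CurvatureLine-class] of kind `"internal"`.
#' @export
smoothPath <- function(domain, geodesic, window = 5, iterations = 2) {
  path <- if (is.list(geodesic)) geodesic$path else as.integer(geodesic)
  mesh <- domain@surface
  pts <- mesh@vertices[path, , drop = FALSE]
  rawLen <- .polylineLength(pts)
  if (length(path) >= 3L) {
    cur <- pts
    for (it in seq_len(iterations)) {
      cand <- .movingAverage(cur, window = window, iterations = 1L)
      cand <- .closestPointOnMesh(mesh, cand)$points
      cand[1, ] <- pts[1, ]; cand[nrow(cand), ] <- pts[nrow(pts), ]
      if (.polylineLength(cand) < 0.9 * rawLen) {
        # very jagged input: blend toward the smoothed line only as far as
        # the over-smoothing guard allows (length stays >= 0.9 x raw)
        lo <- 0; hi <- 1
        for (b in 1:20) {
          mid <- (lo + hi) / 2
          trial <- cur + mid * (cand - cur)
          if (.polylineLength(trial) >= 0.905 * rawLen) lo <- mid else hi <- mid
        }
        cur <- cur + lo * (cand - cur)
        break
      }
      cur <- cand
    }
    pts <- cur
  }
  len <- .polylineLength(pts)
  new("CurvatureLine", kind = "internal", points = pts, length = len,
      rawPath = as.integer(path), anchors = matrix(numeric(0), 0, 3))
}

#' External curvature line by ray casting through the centerline
#'
#' For each cross-section, the intersection of the internal curvature line
#' with the section plane gives an internal anchor; the ray from it
#' through the section center (the unit versor toward the lumen center)
#' is cast against the surface, and the first intersection strictly beyond
#' the center is the external anchor. A natural interpolating cubic spline
#' through the ordered anchors, measured on a 10x oversampled polyline,
#' is the external curvature line (ECL). Sections whose ray misses the
#' surface, or with a degenerate (zero) versor, are skipped with a
#' warning; more than 20% skipped is an error.
#'
#' @param domain an [AAoDomain-class].
#' @param sections list of [PlaneSection-class] from [extractSections()].
#' @param icl internal [CurvatureLine-class] from [smoothPath()].
#' @return A [CurvatureLine-class] of kind `"external"` with per-section
#'   anchors.
#' @export
externalLine <- function(domain, sections, icl) {
  mesh <- domain@surface
  iclPts <- icl@points
  anchors <- matrix(NA_real_, length(sections), 3)
  skipped <- 0L
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    xic <- .intersectPolylinePlane(iclPts, s@plane, s@center)
    v <- s@center - xic
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) {
      warning("section ", s@index,
              ": internal anchor coincides with the center, skipped")
      skipped <- skipped + 1L
      next
    }
    v <- v / nv
    hits <- .rayMeshIntersections(mesh, xic, v)
    hits <- hits[hits > nv + 1e-6]
    if (length(hits) == 0L) {
      warning("section ", s@index, ": ray missed the surface, skipped")
      skipped <- skipped + 1L
      next
    }
    anchors[i, ] <- xic + hits[1] * v
  }
  if (skipped > 0.2 * length(sections))
    stop("external line failed: ", skipped, " of ", length(sections),
         " sections skipped")
  anchors <- anchors[stats::complete.cases(anchors), , drop = FALSE]
  if (nrow(anchors) < 4L) stop("too few external anchors for a spline")
  # the first/last sections sit slightly inside the cut planes; extend the
  # anchor polyline to the annulus/ostium planes so the ECL spans the domain
  spacing <- stats::median(.rowNorms(anchors[-1, , drop = FALSE] -
                                       anchors[-nrow(anchors), , drop = FALSE]))
  extendTo <- function(a, b, loop) {
    dir <- a - b
    dn <- sum(dir * loop@normal)
    if (abs(dn) < 1e-9) return(NULL)
    t <- sum((loop@centroid - a) * loop@normal) / dn
    if (t <= 0 || .rowNorms(matrix(t * dir, 1)) > 5 * spacing) return(NULL)
    a + t * dir
  }
  ext1 <- extendTo(anchors[1, ], anchors[2, ], domain@annulus)
  ext2 <- extendTo(anchors[nrow(anchors), ], anchors[nrow(anchors) - 1, ],
                   domain@ostium)
  if (!is.null(ext1)) anchors <- rbind(ext1, anchors)
  if (!is.null(ext2)) anchors <- rbind(anchors, ext2)
  seg <- .rowNorms(anchors[-1, , drop = FALSE] -
                     anchors[-nrow(anchors), , drop = FALSE])
  param <- c(0, cumsum(seg))
  dense <- seq(0, param[length(param)], length.out = 10L * nrow(anchors))
  pts <- vapply(1:3, function(d)
    stats::spline(param, anchors[, d], xout = dense,
                  method = "natural")$y,
    numeric(length(dense)))
  pts <- matrix(pts, ncol = 3)
  new("CurvatureLine", kind = "external", points = pts,
      length = .polylineLength(pts), rawPath = integer(0),
      anchors = anchors)
}

# First crossing of a polyline with a plane (linear interpolation); if the
# polyline does not cross, the nearest polyline point is used (warning).
# Among several crossings, the one nearest `ref` wins.
.intersectPolylinePlane <- function(pts, plane, ref) {
  d <- as.numeric((pts %*% plane@normal) - sum(plane@point * plane@normal))
  s <- which(d[-1] * d[-length(d)] <= 0 &
               abs(d[-1] - d[-length(d)]) > 1e-300)
  if (length(s) == 0L) {
    warning("curve does not cross the section plane; using nearest point")
    return(pts[which.min(abs(d)), ])
  }
  cand <- t(vapply(s, function(i) {
    t <- d[i] / (d[i] - d[i + 1])
    pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
  }, numeric(3)))
  cand[which.min(.rowNorms(sweep(cand, 2, ref))), ]
}

#' External/internal curvature-line length ratio
#'
#' `EILR = L(ECL) / L(ICL)` (dimensionless). Sensitive to outward wall
#' expansion, as in saccular or root aneurysms.
#'
#' @param ecl,icl the two [CurvatureLine-class] objects (order matters).
#' @return EILR (dimensionless).
#' @export
eilr <- function(ecl, icl) {
  if (icl@length <= 0) stop("internal curvature line has zero length")
  ecl@length / icl@length
}

#' Centerline tortuosity
#'
#' `T = L(C) / L(C0)` where `C0` is the straight segment joining the
#' centerline endpoints; `T = 1` for a straight vessel and grows with
#' curvature (a semicircle gives `pi/2`).
#'
#' @param centerline a [Centerline-class].
#' @return Tortuosity (dimensionless, >= 1).
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' semi <- .makeCenterline(cbind(cos(th), sin(th), 0))
#' tortuosity(semi)  # ~ pi/2
#' @export
tortuosity <- function(centerline) {
  c0 <- chordLength(centerline)
  if (c0 <= 1e-12)
    stop("tortuosity undefined: centerline endpoints coincide")
  centerlineLength(centerline) / c0
}

#' Export a curvature line as 3-column CSV
#'
#' @param line a [CurvatureLine-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportCurvatureLine <- function(line, path) {
  p <- line@points
  utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}
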